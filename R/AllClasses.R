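#' MotifLibrary: consensus models for PPR and auxiliary motifs
#'
#' Holds one consensus amino-acid string per motif class together with a
#' per-position substitution probability `epsilon` describing how
#' degenerate instances of the motif are. The canonical plant PPR repeat
#' is a degenerate ~35-residue unit; the library also carries the longer
#' C-terminal E, E+ and DYW domains (the DYW consensus ends with the
#' literal Asp-Tyr-Trp tripeptide) and the auxiliary RRM, LAGLIDADG and
#' SMR domains found fused to some PPR proteins.
#'
#' @slot consensus Named character vector of consensus sequences, one per
#'   motif class.
#' @slot epsilon Named numeric vector in `[0, 0.5)`: the probability that
#'   any one consensus position is substituted in a sampled instance.
#' @seealso [buildDefaultMotifLibrary()]
#' @export
setClass("MotifLibrary",
         representation(consensus = "character", epsilon = "numeric"))

setValidity("MotifLibrary", function(object) {
  msg <- character()
  need <- names(.MOTIF_LENGTHS)
  if (!all(need %in% names(object@consensus)))
    msg <- c(msg, paste("missing consensus for:",
                        paste(setdiff(need, names(object@consensus)),
                              collapse = ", ")))
  else {
    lens <- nchar(object@consensus[need])
    bad <- need[lens != .MOTIF_LENGTHS[need]]
    if (length(bad))
      msg <- c(msg, paste("wrong consensus length for:",
                          paste(bad, collapse = ", ")))
    dyw <- object@consensus[["DYW"]]
    if (substr(dyw, nchar(dyw) - 2L, nchar(dyw)) != "DYW")
      msg <- c(msg, "DYW consensus must end with the residues D,Y,W")
  }
  if (!all(names(object@consensus) %in% names(object@epsilon)))
    msg <- c(msg, "epsilon must be named for every consensus class")
  if (any(object@epsilon < 0 | object@epsilon >= 0.5))
    msg <- c(msg, "epsilon must lie in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MotifLibrary", function(object) {
  cat("MotifLibrary with", length(object@consensus), "motif classes\n")
  lens <- nchar(object@consensus)
  cat(paste0("  ", format(names(lens)), " length ", lens,
             "  epsilon ", object@epsilon[names(lens)], "\n"), sep = "")
})

#' @describeIn MotifLibrary Motif class names present in the library.
#' @param x A `MotifLibrary`.
#' @export
motifClasses <- function(x) names(x@consensus)

#' @describeIn MotifLibrary Consensus sequence of one motif class.
#' @param motifClass Class name, e.g. `"P"` or `"DYW"`.
#' @export
motifConsensus <- function(x, motifClass) {
  if (!motifClass %in% names(x@consensus))
    stop("unknown motif class: ", motifClass)
  x@consensus[[motifClass]]
}

#' ScanParams: thresholds for motif screening and PPR identification
#'
#' Bundles the thresholds of the identification workflow: domain hits are
#' first screened at a permissive E-value (<= 10), a protein is accepted
#' as a PPR protein only if it carries at least `minRepeatMotifs`
#' repeat-class (P/L/S/L2) motifs after overlap resolution and at least
#' one hit with E-value below `confidentEvalueMax` (< 1.0). Hits from the
#' built-in PSSM scanner carry bit scores instead of E-values and are
#' screened at `pssmScoreMin`.
#'
#' @slot screenEvalueMax Permissive screening E-value ceiling (default 10).
#' @slot confidentEvalueMax Confident-hit E-value ceiling (default 1.0).
#' @slot minRepeatMotifs Minimum resolved repeat-class motifs (default 2).
#' @slot overlapTolerance Residues two chained motifs may overlap
#'   (default 3).
#' @slot pssmScoreMin Bit-score floor for scanner hits (default 8).
#' @export
setClass("ScanParams",
         representation(screenEvalueMax = "numeric",
                        confidentEvalueMax = "numeric",
                        minRepeatMotifs = "integer",
                        overlapTolerance = "integer",
                        pssmScoreMin = "numeric"))

setValidity("ScanParams", function(object) {
  msg <- character()
  if (object@confidentEvalueMax > object@screenEvalueMax)
    msg <- c(msg, "confidentEvalueMax must be <= screenEvalueMax")
  if (object@minRepeatMotifs < 1L)
    msg <- c(msg, "minRepeatMotifs must be >= 1")
  if (object@overlapTolerance < 0L)
    msg <- c(msg, "overlapTolerance must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ScanParams-class
#' @param screenEvalueMax,confidentEvalueMax,minRepeatMotifs,overlapTolerance,pssmScoreMin
#'   See the class slots.
#' @return A `ScanParams` object.
#' @examples
#' ScanParams()
#' ScanParams(minRepeatMotifs = 3L)
#' @export
ScanParams <- function(screenEvalueMax = 10, confidentEvalueMax = 1.0,
                       minRepeatMotifs = 2L, overlapTolerance = 3L,
                       pssmScoreMin = 8.0) {
  new("ScanParams",
      screenEvalueMax = screenEvalueMax,
      confidentEvalueMax = confidentEvalueMax,
      minRepeatMotifs = as.integer(minRepeatMotifs),
      overlapTolerance = as.integer(overlapTolerance),
      pssmScoreMin = pssmScoreMin)
}

setMethod("show", "ScanParams", function(object) {
  cat("ScanParams: screen E <=", object@screenEvalueMax,
      "| confident E <", object@confidentEvalueMax,
      "| min repeat motifs", object@minRepeatMotifs,
      "| overlap tol", object@overlapTolerance, "aa",
      "| PSSM score >=", object@pssmScoreMin, "bits\n")
})

#' GeneModels: positioned gene models with exon/CDS structure
#'
#' The in-memory genome annotation used throughout the pipeline: one
#' positioned gene per entry (1-based inclusive coordinates, as in GFF3),
#' with per-transcript exon and CDS intervals and a representative
#' transcript chosen as the one with the longest total CDS (ties broken
#' by lexicographically smallest transcript id). Intron counts and
#' chromosomal statistics are computed from the representative
#' transcript only.
#'
#' @slot genes A [GenomicRanges::GRanges] of gene spans with metadata
#'   columns `gene_id`, `representative_tx` and `cds_incomplete` (TRUE
#'   when the representative CDS length is not divisible by 3).
#' @slot exons A [GenomicRanges::GRangesList] of exon intervals, one
#'   element per transcript, named by transcript id.
#' @slot cds A [GenomicRanges::GRangesList] of CDS intervals, one element
#'   per transcript, named by transcript id.
#' @slot txGene data.frame mapping `tx_id` to `gene_id`.
#' @seealso [readGff3()], [countIntrons()], [intronBins()],
#'   [chromosomeDistribution()]
#' @export
setClass("GeneModels",
         representation(genes = "GRanges", exons = "GRangesList",
                        cds = "GRangesList", txGene = "data.frame"))

setValidity("GeneModels", function(object) {
  msg <- character()
  g <- object@genes
  if (!all(c("gene_id", "representative_tx", "cds_incomplete") %in%
           colnames(mcols(g))))
    msg <- c(msg, "genes must carry gene_id, representative_tx, cds_incomplete")
  else {
    if (anyDuplicated(mcols(g)$gene_id))
      msg <- c(msg, "duplicated gene_id")
    if (!all(mcols(g)$representative_tx %in% object@txGene$tx_id))
      msg <- c(msg, "representative_tx not among the gene's transcripts")
    bad <- .exonsOutsideGenes(g, object@exons, object@txGene)
    if (length(bad))
      msg <- c(msg, paste("exon(s) outside the gene span for transcript(s):",
                          paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneModels", function(object) {
  nch <- length(unique(as.character(seqnames(object@genes))))
  cat("GeneModels:", length(object@genes), "genes,",
      nrow(object@txGene), "transcripts on", nch, "chromosome(s)\n")
})

setMethod("length", "GeneModels", function(x) length(x@genes))

#' @describeIn GeneModels Gene identifiers, in annotation order.
#' @param x A `GeneModels` object.
#' @export
geneIds <- function(x) mcols(x@genes)$gene_id

#' @describeIn GeneModels Gene spans as a `GRanges` named by gene id.
#' @export
geneRanges <- function(x) {
  g <- x@genes
  names(g) <- mcols(g)$gene_id
  g
}

#' @describeIn GeneModels Representative transcript id per gene (named
#'   character vector).
#' @export
representativeTx <- function(x)
  setNames(mcols(x@genes)$representative_tx, mcols(x@genes)$gene_id)

#' @describeIn GeneModels Exon intervals of one transcript.
#' @param tx_id Transcript identifier.
#' @export
transcriptExons <- function(x, tx_id) {
  if (!tx_id %in% names(x@exons)) stop("unknown transcript: ", tx_id)
  x@exons[[tx_id]]
}

#' Flatten gene models to a per-gene table
#'
#' @param x A [GeneModels] object.
#' @param row.names,optional Ignored (S3 compatibility).
#' @param ... Ignored.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `representative_tx`, `n_exons`, `cds_length`,
#'   `cds_incomplete`.
#' @exportS3Method base::as.data.frame
#' @export
as.data.frame.GeneModels <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  g <- x@genes
  rep_tx <- mcols(g)$representative_tx
  nex <- vapply(rep_tx, function(tx) length(x@exons[[tx]]), integer(1))
  clen <- vapply(rep_tx, function(tx) {
    cd <- x@cds[[tx]]
    if (is.null(cd)) 0L else sum(GenomicRanges::width(cd))
  }, integer(1))
  data.frame(gene_id = mcols(g)$gene_id,
             chrom = as.character(seqnames(g)),
             start = GenomicRanges::start(g),
             end = GenomicRanges::end(g),
             strand = as.character(strand(g)),
             representative_tx = rep_tx,
             n_exons = nex,
             cds_length = clen,
             cds_incomplete = mcols(g)$cds_incomplete,
             row.names = NULL)
}

setMethod("as.data.frame", "GeneModels", as.data.frame.GeneModels)

# Transcripts whose exon envelope escapes the parent gene span.
.exonsOutsideGenes <- function(genes, exons, txGene) {
  withEx <- names(exons)[S4Vectors::elementNROWS(exons) > 0L]
  withEx <- intersect(withEx, txGene$tx_id)
  if (!length(withEx)) return(character(0))
  sub <- exons[withEx]
  exMin <- min(GenomicRanges::start(sub))   # per-transcript minima
  exMax <- max(GenomicRanges::end(sub))
  gid <- setNames(txGene$gene_id, txGene$tx_id)[withEx]
  gs <- setNames(GenomicRanges::start(genes), mcols(genes)$gene_id)
  ge <- setNames(GenomicRanges::end(genes), mcols(genes)$gene_id)
  bad <- exMin < gs[gid] | exMax > ge[gid]
  withEx[bad]
}

# Accept either a GeneModels or an already-flattened gene table.
.geneTable <- function(genes) {
  if (is(genes, "GeneModels")) return(as.data.frame(genes))
  if (is.data.frame(genes)) {
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(genes)))
      stop("gene table must have columns: ", paste(need, collapse = ", "))
    return(genes)
  }
  stop("expected a GeneModels object or a gene table data.frame")
}
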