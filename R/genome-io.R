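# Readers and writers for the standard formats the pipeline touches.
# All coordinates are 1-based inclusive, as in GFF3 and HMMER tables.

.PROTEIN_ALPHABET <- c(.AA20, "X")
.NUC_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a FASTA file into a Biostrings set
#'
#' Reads protein or nucleotide FASTA, uppercasing sequences and checking
#' the alphabet. Record ids must be unique and sequences non-empty.
#'
#' @param path Path to a FASTA file.
#' @param kind `"auto"` (default), `"protein"` or `"nucleotide"`. Under
#'   `"auto"` the file is called nucleotide when every residue is one of
#'   A, C, G, T, N.
#' @return An [Biostrings::AAStringSet] or [Biostrings::DNAStringSet],
#'   named by record id, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "MKVL", ">g2", "MPPR"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path, kind = c("auto", "protein", "nucleotide")) {
  kind <- match.arg(kind)
  raw <- readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (any(!nzchar(seqs))) {
    empty <- ids[!nzchar(seqs)]
    stop("empty sequence for id(s): ", paste(empty, collapse = ", "))
  }
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  isNuc <- all(chars %in% .NUC_ALPHABET)
  if (kind == "auto") kind <- if (isNuc) "nucleotide" else "protein"
  if (kind == "nucleotide") {
    if (!isNuc)
      stop("non-nucleotide residue(s): ",
           paste(setdiff(chars, .NUC_ALPHABET), collapse = ", "))
    out <- DNAStringSet(seqs)
  } else {
    bad <- setdiff(chars, .PROTEIN_ALPHABET)
    if (length(bad))
      stop("non-protein residue(s): ", paste(bad, collapse = ", "))
    out <- AAStringSet(seqs)
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A named `XStringSet` or named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- BStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 annotation (gene / mRNA / exon / CDS features with
#' resolvable `Parent` attributes) into a [GeneModels] object. The
#' representative transcript of each gene is the one with the longest
#' total CDS, ties broken by the lexicographically smallest transcript
#' id. A representative CDS length not divisible by 3 is flagged
#' (`cds_incomplete`), not fatal.
#'
#' @param path Path to a GFF3 file.
#' @return A [GeneModels] object.
#' @export
readGff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("failed to parse GFF3 '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  type <- as.character(gr$type)
  getId <- function(x) as.character(mcols(x)$ID)
  firstParent <- function(x) {
    p <- mcols(x)$Parent
    vapply(as.list(p), function(v)
      if (length(v)) as.character(v[[1L]]) else NA_character_,
      character(1))
  }

  genes <- gr[type == "gene"]
  geneIdsV <- getId(genes)
  if (anyDuplicated(geneIdsV)) stop("duplicated gene ID in ", path)

  mrna <- gr[type %in% c("mRNA", "transcript")]
  txIds <- getId(mrna)
  txParent <- firstParent(mrna)
  if (any(is.na(txParent)))
    stop("mRNA without Parent attribute: ",
         paste(txIds[is.na(txParent)], collapse = ", "))
  orphan <- setdiff(txParent, geneIdsV)
  if (length(orphan))
    stop("mRNA Parent does not resolve to a gene: ",
         paste(orphan, collapse = ", "))

  exon <- gr[type == "exon"]
  cds <- gr[type == "CDS"]
  splitByTx <- function(feat) {
    par <- firstParent(feat)
    if (any(is.na(par)))
      stop("exon/CDS feature without Parent attribute in ", path)
    bad <- setdiff(par, txIds)
    if (length(bad))
      stop("exon/CDS Parent does not resolve to an mRNA: ",
           paste(bad, collapse = ", "))
    lst <- split(feat, factor(par, levels = txIds))
    GenomicRanges::GRangesList(lapply(lst, function(g)
      GenomicRanges::sort(g)))
  }
  exonsByTx <- splitByTx(exon)
  cdsByTx <- splitByTx(cds)

  # exon containment in the parent gene span
  genesAnn <- genes
  mcols(genesAnn) <- S4Vectors::DataFrame(gene_id = geneIdsV)
  badTx <- .exonsOutsideGenes(genesAnn,  exonsByTx,
                              data.frame(tx_id = txIds,
                                         gene_id = txParent))
  if (length(badTx))
    stop("exon of transcript ", badTx[1L],
         " lies outside the span of its gene")

  cdsLen <- vapply(txIds, function(tx) {
    cd <- cdsByTx[[tx]]
    if (is.null(cd) || !length(cd)) 0L else sum(GenomicRanges::width(cd))
  }, integer(1))

  repTx <- vapply(geneIdsV, function(gid) {
    txs <- txIds[txParent == gid]
    if (!length(txs)) stop("gene without mRNA: ", gid)
    txs[order(-cdsLen[txs], txs)][1L]
  }, character(1))

  incomplete <- cdsLen[repTx] %% 3L != 0L
  if (any(incomplete))
    warning("representative CDS length not divisible by 3 for: ",
            paste(geneIdsV[incomplete], collapse = ", "))

  out <- genes
  mcols(out) <- S4Vectors::DataFrame(gene_id = geneIdsV,
                                     representative_tx = unname(repTx),
                                     cds_incomplete = unname(incomplete))
  new("GeneModels", genes = out, exons = exonsByTx, cds = cdsByTx,
      txGene = data.frame(tx_id = txIds, gene_id = txParent))
}

# Default mapping from domain-profile names to motif classes. Profile
# names with a trailing numeric suffix (e.g. LAGLIDADG_2) fall back to
# the suffix-stripped name.
#' @rdname readDomtblout
#' @export
defaultMotifNameMap <- function() {
  c(PPR_P = "P", PPR_L = "L", PPR_S = "S", PPR_L2 = "L2",
    PPR_E = "E", PPR_Eplus = "Eplus", PPR_DYW = "DYW",
    PPR = "PPR_generic", PPR_1 = "PPR_generic", PPR_2 = "PPR_generic",
    PPR_3 = "PPR_generic",
    RRM = "RRM", RRM_1 = "RRM", LAGLIDADG = "LAGLIDADG", SMR = "SMR")
}

#' Read per-domain motif hits from an HMMER3 domain table
#'
#' Parses the `domtblout` dialect (whitespace-aligned columns, `#`
#' comment lines). Each domain row yields one motif hit using the
#' alignment coordinates (`ali from`/`ali to`) and the per-domain
#' independent E-value, the quantities relevant for chaining motifs into
#' an architecture. The profile (query) name is mapped to a motif class
#' through `nameMap`; unmappable names are retained with class `"other"`
#' and a warning.
#'
#' @param path Path to a domtblout file.
#' @param nameMap Named character vector mapping profile names to motif
#'   classes; see [defaultMotifNameMap()].
#' @return data.frame of motif hits with columns `protein_id`,
#'   `motif_class`, `start`, `end`, `score`, `evalue`.
#' @export
readDomtblout <- function(path, nameMap = defaultMotifNameMap()) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  out <- data.frame(protein_id = character(), motif_class = character(),
                    start = integer(), end = integer(),
                    score = numeric(), evalue = numeric())
  if (!length(rows)) return(out)
  parsed <- lapply(rows, function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) < 22L)
      stop("malformed domtblout row at line ", i, ": expected >= 22 ",
           "columns, got ", length(f))
    vals <- suppressWarnings(as.numeric(f[c(13L, 14L, 18L, 19L)]))
    if (any(is.na(vals)))
      stop("malformed numeric field in domtblout at line ", i)
    list(protein_id = f[1L], profile = f[4L], evalue = vals[1L],
         score = vals[2L], start = as.integer(vals[3L]),
         end = as.integer(vals[4L]))
  })
  profile <- vapply(parsed, `[[`, character(1), "profile")
  cls <- nameMap[profile]
  stripped <- sub("_[0-9]+$", "", profile)
  cls[is.na(cls)] <- nameMap[stripped[is.na(cls)]]
  unknown <- unique(profile[is.na(cls)])
  if (length(unknown))
    warning("unmappable profile name(s) kept as class 'other': ",
            paste(unknown, collapse = ", "))
  cls[is.na(cls)] <- "other"
  data.frame(protein_id = vapply(parsed, `[[`, character(1), "protein_id"),
             motif_class = unname(cls),
             start = vapply(parsed, `[[`, integer(1), "start"),
             end = vapply(parsed, `[[`, integer(1), "end"),
             score = vapply(parsed, `[[`, numeric(1), "score"),
             evalue = vapply(parsed, `[[`, numeric(1), "evalue"))
}

#' Write motif hits as a minimal HMMER3-style domain table
#'
#' Emits rows in the 23-column domtblout layout (placeholder values for
#' the columns the pipeline does not use) so that simulated truth hits
#' travel through the same format as real search output.
#'
#' @param hits data.frame with columns `protein_id`, `profile`, `start`,
#'   `end`, `score`, `evalue`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeDomtblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# target name accession tlen query name accession",
                   "qlen E-value score bias # of c-Evalue i-Evalue score",
                   "bias hmm_from hmm_to ali_from ali_to env_from env_to",
                   "acc description"), con)
  if (nrow(hits)) {
    ev <- format(hits$evalue, scientific = TRUE, digits = 3)
    lines <- paste(hits$protein_id, "-", 999L, hits$profile, "-", 99L,
                   ev, format(hits$score, digits = 4), "0.0",
                   1L, 1L, ev, ev, format(hits$score, digits = 4), "0.0",
                   1L, hits$end - hits$start + 1L,
                   hits$start, hits$end, hits$start, hits$end,
                   "0.99", "-")
    writeLines(lines, con)
  }
  invisible(path)
}

.SIMILARITY_COLS <- c("query_id", "subject_id", "pct_identity",
                      "aln_length", "mismatches", "gap_opens",
                      "q_start", "q_end", "s_start", "s_end",
                      "evalue", "bitscore")

#' Read 12-column tabular similarity hits
#'
#' Parses the tab-separated 12-column pairwise-similarity dialect
#' (BLAST `outfmt 6`): query, subject, percent identity, alignment
#' length, mismatches, gap opens, query/subject start/end, E-value, bit
#' score. Self-hits are retained; downstream filters remove them.
#'
#' @param path Path to the tabular file.
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`.
#' @export
readSimilarityTab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- as.data.frame(setNames(
    c(rep(list(character()), 2L), rep(list(numeric()), 10L)),
    .SIMILARITY_COLS))
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("similarity table row with ", nf[nf != 12L][1L],
         " columns (expected 12) at line ", which(nf != 12L)[1L])
  m <- do.call(rbind, parts)
  out <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                    stringsAsFactors = FALSE)
  num <- apply(m[, 3:12, drop = FALSE], 2L, as.numeric)
  if (!is.matrix(num)) num <- matrix(num, nrow = 1L)
  colnames(num) <- .SIMILARITY_COLS[3:12]
  cbind(out, as.data.frame(num))
}

#' Write similarity hits as a 12-column tab-separated table
#'
#' @param hits data.frame with the columns of [readSimilarityTab()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeSimilarityTab <- function(hits, path) {
  stopifnot(all(.SIMILARITY_COLS %in% names(hits)))
  df <- hits[, .SIMILARITY_COLS]
  df$evalue <- format(df$evalue, scientific = TRUE, digits = 3)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Plain GFF3 writer for simulator output (gene / mRNA / exon / CDS rows
# with ID/Parent attributes); read back by rtracklayer in readGff3().
writeGff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(paste(features$chrom, "pprscape", features$type,
                   features$start, features$end, ".", features$strand,
                   ifelse(features$type == "CDS", "0", "."),
                   features$attributes, sep = "\t"), con)
  invisible(path)
}
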