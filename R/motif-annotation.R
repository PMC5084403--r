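# Motif-level annotation: a PSSM scanner over the consensus library,
# E-value screening of externally computed domain hits, and the decision
# of which proteins qualify as PPR proteins.

# Log-odds PSSM (bits) of one consensus under epsilon-smoothing against
# a uniform 1/20 background: consensus residue log2((1-eps)/0.05),
# others log2((eps/19)/0.05).
.buildPssm <- function(cons, eps) {
  chars <- strsplit(cons, "")[[1]]
  L <- length(chars)
  m <- matrix(log2((eps / 19) / 0.05), nrow = 20L, ncol = L,
              dimnames = list(.AA20, NULL))
  m[cbind(match(chars, .AA20), seq_len(L))] <- log2((1 - eps) / 0.05)
  m
}

#' Scan a protein with per-class PSSMs
#'
#' Slides a log-odds position-specific scoring matrix for every motif
#' class in the library over the protein and reports, per class, the
#' non-overlapping local score maxima at or above `pssmScoreMin`.
#' Scanner hits carry bit scores and no E-value (their `evalue` is
#' `NA`); screening of scanner hits is therefore score-based.
#'
#' @param protein A protein sequence (character string, `AAString`, or a
#'   length-1 named `AAStringSet`); `X` residues match nothing.
#' @param library A [MotifLibrary].
#' @param params A [ScanParams].
#' @param proteinId Id recorded in the hits (defaults to the sequence
#'   name if present).
#' @return data.frame of motif hits (`protein_id`, `motif_class`,
#'   `start`, `end`, `score`, `evalue`), sorted by start. Proteins
#'   shorter than the shortest consensus yield zero rows.
#' @export
scanProteinPssm <- function(protein, library, params = ScanParams(),
                            proteinId = NULL) {
  if (is.null(proteinId))
    proteinId <- if (!is.null(names(protein))) names(protein)[1L]
                 else "protein"
  seqStr <- toupper(as.character(protein)[1L])
  res <- match(strsplit(seqStr, "")[[1]], .AA20)   # X and unknowns -> NA
  n <- length(res)
  hits <- list()
  for (cls in names(library@consensus)) {
    pssm <- .buildPssm(library@consensus[[cls]], library@epsilon[[cls]])
    L <- ncol(pssm)
    if (n < L) next
    nW <- n - L + 1L
    scores <- vapply(seq_len(nW), function(i) {
      idx <- res[i:(i + L - 1L)]
      ok <- !is.na(idx)
      if (!any(ok)) return(-Inf)
      sum(pssm[cbind(idx[ok], which(ok))])
    }, numeric(1))
    cand <- which(scores >= params@pssmScoreMin)
    if (!length(cand)) next
    cand <- cand[order(-scores[cand], cand)]
    kept <- integer(0)
    for (i in cand) {
      if (!length(kept) || all(abs(kept - i) >= L)) kept <- c(kept, i)
    }
    hits[[cls]] <- data.frame(protein_id = proteinId, motif_class = cls,
                              start = kept, end = kept + L - 1L,
                              score = scores[kept], evalue = NA_real_)
  }
  if (!length(hits))
    return(data.frame(protein_id = character(), motif_class = character(),
                      start = integer(), end = integer(),
                      score = numeric(), evalue = numeric()))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$start, out$motif_class), , drop = FALSE]
}

#' Screen motif hits at the permissive E-value threshold
#'
#' Removes hits with E-value above `screenEvalueMax` (default 10, the
#' permissive search threshold); scanner hits without an E-value pass.
#' The result is ordered by `(protein_id, start)` and the operation is
#' idempotent.
#'
#' @param hits Motif-hit data.frame ([readDomtblout()] /
#'   [scanProteinPssm()] columns).
#' @param params A [ScanParams].
#' @return The screened, sorted hit data.frame.
#' @export
filterHits <- function(hits, params = ScanParams()) {
  if (!nrow(hits)) return(hits)
  keep <- is.na(hits$evalue) | hits$evalue <= params@screenEvalueMax
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decide which proteins qualify as PPR proteins
#'
#' A protein qualifies if, after overlap resolution
#' ([chainArchitecture()]), it retains at least `minRepeatMotifs`
#' repeat-class (P/L/S/L2) motifs and carries at least one hit with
#' E-value below `confidentEvalueMax` (scanner hits, which have no
#' E-value, count as confident). Input hits are expected to be screened
#' by [filterHits()] already.
#'
#' @param hits Screened motif-hit data.frame covering any number of
#'   proteins.
#' @param params A [ScanParams].
#' @return Sorted character vector of qualifying protein ids.
#' @export
identifyPprProteins <- function(hits, params = ScanParams()) {
  if (!nrow(hits)) return(character(0))
  byProt <- split(hits, hits$protein_id)
  ok <- vapply(byProt, function(h) {
    confident <- any(is.na(h$evalue) | h$evalue < params@confidentEvalueMax)
    if (!confident) return(FALSE)
    arch <- chainArchitecture(h, params@overlapTolerance)
    sum(arch$motif_class %in% .REPEAT_CLASSES) >= params@minRepeatMotifs
  }, logical(1))
  sort(names(byProt)[ok])
}
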