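# Chaining motif hits into an ordered architecture and assigning the
# P/PLS subfamily, the PLS / E-E+ / DYW subgroup and auxiliary domains.

#' Chain motif hits into a non-overlapping ordered architecture
#'
#' Greedy selection in descending score order (ties broken by smaller
#' start, then motif class name): a hit is kept only if it overlaps
#' every already-kept hit by at most `overlapTolerance` residues. The
#' result is sorted by start, so it reads as the protein's N-to-C motif
#' architecture. The outcome is independent of the input row order.
#'
#' @param hits Motif hits of a single protein (screened).
#' @param overlapTolerance Maximum residue overlap between kept motifs.
#' @return data.frame of the kept hits, sorted by `start`.
#' @export
chainArchitecture <- function(hits, overlapTolerance = 3L) {
  if (!nrow(hits)) return(hits)
  if (length(unique(hits$protein_id)) > 1L)
    stop("chainArchitecture expects hits from a single protein")
  score <- hits$score
  score[is.na(score)] <- -Inf
  ord <- order(-score, hits$start, hits$motif_class)
  h <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    kept <- which(keep)
    if (!length(kept)) {
      keep[i] <- TRUE
      next
    }
    ov <- pmax(0L, pmin(h$end[kept], h$end[i]) -
                 pmax(h$start[kept], h$start[i]) + 1L)
    if (all(ov <= overlapTolerance)) keep[i] <- TRUE
  }
  out <- h[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign the P or PLS subfamily from an architecture
#'
#' A protein belongs to the PLS subfamily when its resolved architecture
#' contains at least one L, S or L2 repeat variant; pure-P repeat arrays
#' are subfamily P.
#'
#' @param arch A chained architecture ([chainArchitecture()]).
#' @return `"P"` or `"PLS"`.
#' @export
assignSubfamily <- function(arch) {
  nRepeat <- sum(arch$motif_class %in% .REPEAT_CLASSES)
  if (nRepeat == 0L)
    stop("architecture has no repeat-class (P/L/S/L2) motifs")
  if (any(arch$motif_class %in% c("L", "S", "L2"))) "PLS" else "P"
}

#' Assign the PLS-subfamily subgroup
#'
#' P-subfamily proteins have no subgroup (`"none"`). Within the PLS
#' subfamily the C-terminal domain content decides: a DYW motif gives
#' subgroup `"DYW"` (DYW precedence is absolute -- DYW proteins carry
#' E/E+ motifs upstream and remain DYW), otherwise an E or E+ motif
#' gives `"E/E+"`, otherwise `"PLS"`.
#'
#' @param arch A chained architecture.
#' @param subfamily `"P"` or `"PLS"` (from [assignSubfamily()]).
#' @return One of `"none"`, `"PLS"`, `"E/E+"`, `"DYW"`.
#' @export
assignSubgroup <- function(arch, subfamily) {
  if (subfamily == "P") return("none")
  if ("DYW" %in% arch$motif_class) return("DYW")
  if (any(arch$motif_class %in% c("E", "Eplus"))) return("E/E+")
  "PLS"
}

#' Detect auxiliary (non-repeat) domains among a protein's hits
#'
#' Reports the RRM, LAGLIDADG, SMR and `"other"` domain classes present
#' among the screened hits. Auxiliary domains are annotations on top of
#' the subfamily call, not subgroups: a P-class protein with an SMR
#' domain remains subfamily P.
#'
#' @param hits Screened motif hits of one protein.
#' @return Character vector (possibly empty) of auxiliary domain
#'   classes, sorted.
#' @export
detectAuxDomains <- function(hits) {
  sort(intersect(unique(hits$motif_class), .AUX_CLASSES))
}

#' Classify a set of proteins from their motif hits
#'
#' Runs chaining, subfamily, subgroup and auxiliary-domain assignment
#' per protein.
#'
#' @param hits Screened motif-hit data.frame (any number of proteins).
#' @param params A [ScanParams].
#' @return data.frame with one row per protein: `protein_id`,
#'   `subfamily`, `subgroup`, `aux_domains` (comma-joined, `""` if
#'   none), `n_motifs`.
#' @export
classifyProteins <- function(hits, params = ScanParams()) {
  if (!nrow(hits))
    return(data.frame(protein_id = character(), subfamily = character(),
                      subgroup = character(), aux_domains = character(),
                      n_motifs = integer()))
  byProt <- split(hits, hits$protein_id)
  rows <- lapply(names(byProt), function(id) {
    h <- byProt[[id]]
    arch <- chainArchitecture(h, params@overlapTolerance)
    subf <- assignSubfamily(arch)
    data.frame(protein_id = id, subfamily = subf,
               subgroup = assignSubgroup(arch, subf),
               aux_domains = paste(detectAuxDomains(h), collapse = ","),
               n_motifs = nrow(arch))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Family census by subfamily and subgroup
#'
#' Tallies subfamily calls into the census form used in family surveys:
#' total, P, PLS total, and the PLS / E-E+ / DYW subgroup counts. The
#' invariants `P + PLS_total == total` and
#' `PLS + EEplus + DYW == PLS_total` are enforced.
#'
#' @param calls data.frame of subfamily calls ([classifyProteins()]).
#' @param species Label for the census row.
#' @return One-row data.frame: `species`, `total`, `P`, `PLS_total`,
#'   `PLS`, `EEplus`, `DYW`.
#' @export
pprCensus <- function(calls, species = "species") {
  total <- nrow(calls)
  nP <- sum(calls$subfamily == "P")
  plsTotal <- sum(calls$subfamily == "PLS")
  nPls <- sum(calls$subgroup == "PLS")
  nE <- sum(calls$subgroup == "E/E+")
  nDyw <- sum(calls$subgroup == "DYW")
  stopifnot(nP + plsTotal == total, nPls + nE + nDyw == plsTotal)
  data.frame(species = species, total = total, P = nP,
             PLS_total = plsTotal, PLS = nPls, EEplus = nE, DYW = nDyw)
}
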