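# Nei-Gojobori (1986) Ka/Ks estimation: synonymous/nonsynonymous site
# counting, equal-weight pathway averaging of codon differences,
# Jukes-Cantor multiple-hit correction, and molecular-clock dating.

.codonEnv <- new.env(parent = emptyenv())

.NUCS <- c("A", "C", "G", "T")
.isTransition <- function(a, b)
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
  (a %in% c("C", "T") && b %in% c("C", "T"))

# Precomputed lookup tables over the 64 codons: amino acid, the 9
# single-nucleotide neighbours of each codon with synonymous/stop/
# transition flags, and NG86 site counts for the 61 sense codons.
.codonData <- function() {
  if (!is.null(.codonEnv$codons)) return(.codonEnv)
  codons <- as.vector(outer(outer(.NUCS, .NUCS, paste0), .NUCS, paste0))
  codons <- sort(codons)
  aa <- GENETIC_CODE[codons]
  idx <- setNames(seq_along(codons), codons)
  nbr <- array(NA_integer_, c(64L, 9L))      # neighbour codon index
  syn <- array(NA, c(64L, 9L))               # synonymous change?
  stp <- array(NA, c(64L, 9L))               # change creates a stop?
  tsn <- array(NA, c(64L, 9L))               # transition?
  for (i in seq_along(codons)) {
    cod <- strsplit(codons[i], "")[[1]]
    j <- 0L
    for (pos in 1:3) for (nt in setdiff(.NUCS, cod[pos])) {
      j <- j + 1L
      mut <- cod
      mut[pos] <- nt
      mutStr <- paste(mut, collapse = "")
      nbr[i, j] <- idx[[mutStr]]
      stp[i, j] <- aa[[mutStr]] == "*"
      syn[i, j] <- !stp[i, j] && aa[[mutStr]] == aa[[codons[i]]]
      tsn[i, j] <- .isTransition(cod[pos], nt)
    }
  }
  sense <- codons[aa != "*"]
  # per-codon synonymous sites: for each position, the fraction of the 3
  # possible changes that are synonymous (changes to stops count as
  # nonsynonymous), summed over positions.
  sSites <- setNames(vapply(sense, function(cdn) {
    i <- idx[[cdn]]
    sum(syn[i, ]) / 3
  }, numeric(1)), sense)
  .codonEnv$codons <- codons
  .codonEnv$aa <- aa
  .codonEnv$idx <- idx
  .codonEnv$nbr <- nbr
  .codonEnv$syn <- syn
  .codonEnv$stp <- stp
  .codonEnv$tsn <- tsn
  .codonEnv$sense <- sense
  .codonEnv$sSites <- sSites
  .codonEnv
}

.checkCodon <- function(codon) {
  cd <- .codonData()
  if (!codon %in% cd$codons)
    stop("not a valid codon: ", codon)
  if (cd$aa[[codon]] == "*")
    stop("stop codon not allowed: ", codon)
}

#' NG86 synonymous and nonsynonymous site counts of a codon
#'
#' For each of the nine single-nucleotide changes of a sense codon,
#' classifies the change as synonymous or nonsynonymous under the
#' standard genetic code (changes producing a stop codon count as
#' nonsynonymous). The synonymous site count `s` is the per-position
#' synonymous fraction summed over the three positions; `n = 3 - s`.
#'
#' @param codon A 3-letter sense codon, e.g. `"GGG"`.
#' @return Named numeric vector `c(s = , n = )` with `s + n == 3`.
#' @examples
#' ng86Sites("TTT")  # s = 1/3
#' ng86Sites("GGG")  # s = 1 (fourfold-degenerate third position)
#' @export
ng86Sites <- function(codon) {
  .checkCodon(codon)
  s <- .codonData()$sSites[[codon]]
  c(s = s, n = 3 - s)
}

# All orderings of positions 1..d (d <= 3), as a list of integer vectors.
.permutations <- function(d) {
  if (d == 1L) return(list(1L))
  if (d == 2L) return(list(c(1L, 2L), c(2L, 1L)))
  list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
       c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
}

#' NG86 pathway-averaged synonymous/nonsynonymous differences
#'
#' Counts synonymous and nonsynonymous differences between two sense
#' codons by averaging over all orderings of the single-nucleotide steps
#' connecting them (NG86 equal-weight pathway averaging). Pathways that
#' pass through a stop codon are excluded; if every pathway does, the
#' average is taken over all pathways anyway, with steps into or out of a
#' stop counted as nonsynonymous.
#'
#' @param codonA,codonB 3-letter sense codons.
#' @return Named numeric vector `c(sd = , nd = )`; `sd + nd` equals the
#'   number of differing positions.
#' @examples
#' ng86Differences("TTT", "TTC")  # c(sd = 1, nd = 0)
#' ng86Differences("TTT", "GTA")  # c(sd = 0.5, nd = 1.5)
#' @export
ng86Differences <- function(codonA, codonB) {
  .checkCodon(codonA)
  .checkCodon(codonB)
  if (codonA == codonB) return(c(sd = 0, nd = 0))
  cd <- .codonData()
  a <- strsplit(codonA, "")[[1]]
  b <- strsplit(codonB, "")[[1]]
  diffPos <- which(a != b)
  d <- length(diffPos)
  paths <- .permutations(d)
  res <- lapply(paths, function(ord) {
    cur <- a
    sd <- 0
    nd <- 0
    viaStop <- FALSE
    for (p in diffPos[ord]) {
      nxt <- cur
      nxt[p] <- b[p]
      aaCur <- cd$aa[[paste(cur, collapse = "")]]
      aaNxt <- cd$aa[[paste(nxt, collapse = "")]]
      if (aaNxt == "*" && !identical(paste(nxt, collapse = ""), codonB))
        viaStop <- TRUE
      if (aaCur == aaNxt && aaNxt != "*") sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd, viaStop = as.numeric(viaStop))
  })
  m <- do.call(rbind, res)
  ok <- m[, "viaStop"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, "sd"]), nd = mean(m[ok, "nd"]))
}

#' Jukes-Cantor distance correction
#'
#' Converts an observed proportion of differences per site into an
#' estimated number of substitutions per site,
#' `d = -(3/4) * log(1 - 4p/3)`. Proportions at or beyond the 0.75
#' saturation boundary have no finite corrected distance and return
#' `NA`.
#'
#' @param p Observed proportion of differing sites (`>= 0`).
#' @return Corrected distance, or `NA_real_` when `p >= 0.75`
#'   (saturated).
#' @examples
#' jcCorrect(0)    # 0
#' jcCorrect(0.1)  # 0.107326
#' @export
jcCorrect <- function(p) {
  if (any(p < 0)) stop("proportion must be >= 0")
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Global protein alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine
#' gaps (open 10, extend 0.5), the classical parameterization of
#' ClustalW-style pairwise protein alignment.
#'
#' @param p1,p2 Protein sequences (character strings or `AAString`).
#' @param gapOpen,gapExtend Affine gap penalties.
#' @return List with elements `a`, `b` (aligned strings of equal length,
#'   gaps as `-`) and `score`.
#' @export
alignProteins <- function(p1, p2, gapOpen = 10, gapExtend = 0.5) {
  p1 <- as.character(p1)
  p2 <- as.character(p2)
  if (!nzchar(p1) || !nzchar(p2)) stop("cannot align an empty sequence")
  aln <- pairwiseAlignment(AAStringSet(p1), AAStringSet(p2),
                           type = "global",
                           substitutionMatrix = "BLOSUM62",
                           gapOpening = gapOpen, gapExtension = gapExtend)
  list(a = as.character(alignedPattern(aln)),
       b = as.character(alignedSubject(aln)),
       score = BiocGenerics::score(aln))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps each aligned residue column back to the codon that encodes it
#' (PAL2NAL-style). Columns containing a gap in either sequence are
#' dropped, as are columns where either codon is a stop. A terminal stop
#' codon on either CDS is trimmed before checking that the CDS
#' translation equals the ungapped protein.
#'
#' @param alnA,alnB Aligned protein strings of equal length (gaps `-`).
#' @param cdsA,cdsB Coding sequences of the two proteins.
#' @return data.frame with columns `codon_a`, `codon_b`, one row per
#'   retained codon column.
#' @export
backtranslate <- function(alnA, alnB, cdsA, cdsB) {
  if (nchar(alnA) != nchar(alnB))
    stop("aligned sequences must have equal length")
  prep <- function(aln, cds, label) {
    cds <- toupper(as.character(cds))
    if (nchar(cds) %% 3L != 0L)
      stop("CDS length of ", label, " not divisible by 3")
    codons <- substring(cds, seq(1L, nchar(cds), 3L),
                        seq(3L, nchar(cds), 3L))
    aaAll <- GENETIC_CODE[codons]
    if (aaAll[length(aaAll)] == "*") {
      codons <- codons[-length(codons)]
      aaAll <- aaAll[-length(aaAll)]
    }
    prot <- gsub("-", "", aln, fixed = TRUE)
    if (length(codons) != nchar(prot))
      stop(label, ": CDS encodes ", length(codons),
           " residues but protein has ", nchar(prot))
    protChars <- strsplit(prot, "")[[1]]
    mismatch <- which(aaAll != protChars)
    if (length(mismatch))
      stop(label, ": CDS translation differs from protein at residue ",
           mismatch[1L], " (", aaAll[mismatch[1L]], " vs ",
           protChars[mismatch[1L]], ")")
    codons
  }
  codA <- prep(alnA, cdsA, "sequence A")
  codB <- prep(alnB, cdsB, "sequence B")
  colsA <- strsplit(alnA, "")[[1]]
  colsB <- strsplit(alnB, "")[[1]]
  ia <- cumsum(colsA != "-")
  ib <- cumsum(colsB != "-")
  keep <- colsA != "-" & colsB != "-"
  ca <- codA[ia[keep]]
  cb <- codB[ib[keep]]
  aa <- GENETIC_CODE[ca]
  ab <- GENETIC_CODE[cb]
  ok <- aa != "*" & ab != "*"
  data.frame(codon_a = ca[ok], codon_b = cb[ok])
}

#' Compute NG86 Ka, Ks and omega for a codon alignment
#'
#' Site counts are averaged over the two sequences; synonymous and
#' nonsynonymous differences are summed over columns with pathway
#' averaging ([ng86Differences()]); proportions are Jukes-Cantor
#' corrected. `omega = Ka/Ks` is defined only when both distances are
#' unsaturated and `Ks > 0`.
#'
#' @param aln A codon alignment as returned by [backtranslate()] (columns
#'   `codon_a`, `codon_b`).
#' @param pairId Identifier copied into the result row.
#' @param keepSaturated If `TRUE`, saturated proportions (`p >= 0.75`)
#'   fall back to the uncorrected proportion instead of being flagged
#'   invalid, mimicking published pipelines that retain heavily
#'   saturated duplicate pairs.
#' @return One-row data.frame: `pair_id`, `n_codons`, `S_sites`,
#'   `N_sites`, `Sd`, `Nd`, `ps`, `pn`, `Ks`, `Ka`, `omega`, `ks_valid`,
#'   `ka_valid`, `omega_reason`.
#' @export
computeKaKs <- function(aln, pairId = "pair", keepSaturated = FALSE) {
  if (!nrow(aln)) stop("empty codon alignment")
  cd <- .codonData()
  sA <- sum(cd$sSites[aln$codon_a])
  sB <- sum(cd$sSites[aln$codon_b])
  if (anyNA(c(sA, sB))) stop("alignment contains a stop or invalid codon")
  S <- (sA + sB) / 2
  N <- 3 * nrow(aln) - S
  diffs <- mapply(function(a, b) ng86Differences(a, b),
                  aln$codon_a, aln$codon_b)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ksValid <- ps < 0.75
  kaValid <- pn < 0.75
  Ks <- if (ksValid) jcCorrect(ps) else if (keepSaturated) ps else NA_real_
  Ka <- if (kaValid) jcCorrect(pn) else if (keepSaturated) pn else NA_real_
  if (keepSaturated) {
    ksValid <- TRUE
    kaValid <- TRUE
  }
  if (!ksValid || !kaValid) {
    omega <- NA_real_
    reason <- "saturated"
  } else if (Ks <= 0) {
    omega <- NA_real_
    reason <- "Ks is zero"
  } else {
    omega <- Ka / Ks
    reason <- ""
  }
  data.frame(pair_id = pairId, n_codons = nrow(aln),
             S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
             ps = ps, pn = pn, Ks = Ks, Ka = Ka, omega = omega,
             ks_valid = ksValid, ka_valid = kaValid,
             omega_reason = reason)
}

#' Date a duplication event from its synonymous divergence
#'
#' Applies the molecular clock `T = Ks / (2 * lambda)`, reported in
#' million years (Mya). The default clock rate, 6.5e-9 synonymous
#' substitutions per site per year, is the conventional rate for grasses.
#'
#' @param ks Synonymous substitutions per synonymous site (may be a
#'   vector; `NA` propagates).
#' @param lambda Clock rate in synonymous substitutions/site/year.
#' @return Time since duplication in Mya.
#' @examples
#' estimateTime(0.13)  # 10 Mya
#' estimateTime(5.81)  # ~446.9 Mya
#' @export
estimateTime <- function(ks, lambda = 6.5e-9) {
  if (lambda <= 0) stop("lambda must be positive")
  if (any(ks < 0, na.rm = TRUE)) stop("Ks must be >= 0")
  ks / (2 * lambda) / 1e6
}

#' Summarize Ka/Ks results for a duplication group
#'
#' Arithmetic means of Ka, Ks, omega and per-pair duplication times over
#' pairs with valid estimates; pairs with saturated or undefined
#' estimates are counted as excluded. The mean time is the mean of the
#' per-pair times, not the time of the mean Ks (the two differ on skewed
#' Ks distributions).
#'
#' @param results data.frame of rows from [computeKaKs()].
#' @param group Label for the group (e.g. `"tandem"`, `"segmental"`).
#' @param lambda Clock rate passed to [estimateTime()].
#' @return One-row data.frame: `group`, `n_pairs`, `n_valid_ks`,
#'   `n_valid_omega`, `n_excluded`, `mean_ka`, `mean_ks`, `mean_omega`,
#'   `mean_time_mya`.
#' @export
summarizePairs <- function(results, group = "all", lambda = 6.5e-9) {
  okKs <- !is.na(results$Ks) & results$ks_valid
  okOm <- !is.na(results$omega)
  meanOr <- function(x) if (length(x)) mean(x) else NA_real_
  data.frame(group = group,
             n_pairs = nrow(results),
             n_valid_ks = sum(okKs),
             n_valid_omega = sum(okOm),
             n_excluded = sum(!okKs),
             mean_ka = meanOr(results$Ka[!is.na(results$Ka) &
                                           results$ka_valid]),
             mean_ks = meanOr(results$Ks[okKs]),
             mean_omega = meanOr(results$omega[okOm]),
             mean_time_mya = meanOr(estimateTime(results$Ks[okKs],
                                                 lambda)))
}

#' Full Ka/Ks workflow for a set of gene pairs
#'
#' For each pair: align the two proteins ([alignProteins()]),
#' back-translate to codons ([backtranslate()]) and estimate NG86
#' Ka/Ks ([computeKaKs()]).
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param proteins Named protein sequences (`AAStringSet` or character).
#' @param cds Named coding sequences (`DNAStringSet` or character).
#' @param keepSaturated Passed to [computeKaKs()].
#' @return data.frame with one [computeKaKs()] row per pair.
#' @export
kaksPipeline <- function(pairs, proteins, cds, keepSaturated = FALSE) {
  proteins <- setNames(as.character(proteins), names(proteins))
  cds <- setNames(as.character(cds), names(cds))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]
    b <- pairs$gene_b[i]
    if (!a %in% names(proteins) || !b %in% names(proteins))
      stop("missing protein sequence for pair ", a, "/", b)
    if (!a %in% names(cds) || !b %in% names(cds))
      stop("missing CDS for pair ", a, "/", b)
    aln <- alignProteins(proteins[[a]], proteins[[b]])
    codAln <- backtranslate(aln$a, aln$b, cds[[a]], cds[[b]])
    computeKaKs(codAln, pairId = paste(a, b, sep = "|"),
                keepSaturated = keepSaturated)
  })
  do.call(rbind, rows)
}
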