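# Independent brute-force oracles for the NG86 machinery. These work
# directly from Biostrings::GENETIC_CODE with naive enumeration and are
# kept structurally separate from the package implementation.

oracleNucs <- c("A", "C", "G", "T")
oracleCode <- Biostrings::GENETIC_CODE

oracleNeighbours <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) for (nt in setdiff(oracleNucs, chars[pos])) {
    mut <- chars
    mut[pos] <- nt
    out <- c(out, paste(mut, collapse = ""))
  }
  out
}

# synonymous site count: fraction of the 9 single-nt changes that keep
# the amino acid (stops count as nonsynonymous)
oracleSites <- function(codon) {
  nb <- oracleNeighbours(codon)
  syn <- sum(oracleCode[nb] == oracleCode[codon] & oracleCode[nb] != "*")
  s <- syn / 3
  c(s = s, n = 3 - s)
}

# pathway-averaged differences: enumerate every ordering of the
# differing positions; drop orderings whose intermediate codons are
# stops, averaging over all orderings when none survive
oracleDifferences <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  dp <- which(a != b)
  if (!length(dp)) return(c(sd = 0, nd = 0))
  perms <- if (length(dp) == 1L) list(dp)
  else if (length(dp) == 2L) list(dp, rev(dp))
  else {
    idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    lapply(idx, function(i) dp[i])
  }
  tally <- lapply(perms, function(ord) {
    cur <- a
    sd <- 0; nd <- 0; bad <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      curStr <- paste(cur, collapse = "")
      nxtStr <- paste(nxt, collapse = "")
      if (oracleCode[[nxtStr]] == "*" && nxtStr != cb) bad <- TRUE
      if (oracleCode[[curStr]] == oracleCode[[nxtStr]] &&
          oracleCode[[nxtStr]] != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, bad = bad)
  })
  ok <- !vapply(tally, `[[`, logical(1), "bad")
  if (!any(ok)) ok <- rep(TRUE, length(tally))
  c(sd = mean(vapply(tally[ok], `[[`, numeric(1), "sd")),
    nd = mean(vapply(tally[ok], `[[`, numeric(1), "nd")))
}

oracleSenseCodons <- function() {
  all <- as.vector(outer(outer(oracleNucs, oracleNucs, paste0),
                         oracleNucs, paste0))
  sort(all[oracleCode[all] != "*"])
}

# column-by-column Ka/Ks oracle over a codon alignment
oracleKaKs <- function(codA, codB) {
  sA <- sum(vapply(codA, function(c) oracleSites(c)[["s"]], numeric(1)))
  sB <- sum(vapply(codB, function(c) oracleSites(c)[["s"]], numeric(1)))
  S <- (sA + sB) / 2
  N <- 3 * length(codA) - S
  d <- mapply(function(x, y) oracleDifferences(x, y), codA, codB)
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ks = jc(ps), Ka = jc(pn))
}

randomSenseCodons <- function(n) {
  sense <- oracleSenseCodons()
  sense[sample.int(length(sense), n, replace = TRUE)]
}

splitCodons <- function(cds)
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
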