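# Duplication analysis: tandem arrays by the < 100 kb rule, segmental
# duplications via top-hit filtering plus collinear-block chaining,
# reciprocal-best-hit orthologs, and per-chromosome synteny tables.

#' Detect tandem arrays of PPR genes
#'
#' Per chromosome, genes are sorted by start and consecutive genes whose
#' intergenic gap (`next start - previous end - 1`) is strictly below
#' `maxGap` (default 100 kb) are linked regardless of strand -- tandem
#' copies occur in the same or inverse orientation. Maximal linked runs
#' of two or more genes become arrays; runs larger than seven are kept
#' whole and flagged `oversize` (the 2-7 range seen in real families is
#' an observation, not a rule). Arrays partition their members.
#'
#' @param genes PPR genes: a [GeneModels] object or a gene table with
#'   `gene_id`, `chrom`, `start`, `end`.
#' @param maxGap Intergenic-gap threshold in bp (strict `<`).
#' @return data.frame with one row per array member: `array_id`,
#'   `chrom`, `gene_id`, `position_in_array`, `size`, `oversize`.
#' @export
findTandemArrays <- function(genes, maxGap = 100000) {
  tab <- .geneTable(genes)
  empty <- data.frame(array_id = character(), chrom = character(),
                      gene_id = character(), position_in_array = integer(),
                      size = integer(), oversize = logical())
  if (!nrow(tab)) return(empty)
  out <- list()
  nArr <- 0L
  for (ch in sort(unique(tab$chrom))) {
    g <- tab[tab$chrom == ch, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) < 2L) next
    gap <- g$start[-1L] - g$end[-nrow(g)] - 1L
    linked <- gap < maxGap
    runStart <- 1L
    flush <- function(from, to) {
      if (to - from + 1L < 2L) return()
      nArr <<- nArr + 1L
      size <- to - from + 1L
      out[[nArr]] <<- data.frame(
        array_id = sprintf("TA%03d", nArr), chrom = ch,
        gene_id = g$gene_id[from:to],
        position_in_array = seq_len(size),
        size = size, oversize = size > 7L)
    }
    for (i in seq_along(linked)) {
      if (!linked[i]) {
        flush(runStart, i)
        runStart <- i + 1L
      }
    }
    flush(runStart, nrow(g))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Candidate duplicate pairs by top-hit filtering
#'
#' Mirrors the published screen for segmental duplicates: per query,
#' self-hits are removed, hits are ranked by ascending E-value (ties by
#' descending bit score, then subject id), the top `k` subjects are
#' retained and those with E-value below `evalueMax` survive. The pair
#' set is then symmetrized: an unordered pair is kept if either
#' direction qualifies. Output is invariant under input row permutation.
#'
#' @param hits Similarity hits ([readSimilarityTab()] columns).
#' @param k Number of top matches retained per query (default 5).
#' @param evalueMax E-value ceiling (strict `<`, default 1e-5).
#' @return data.frame of unordered candidate pairs: `gene_a`, `gene_b`
#'   (`gene_a < gene_b`), `evalue` (best qualifying direction), sorted.
#' @export
topHitsFilter <- function(hits, k = 5L, evalueMax = 1e-5) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      evalue = numeric())
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (!nrow(h)) return(empty)
  h <- h[order(h$query_id, h$evalue, -h$bitscore, h$subject_id), ,
         drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(h)), h$query_id),
                        function(i) head(i, k)), use.names = FALSE)
  h <- h[keep, , drop = FALSE]
  h <- h[h$evalue < evalueMax, , drop = FALSE]
  if (!nrow(h)) return(empty)
  a <- pmin(h$query_id, h$subject_id)
  b <- pmax(h$query_id, h$subject_id)
  key <- paste(a, b, sep = "\r")
  ev <- tapply(h$evalue, key, min)
  parts <- strsplit(names(ev), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, character(1), 1L),
                    gene_b = vapply(parts, `[`, character(1), 2L),
                    evalue = as.numeric(ev))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ordinal gene ranks per chromosome
#'
#' Assigns each gene its ordinal position along its chromosome (sorted
#' by start), the coordinate system used for collinearity chaining.
#'
#' @param genes A [GeneModels] object or gene table.
#' @return data.frame `gene_id`, `chrom`, `rank`.
#' @export
geneRanks <- function(genes) {
  tab <- .geneTable(genes)
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  res <- data.frame(gene_id = tab$gene_id, chrom = tab$chrom)
  res$rank <- as.integer(stats::ave(seq_len(nrow(tab)), tab$chrom,
                                    FUN = seq_along))
  res
}

# Annotate unordered gene pairs with chromosome and rank on both sides,
# canonicalized so chrom_a <= chrom_b (rank_a <= rank_b within a
# chromosome).
.annotatePairs <- function(pairs, ranks) {
  idx <- match(pairs$gene_a, ranks$gene_id)
  jdx <- match(pairs$gene_b, ranks$gene_id)
  if (anyNA(idx) || anyNA(jdx))
    stop("pair gene(s) missing from the rank table")
  out <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    chrom_a = ranks$chrom[idx], rank_a = ranks$rank[idx],
                    chrom_b = ranks$chrom[jdx], rank_b = ranks$rank[jdx])
  swap <- out$chrom_a > out$chrom_b |
    (out$chrom_a == out$chrom_b & out$rank_a > out$rank_b)
  if (any(swap)) {
    tmp <- out[swap, ]
    out[swap, c("gene_a", "chrom_a", "rank_a")] <-
      tmp[, c("gene_b", "chrom_b", "rank_b")]
    out[swap, c("gene_b", "chrom_b", "rank_b")] <-
      tmp[, c("gene_a", "chrom_a", "rank_a")]
  }
  out
}

# Longest strictly monotone chain under a rank-gap cap on both axes;
# O(n^2) dynamic program. Returns indices into the anchor subset.
.longestChain <- function(ra, rb, maxGap, decreasing) {
  n <- length(ra)
  ord <- order(ra, if (decreasing) -rb else rb)
  ra <- ra[ord]
  rb <- rb[ord]
  len <- rep(1L, n)
  prev <- rep(0L, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      da <- ra[j] - ra[i]
      db <- if (decreasing) rb[i] - rb[j] else rb[j] - rb[i]
      if (da > 0L && da <= maxGap && db > 0L && db <= maxGap &&
          len[i] + 1L > len[j]) {
        len[j] <- len[i] + 1L
        prev[j] <- i
      }
    }
  }
  best <- which.max(len)
  chain <- integer(0)
  while (best != 0L) {
    chain <- c(best, chain)
    best <- prev[best]
  }
  ord[chain]
}

#' Detect collinear blocks from homologous anchor pairs
#'
#' Per chromosome pair, anchors are chained by the longest strictly
#' monotone subsequence of gene ranks (run both increasing and
#' decreasing on the target axis) with consecutive-anchor rank gaps of
#' at most `maxRankGap` on both axes. Chains with at least `minAnchors`
#' anchors become blocks; anchors consumed by a block are removed before
#' searching for further blocks. Anchor ranks within a block are
#' strictly monotone by construction.
#'
#' @param pairs Unordered homologous gene pairs (`gene_a`, `gene_b`),
#'   e.g. from [topHitsFilter()] over all genes.
#' @param ranks Gene rank table from [geneRanks()].
#' @param minAnchors Minimum anchors per block (default 5).
#' @param maxRankGap Maximum rank gap between consecutive anchors
#'   (default 25).
#' @return List with `blocks` (data.frame `block_id`, `chrom_a`,
#'   `chrom_b`, `orientation`, `n_anchors`, `a_min`, `a_max`, `b_min`,
#'   `b_max`) and `anchors` (the annotated pairs with their `block_id`,
#'   `NA` for unchained anchors).
#' @export
detectCollinearBlocks <- function(pairs, ranks, minAnchors = 5L,
                                  maxRankGap = 25L) {
  ann <- .annotatePairs(pairs, ranks)
  ann$block_id <- NA_character_
  blocks <- list()
  nBlk <- 0L
  for (key in unique(paste(ann$chrom_a, ann$chrom_b, sep = "\r"))) {
    sel <- which(paste(ann$chrom_a, ann$chrom_b, sep = "\r") == key &
                   is.na(ann$block_id))
    repeat {
      avail <- sel[is.na(ann$block_id[sel])]
      if (length(avail) < minAnchors) break
      inc <- .longestChain(ann$rank_a[avail], ann$rank_b[avail],
                           maxRankGap, decreasing = FALSE)
      dec <- .longestChain(ann$rank_a[avail], ann$rank_b[avail],
                           maxRankGap, decreasing = TRUE)
      useDec <- length(dec) > length(inc)
      chain <- avail[if (useDec) dec else inc]
      if (length(chain) < minAnchors) break
      nBlk <- nBlk + 1L
      id <- sprintf("CB%03d", nBlk)
      ann$block_id[chain] <- id
      blocks[[nBlk]] <- data.frame(
        block_id = id,
        chrom_a = ann$chrom_a[chain[1L]],
        chrom_b = ann$chrom_b[chain[1L]],
        orientation = if (useDec) "inverted" else "same",
        n_anchors = length(chain),
        a_min = min(ann$rank_a[chain]), a_max = max(ann$rank_a[chain]),
        b_min = min(ann$rank_b[chain]), b_max = max(ann$rank_b[chain]))
    }
  }
  blockDf <- if (length(blocks)) do.call(rbind, blocks)
  else data.frame(block_id = character(), chrom_a = character(),
                  chrom_b = character(), orientation = character(),
                  n_anchors = integer(), a_min = integer(),
                  a_max = integer(), b_min = integer(), b_max = integer())
  list(blocks = blockDf, anchors = ann)
}

#' Call segmental duplicate pairs from candidates and collinear blocks
#'
#' A candidate pair is called segmental when both genes lie within the
#' rank span of one collinear block on their respective chromosomes.
#' Pairs whose genes are co-members of one tandem array are excluded:
#' tandem takes precedence, so the tandem and segmental sets are
#' disjoint.
#'
#' @param candidates Candidate pairs from [topHitsFilter()].
#' @param blocks Block table from [detectCollinearBlocks()]`$blocks`.
#' @param ranks Gene rank table from [geneRanks()].
#' @param tandemArrays Optional tandem-array membership from
#'   [findTandemArrays()].
#' @return data.frame of duplicate pairs: `gene_a`, `gene_b`,
#'   `dup_type` (`"segmental"`), `evalue`, `block_id`.
#' @export
callSegmentalPairs <- function(candidates, blocks, ranks,
                               tandemArrays = NULL) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      dup_type = character(), evalue = numeric(),
                      block_id = character())
  if (!nrow(candidates) || !nrow(blocks)) return(empty)
  ann <- .annotatePairs(candidates, ranks)   # preserves row order
  ann$evalue <- if ("evalue" %in% names(candidates)) candidates$evalue
                else NA_real_
  if (!is.null(tandemArrays) && nrow(tandemArrays)) {
    arr <- setNames(tandemArrays$array_id, tandemArrays$gene_id)
    co <- !is.na(arr[ann$gene_a]) & !is.na(arr[ann$gene_b]) &
      arr[ann$gene_a] == arr[ann$gene_b]
    ann <- ann[!co, , drop = FALSE]
  }
  if (!nrow(ann)) return(empty)
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    p <- ann[i, ]
    hit <- blocks[
      (blocks$chrom_a == p$chrom_a & blocks$chrom_b == p$chrom_b &
         p$rank_a >= blocks$a_min & p$rank_a <= blocks$a_max &
         p$rank_b >= blocks$b_min & p$rank_b <= blocks$b_max) |
        (blocks$chrom_a == p$chrom_b & blocks$chrom_b == p$chrom_a &
           p$rank_b >= blocks$a_min & p$rank_b <= blocks$a_max &
           p$rank_a >= blocks$b_min & p$rank_a <= blocks$b_max), ,
      drop = FALSE]
    if (!nrow(hit)) return(NULL)
    data.frame(gene_a = p$gene_a, gene_b = p$gene_b,
               dup_type = "segmental", evalue = p$evalue,
               block_id = hit$block_id[1L])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reciprocal-best-hit ortholog pairs
#'
#' A pair `(a, b)` is orthologous when `b` is `a`'s best hit in the
#' A-to-B search and `a` is `b`'s best hit in the B-to-A search, both
#' with E-value below `evalueMax`. Best hits are chosen by lowest
#' E-value, ties by highest bit score, then subject id.
#'
#' @param hitsAb,hitsBa Similarity hits for the two search directions.
#' @param evalueMax E-value ceiling (strict `<`, default 1e-5).
#' @return data.frame `gene_a`, `gene_b`, `evalue_ab`, `evalue_ba`.
#' @export
rbhOrthologs <- function(hitsAb, hitsBa, evalueMax = 1e-5) {
  best <- function(h) {
    h <- h[h$query_id != h$subject_id & h$evalue < evalueMax, ,
           drop = FALSE]
    if (!nrow(h))
      return(data.frame(query_id = character(), subject_id = character(),
                        evalue = numeric()))
    h <- h[order(h$query_id, h$evalue, -h$bitscore, h$subject_id), ,
           drop = FALSE]
    h[!duplicated(h$query_id), c("query_id", "subject_id", "evalue"),
      drop = FALSE]
  }
  ab <- best(hitsAb)
  ba <- best(hitsBa)
  baMap <- setNames(ba$subject_id, ba$query_id)
  baEv <- setNames(ba$evalue, ba$query_id)
  mutual <- !is.na(baMap[ab$subject_id]) &
    baMap[ab$subject_id] == ab$query_id
  out <- data.frame(gene_a = ab$query_id[mutual],
                    gene_b = ab$subject_id[mutual],
                    evalue_ab = ab$evalue[mutual],
                    evalue_ba = unname(baEv[ab$subject_id[mutual]]))
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-chromosome synteny table from ortholog pairs
#'
#' For each source chromosome, the percentage of its mapped genes whose
#' ortholog lies on each target chromosome (two decimals; rows sum to
#' 100 within rounding over mapped genes).
#'
#' @param orthologs Ortholog pairs (`gene_a`, `gene_b`), e.g. from
#'   [rbhOrthologs()].
#' @param chromA,chromB Named character vectors mapping gene ids to
#'   chromosomes in the source and target species.
#' @return data.frame `source_chrom`, `target_chrom`, `n`, `percentage`.
#' @export
syntenyTable <- function(orthologs, chromA, chromB) {
  empty <- data.frame(source_chrom = character(),
                      target_chrom = character(), n = integer(),
                      percentage = numeric())
  if (!nrow(orthologs)) return(empty)
  src <- chromA[orthologs$gene_a]
  tgt <- chromB[orthologs$gene_b]
  if (anyNA(src) || anyNA(tgt))
    stop("every ortholog gene must have a chromosome assignment")
  rows <- list()
  for (ch in sort(unique(src))) {
    counts <- table(tgt[src == ch])
    rows[[ch]] <- data.frame(source_chrom = ch,
                             target_chrom = names(counts),
                             n = as.integer(counts),
                             percentage = categoryPercentage(
                               as.integer(counts), sum(counts)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
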