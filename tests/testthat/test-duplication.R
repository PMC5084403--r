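test_that("tandem linking uses the strict 100 kb intergenic-gap rule", {
  g <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                  start = c(10000, 50000, 200000),
                  end = c(12000, 52000, 202000))
  arr <- findTandemArrays(g)
  # gaps: 37,999 (linked) and 147,999 (not)
  expect_identical(sort(arr$gene_id), c("g1", "g2"))
  expect_identical(unique(arr$size), 2L)

  # a gap of exactly 100,000 does not link
  g2 <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                   start = c(1, 112001), end = c(12000, 113000))
  expect_identical(nrow(findTandemArrays(g2)), 0L)
  g3 <- g2
  g3$start[2] <- 112000   # gap 99,999 < 100,000
  expect_identical(nrow(findTandemArrays(g3)), 2L)
})

test_that("oversized tandem runs are kept whole and flagged", {
  g <- data.frame(gene_id = sprintf("g%d", 1:8), chrom = "chr2",
                  start = seq(1, by = 2000, length.out = 8),
                  end = seq(1000, by = 2000, length.out = 8))
  arr <- findTandemArrays(g)
  expect_identical(unique(arr$size), 8L)
  expect_true(all(arr$oversize))
  expect_identical(length(unique(arr$array_id)), 1L)
  # arrays partition their members
  expect_identical(anyDuplicated(arr$gene_id), 0L)
})

test_that("top-hit filtering applies rank then E-value, symmetrized", {
  ev <- c(1e-50, 1e-40, 1e-30, 1e-20, 1e-10, 1e-7, 1e-3)
  hits <- do.call(rbind, lapply(seq_along(ev), function(i)
    mkSim("q", sprintf("s%d", i), ev[i])))
  hits <- rbind(hits, mkSim("q", "q", 0))   # self-hit is dropped
  out <- topHitsFilter(hits)
  # top 5 by E-value, all below 1e-5
  expect_identical(out$gene_b, sprintf("s%d", 1:5))

  # only a self-hit: nothing
  expect_identical(nrow(topHitsFilter(mkSim("x", "x", 0))), 0L)

  # symmetrization: qualifying in one direction is enough
  asym <- rbind(mkSim("a", "b", 1e-20),
                mkSim("b", "a", 1e-3))
  out2 <- topHitsFilter(asym)
  expect_identical(nrow(out2), 1L)
  expect_identical(out2$gene_a, "a")
  expect_equal(out2$evalue, 1e-20)

  # row-permutation invariance
  set.seed(4)
  big <- do.call(rbind, lapply(1:30, function(i)
    mkSim(sprintf("g%d", sample(10, 1)), sprintf("g%d", sample(10, 1)),
          10^-sample(2:40, 1), bitscore = sample(50:500, 1))))
  expect_identical(topHitsFilter(big),
                   topHitsFilter(big[sample(nrow(big)), ]))
})

test_that("collinear chains need monotone ranks and enough anchors", {
  ranks <- data.frame(
    gene_id = c(sprintf("a%d", 1:6), sprintf("b%d", 1:6)),
    chrom = rep(c("chr1", "chr2"), each = 6),
    rank = rep(1:6, 2))
  pairs <- data.frame(gene_a = sprintf("a%d", 1:6),
                      gene_b = sprintf("b%d", 1:6))
  res <- detectCollinearBlocks(pairs, ranks)
  expect_identical(nrow(res$blocks), 1L)
  expect_identical(res$blocks$orientation, "same")
  expect_identical(res$blocks$n_anchors, 6L)

  # reversed target ranks: one inverted block
  pairsRev <- data.frame(gene_a = sprintf("a%d", 1:6),
                         gene_b = sprintf("b%d", 6:1))
  resRev <- detectCollinearBlocks(pairsRev, ranks)
  expect_identical(resRev$blocks$orientation, "inverted")
  expect_identical(resRev$blocks$n_anchors, 6L)

  # four anchors fall below the default minimum of five
  res4 <- detectCollinearBlocks(pairs[1:4, ], ranks)
  expect_identical(nrow(res4$blocks), 0L)

  # anchor ranks inside a block are strictly monotone
  ann <- res$anchors[!is.na(res$anchors$block_id), ]
  ann <- ann[order(ann$rank_a), ]
  expect_true(all(diff(ann$rank_a) > 0))
  expect_true(all(diff(ann$rank_b) > 0))
})

test_that("segmental calls need block coverage; tandem takes precedence", {
  ranks <- data.frame(
    gene_id = c(sprintf("a%d", 1:8), sprintf("b%d", 1:8)),
    chrom = rep(c("chr1", "chr2"), each = 8),
    rank = rep(1:8, 2))
  pairs <- data.frame(gene_a = sprintf("a%d", 1:6),
                      gene_b = sprintf("b%d", 1:6))
  blocks <- detectCollinearBlocks(pairs, ranks)$blocks

  cand <- data.frame(gene_a = c("a3", "a7"), gene_b = c("b3", "b7"),
                     evalue = 1e-30)
  seg <- callSegmentalPairs(cand, blocks, ranks)
  # a3/b3 is inside the block span, a7/b7 is not
  expect_identical(seg$gene_a, "a3")
  expect_identical(seg$dup_type, "segmental")
  expect_identical(seg$block_id, blocks$block_id[1])

  tarr <- data.frame(array_id = "TA001", chrom = "chr1",
                     gene_id = c("a3", "b3"), position_in_array = 1:2,
                     size = 2L, oversize = FALSE)
  segEx <- callSegmentalPairs(cand, blocks, ranks, tandemArrays = tarr)
  expect_identical(nrow(segEx), 0L)
})

test_that("reciprocal best hits require mutual best and the threshold", {
  ab <- rbind(mkSim("a1", "b1", 1e-40, 400),
              mkSim("a1", "b2", 1e-20, 200),
              mkSim("a2", "b2", 1e-30, 300),
              mkSim("a3", "b3", 1e-3, 50))
  ba <- rbind(mkSim("b1", "a1", 1e-40, 400),
              mkSim("b2", "a9", 1e-35, 350),   # b2's best is a9, not a2
              mkSim("b2", "a2", 1e-30, 300),
              mkSim("b3", "a3", 1e-3, 50))
  orth <- rbhOrthologs(ab, ba)
  expect_identical(orth$gene_a, "a1")
  expect_identical(orth$gene_b, "b1")
})

test_that("synteny percentages are per source chromosome over mapped genes", {
  orth <- data.frame(gene_a = c("g1", "g2", "g3"),
                     gene_b = c("h1", "h2", "h3"))
  chromA <- c(g1 = "chr1", g2 = "chr1", g3 = "chr1")
  chromB <- c(h1 = "chrA", h2 = "chrA", h3 = "chrB")
  st <- syntenyTable(orth, chromA, chromB)
  expect_identical(st$percentage, c(66.67, 33.33))
  expect_identical(nrow(syntenyTable(orth[0, ], chromA, chromB)), 0L)
})

test_that("planted 1:1 cross-species blocks are tabulated exactly", {
  shared <- sharedSim()
  tr <- shared$ds$truth
  chromMap <- setNames(paste0("B", 1:4), paste0("chr", 1:4))
  mir <- mirrorOrthologSpecies(tr, chromMap)
  orth <- rbhOrthologs(mir$hits_ab, mir$hits_ba)
  expect_identical(nrow(orth), sum(startsWith(tr$role, "ppr")))
  st <- syntenyTable(orth, mir$chrom_a, mir$chrom_b)
  # every source chromosome maps 100% to its planted counterpart
  expect_identical(st$target_chrom, unname(chromMap[st$source_chrom]))
  expect_true(all(st$percentage == 100))
})

test_that("end-to-end duplication recovery matches the planted truth", {
  shared <- sharedSim()
  tr <- shared$ds$truth
  res <- shared$res

  # tandem arrays: exact recovery
  truthArr <- lapply(split(tr$gene_id[!is.na(tr$tandem_array)],
                           tr$tandem_array[!is.na(tr$tandem_array)]), sort)
  foundArr <- lapply(split(res$tandem_arrays$gene_id,
                           res$tandem_arrays$array_id), sort)
  expect_gte(length(truthArr), 3L)
  expect_true(setequal(truthArr, foundArr))

  # segmental: all planted pairs recovered, nothing else called
  segT <- tr[!is.na(tr$dup_type) & tr$dup_type == "segmental", ]
  truthPairs <- paste(pmin(segT$gene_id, segT$partner),
                      pmax(segT$gene_id, segT$partner))
  found <- res$segmental_pairs
  foundPairs <- paste(pmin(found$gene_a, found$gene_b),
                      pmax(found$gene_a, found$gene_b))
  expect_gte(length(truthPairs), 5L)
  expect_true(setequal(truthPairs, foundPairs))
  # every called pair references a block that covers it
  expect_true(all(found$block_id %in% res$blocks$block_id))
})
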