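test_that("NG86 site counts match enumeration for canonical codons", {
  # values frozen from exhaustive single-change enumeration
  expect_equal(ng86Sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng86Sites("GGG"), c(s = 1, n = 2))   # fourfold third position
  expect_equal(ng86Sites("ATG"), c(s = 0, n = 3))   # Met has one codon
  expect_error(ng86Sites("TAA"), "stop")
  expect_error(ng86Sites("QQQ"), "not a valid codon")
})

test_that("every sense codon splits its three positions into s + n = 3", {
  for (cod in oracleSenseCodons()) {
    sn <- ng86Sites(cod)
    expect_equal(unname(sum(sn)), 3)
    expect_equal(sn, oracleSites(cod))
  }
})

test_that("pathway-averaged differences match frozen enumerations", {
  expect_equal(ng86Differences("TTT", "TTC"), c(sd = 1, nd = 0))
  # two paths: via GTT (1 syn + 1 nonsyn) and via TTA (2 nonsyn)
  expect_equal(ng86Differences("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  expect_equal(ng86Differences("AAA", "AAA"), c(sd = 0, nd = 0))
})

test_that("differences are symmetric and bounded by differing positions", {
  set.seed(13)
  sense <- oracleSenseCodons()
  for (rep in 1:60) {
    a <- sample(sense, 1)
    b <- sample(sense, 1)
    d <- ng86Differences(a, b)
    expect_equal(d, ng86Differences(b, a))
    nd <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(d[["sd"]] + d[["nd"]]), nd)
  }
})

test_that("Jukes-Cantor correction matches the closed form and saturates", {
  expect_identical(jcCorrect(0), 0)
  expect_equal(jcCorrect(0.1), 0.107326, tolerance = 1e-5)
  expect_true(is.na(jcCorrect(0.75)))
  expect_true(is.na(jcCorrect(0.9)))
  expect_error(jcCorrect(-0.1))
})

test_that("protein alignment is global, affine and symmetric in score", {
  aln <- alignProteins("MKVLLP", "MKVLLP")
  expect_identical(aln$a, aln$b)
  expect_false(grepl("-", aln$a))

  gap <- alignProteins("MKV", "MV")
  expect_identical(sum(strsplit(gap$b, "")[[1]] == "-"), 1L)

  s1 <- alignProteins("MKVWWLPHH", "MKVLPH")$score
  s2 <- alignProteins("MKVLPH", "MKVWWLPHH")$score
  expect_equal(s1, s2)
  expect_error(alignProteins("", "MKV"), "empty")
})

test_that("back-translation maps residues to codons and drops gaps", {
  # MK V -> gapless 3-codon columns
  aln <- backtranslate("MKV", "MKV", "ATGAAAGTT", "ATGAAAGTA")
  expect_identical(nrow(aln), 3L)
  expect_identical(aln$codon_a, c("ATG", "AAA", "GTT"))

  # a gap column disappears; terminal stop is trimmed
  aln2 <- backtranslate("MKV", "M-V", "ATGAAAGTTTAA", "ATGGTC")
  expect_identical(nrow(aln2), 2L)
  expect_identical(aln2$codon_b, c("ATG", "GTC"))

  # CDS/protein discordance is fatal and names the residue
  expect_error(backtranslate("MKV", "MKV", "ATGAAATAA", "ATGAAAGTT"),
               "residue")
})

test_that("Ka/Ks on a codon alignment matches the brute-force oracle", {
  set.seed(19)
  for (rep in 1:5) {
    codA <- randomSenseCodons(20)
    codB <- randomSenseCodons(20)
    aln <- data.frame(codon_a = codA, codon_b = codB)
    got <- computeKaKs(aln)
    want <- oracleKaKs(codA, codB)
    expect_equal(got$S_sites, want$S)
    expect_equal(got$N_sites, want$N)
    expect_equal(got$Sd, want$Sd)
    expect_equal(got$Nd, want$Nd)
    if (got$ks_valid) expect_equal(got$Ks, want$Ks)
    # symmetry under swapping sequence roles
    swp <- computeKaKs(data.frame(codon_a = codB, codon_b = codA))
    expect_equal(got$Ks, swp$Ks)
    expect_equal(got$Ka, swp$Ka)
  }
})

test_that("identical sequences give zero distances and undefined omega", {
  cod <- randomSenseCodons(15)
  res <- computeKaKs(data.frame(codon_a = cod, codon_b = cod))
  expect_identical(res$Ks, 0)
  expect_identical(res$Ka, 0)
  expect_true(is.na(res$omega))
  expect_identical(res$omega_reason, "Ks is zero")
  expect_equal(res$S_sites + res$N_sites, 3 * 15)
})

test_that("saturated pairs are excluded unless explicitly retained", {
  # maximally different codon columns saturate ps
  aln <- data.frame(codon_a = rep("GGG", 30), codon_b = rep("CCC", 30))
  res <- computeKaKs(aln)
  expect_false(res$ks_valid)
  expect_true(is.na(res$Ks))
  keep <- computeKaKs(aln, keepSaturated = TRUE)
  expect_true(keep$ks_valid)
  expect_false(is.na(keep$Ks))   # raw proportion stands in
})

test_that("clock dating is linear in Ks and matches the grass clock", {
  expect_identical(estimateTime(0), 0)
  expect_equal(estimateTime(0.13), 10)
  expect_equal(estimateTime(5.81), 446.92, tolerance = 1e-4)
  expect_equal(estimateTime(c(1, 2, 3)), estimateTime(1) * c(1, 2, 3))
  expect_error(estimateTime(0.1, lambda = 0), "positive")
})

test_that("pair summaries average valid pairs and count exclusions", {
  rows <- rbind(
    computeKaKs(data.frame(codon_a = c("GGA", "TTT", rep("AAA", 8)),
                           codon_b = c("GGG", "TTC", rep("AAA", 8))),
                "p1"),
    computeKaKs(data.frame(codon_a = rep("GGG", 10),
                           codon_b = rep("CCC", 10)), "p2"))
  s <- summarizePairs(rows, "toy")
  expect_identical(s$n_pairs, 2L)
  expect_identical(s$n_valid_ks, 1L)
  expect_identical(s$n_excluded, 1L)
  expect_equal(s$mean_ks, rows$Ks[1])
  # mean time equals the clock applied to each pair, averaged
  expect_equal(s$mean_time_mya, estimateTime(rows$Ks[1]))

  two <- data.frame(Ks = c(0.1, 0.3), Ka = c(0.02, 0.06),
                    omega = c(0.2, 0.2), ks_valid = TRUE, ka_valid = TRUE)
  s2 <- summarizePairs(two)
  expect_equal(s2$mean_ks, 0.2)
  expect_equal(s2$mean_time_mya, mean(estimateTime(two$Ks)))
})

test_that("the aligned-pair workflow recovers a planted divergence", {
  set.seed(29)
  anc <- paste(randomSenseCodons(200), collapse = "")
  pair <- evolveCdsPair(anc, targetKs = 0.2, omega = 0.2)
  prot <- c(a = pprscape:::.translateCds(pair$cds_a, trimStop = FALSE),
            b = pprscape:::.translateCds(pair$cds_b, trimStop = FALSE))
  res <- kaksPipeline(data.frame(gene_a = "a", gene_b = "b"),
                      proteins = prot,
                      cds = c(a = pair$cds_a, b = pair$cds_b))
  expect_identical(res$n_codons, 200L)
  expect_true(res$ks_valid)
  expect_gt(res$Ks, 0.05)
  expect_lt(res$Ks, 0.45)
  expect_lt(res$omega, 1)   # purifying selection is visible
})
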