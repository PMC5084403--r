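test_that("default motif library is deterministic with canonical lengths", {
  lib1 <- buildDefaultMotifLibrary(seed = 1L)
  lib2 <- buildDefaultMotifLibrary(seed = 1L)
  expect_identical(lib1@consensus, lib2@consensus)
  expect_identical(nchar(motifConsensus(lib1, "P")), 35L)
  expect_identical(nchar(motifConsensus(lib1, "L")), 36L)
  expect_identical(nchar(motifConsensus(lib1, "S")), 31L)
  expect_identical(nchar(motifConsensus(lib1, "DYW")), 94L)
  dyw <- motifConsensus(lib1, "DYW")
  expect_identical(substr(dyw, 92, 94), "DYW")
  # a different seed gives a different library
  expect_false(identical(buildDefaultMotifLibrary(seed = 2L)@consensus,
                         lib1@consensus))
})

test_that("assembled proteins tile planted motif coordinates", {
  lib0 <- buildDefaultMotifLibrary(seed = 1L, epsilon = 0)
  set.seed(1)
  asm <- assemblePprProtein(c("P", "P", "P"), lib0, linkerMax = 0L)
  cons <- motifConsensus(lib0, "P")
  expect_identical(asm$seq, paste(rep(cons, 3), collapse = ""))
  expect_identical(asm$coords$start, c(1L, 36L, 71L))
  expect_identical(asm$coords$end, c(35L, 70L, 105L))

  arch <- c("P", "L", "S", "E", "Eplus", "DYW")
  asm2 <- assemblePprProtein(arch, buildDefaultMotifLibrary(seed = 1L))
  expect_identical(asm2$coords$motif_class, arch)
  expect_true(all(diff(asm2$coords$start) > 0))
  expect_true(all(asm2$coords$start[-1] > asm2$coords$end[-6]))

  expect_error(assemblePprProtein(c("P", "Z"), lib0), "unknown motif")
})

test_that("motif degeneracy epsilon matches the realized identity", {
  lib <- buildDefaultMotifLibrary(seed = 1L, epsilon = 0.05)
  cons <- strsplit(motifConsensus(lib, "P"), "")[[1]]
  set.seed(99)
  ident <- replicate(100, {
    asm <- assemblePprProtein(rep("P", 10L), lib, linkerMax = 0L)
    inst <- strsplit(asm$seq, "")[[1]]
    mean(inst == rep(cons, 10L))
  })
  expect_gt(mean(ident), 0.93)   # binomial expectation 0.95 +- 0.02
  expect_lt(mean(ident), 0.97)
})

test_that("codon evolution honours zero branch length and omega = 0", {
  set.seed(5)
  anc <- paste(randomSenseCodons(100), collapse = "")
  same <- evolveCdsPair(anc, targetKs = 0, omega = 0.2)
  expect_identical(same$cds_a, anc)
  expect_identical(same$cds_b, anc)

  strict <- evolveCdsPair(anc, targetKs = 0.3, omega = 0)
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAStringSet(x), no.init.codon = TRUE))
  expect_identical(tr(strict$cds_a), tr(anc))
  expect_identical(tr(strict$cds_b), tr(anc))
  expect_false(identical(strict$cds_a, anc))  # synonymous changes happened
  expect_identical(strict$n_nonsyn, c(0L, 0L))

  expect_error(evolveCdsPair("ATGTAAGGG", 0.1, 0.2), "stop codon")
})

test_that("dataset generation is seed-deterministic to the byte", {
  cfg <- SimulationConfig(nChromosomes = 2L, chromLength = 2e6,
                          backgroundGenesPerChrom = 8L,
                          tandemArraySizes = c(2L, 3L),
                          nSegmentalPairs = 2L, seed = 3L)
  d1 <- generateDataset(cfg, file.path(tempdir(), "det1"))
  d2 <- generateDataset(cfg, file.path(tempdir(), "det2"))
  for (f in c("truth", "gff", "proteins", "cds", "similarity", "domtbl"))
    expect_identical(readLines(d1$paths[[f]]), readLines(d2$paths[[f]]),
                     label = paste("file", f))
})

test_that("every emitted protein is the translation of its CDS", {
  ds <- sharedSim()$ds
  prot <- readFasta(ds$paths$proteins, kind = "protein")
  cds <- readFasta(ds$paths$cds, kind = "nucleotide")
  expect_identical(names(prot), names(cds))
  trans <- sub("\\*$", "", as.character(
    Biostrings::translate(cds, no.init.codon = TRUE,
                          if.fuzzy.codon = "error")))
  expect_identical(as.character(prot), trans)
})

test_that("GFF3 round-trip reproduces planted gene coordinates exactly", {
  shared <- sharedSim()
  gm <- shared$res$models
  tab <- as.data.frame(gm)
  tr <- shared$ds$truth
  m <- merge(tab, tr, by = "gene_id")
  expect_identical(nrow(m), nrow(tr))
  expect_identical(m$chrom.x, m$chrom.y)
  expect_identical(m$start.x, as.integer(m$start.y))
  expect_identical(m$end.x, as.integer(m$end.y))
  expect_identical(m$strand.x, m$strand.y)
  # planted intron counts survive the round trip
  introns <- countIntrons(gm)
  expect_identical(unname(introns[m$gene_id]), as.integer(m$intron_count))
})

test_that("truth table bookkeeping is internally consistent", {
  tr <- sharedSim()$ds$truth
  # tandem members share a chromosome and arrays have >= 2 members
  byArr <- split(tr, tr$tandem_array)
  expect_true(length(byArr) >= 3L)
  for (a in byArr) {
    expect_gte(nrow(a), 2L)
    expect_identical(length(unique(a$chrom)), 1L)
  }
  # each segmental duplicate pair appears exactly once
  seg <- tr[!is.na(tr$dup_type) & tr$dup_type == "segmental", ]
  expect_identical(anyDuplicated(c(seg$gene_id, seg$partner)), 0L)
  # spliced chromosome sequence reproduces each CDS
  genome <- readFasta(sharedSim()$ds$paths$genome, kind = "nucleotide")
  cds <- readFasta(sharedSim()$ds$paths$cds, kind = "nucleotide")
  gm <- sharedSim()$res$models
  for (gid in c(seg$gene_id[1], tr$gene_id[1])) {
    tx <- unname(representativeTx(gm)[gid])
    ex <- transcriptExons(gm, tx)
    chromSeq <- genome[[as.character(GenomicRanges::seqnames(ex))[1]]]
    spliced <- paste(vapply(seq_along(ex), function(i)
      as.character(Biostrings::subseq(chromSeq,
                                      GenomicRanges::start(ex)[i],
                                      GenomicRanges::end(ex)[i])),
      character(1)), collapse = "")
    strand <- tr$strand[tr$gene_id == gid]
    if (strand == "-")
      spliced <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(spliced)))
    expect_identical(spliced, as.character(cds[[gid]]))
  }
})
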