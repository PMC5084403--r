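test_that("FASTA reading handles multi-line records, case and order", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC", "gt", ">b", "NN"), fa)
  seqs <- readFasta(fa)
  expect_s4_class(seqs, "DNAStringSet")
  expect_identical(names(seqs), c("a", "b"))
  expect_identical(as.character(seqs), c(a = "ACGT", b = "NN"))

  writeLines(c(">p1 description text", "MKV"), fa)
  prot <- readFasta(fa)
  expect_s4_class(prot, "AAStringSet")
  expect_identical(as.character(prot), c(p1 = "MKV"))
})

test_that("FASTA reading rejects duplicate ids and empty sequences", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "MK", ">a", "MK"), fa)
  expect_error(readFasta(fa), "duplicate.*a")
  writeLines(c(">a", "", ">b", "MK"), fa)
  expect_error(readFasta(fa), "empty sequence")
})

test_that("FASTA round-trip preserves ids and sequences exactly", {
  fa <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(g1 = "MKVLLPWWX", g2 = "MPPRAAA", g3 = "M")
  writeFasta(Biostrings::AAStringSet(seqs), fa)
  back <- readFasta(fa, kind = "protein")
  expect_identical(as.character(back), seqs)
})

test_that("GFF3 parsing builds gene models with the longest-CDS rule", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeTinyGff(gff)
  gm <- readGff3(gff)
  expect_s4_class(gm, "GeneModels")
  expect_identical(geneIds(gm), c("gA", "gB"))
  # three exons for gA
  expect_length(transcriptExons(gm, "gA.1"), 3L)
  # representative transcript = longest total CDS (450 beats 300)
  expect_identical(unname(representativeTx(gm)["gB"]), "gB.1")
  expect_identical(unname(representativeTx(gm)["gA"]), "gA.1")
  tab <- as.data.frame(gm)
  expect_identical(tab$cds_length[tab$gene_id == "gB"], 450L)
  expect_false(any(tab$cds_incomplete))
})

test_that("GFF3 structural errors are fatal, frame problems are not", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeTinyGff(gff, exonOutside = TRUE)
  expect_error(readGff3(gff), "outside the span")

  writeTinyGff(gff, badExon = TRUE)          # start > end
  expect_error(readGff3(gff))

  # orphan mRNA
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tt\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=nope",
               "chr1\tt\texon\t1\t100\t.\t+\t.\tID=e1;Parent=t1"), gff)
  expect_error(readGff3(gff), "does not resolve")

  # CDS length not divisible by 3 is a warning flag, not fatal
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tt\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tt\texon\t1\t100\t.\t+\t.\tID=e1;Parent=t1",
               "chr1\tt\tCDS\t1\t100\t.\t+\t0\tID=c1;Parent=t1"), gff)
  expect_warning(gm <- readGff3(gff), "divisible by 3")
  expect_true(as.data.frame(gm)$cds_incomplete[1])
})

test_that("domtblout parsing uses alignment coords and i-Evalue", {
  tbl <- withr::local_tempfile(fileext = ".domtbl")
  writeLines(c(
    "# comment line",
    paste("g1 - 500 PPR_P PF01535 35 1e-08 40.1 0.0 1 2",
          "2e-07  1e-06 20.5 0.0 1 35 10 44 8 46 0.98 -"),
    # wider whitespace must parse identically
    paste("g1   -  500   PPR_L   -   36  1e-05  30.0 0.0  2 2",
          "5e-04   2e-03  10.0 0.0 1 36   50   86  48 88  0.95  -"),
    paste("g2 - 300 LAGLIDADG_2 - 60 1.0 12 0.0 1 1",
          "2.0 5.0 6.0 0.0 1 60 1 60 1 60 0.9 -")), tbl)
  hits <- readDomtblout(tbl)
  expect_identical(nrow(hits), 3L)
  expect_identical(hits$protein_id, c("g1", "g1", "g2"))
  expect_identical(hits$motif_class, c("P", "L", "LAGLIDADG"))
  expect_identical(hits$start, c(10L, 50L, 1L))
  expect_identical(hits$end, c(44L, 86L, 60L))
  expect_equal(hits$evalue, c(1e-06, 2e-03, 5.0))
})

test_that("domtblout handles empty files, unknown profiles, bad rows", {
  tbl <- withr::local_tempfile(fileext = ".domtbl")
  writeLines("# only a comment", tbl)
  expect_identical(nrow(readDomtblout(tbl)), 0L)

  writeLines(paste("g1 - 500 MYSTERY - 35 1e-08 40 0 1 1",
                   "1e-8 1e-8 40 0 1 35 10 44 8 46 0.98 -"), tbl)
  expect_warning(hits <- readDomtblout(tbl), "MYSTERY")
  expect_identical(hits$motif_class, "other")

  writeLines("g1 PPR_P too few fields", tbl)
  expect_error(readDomtblout(tbl), "line 1")
})

test_that("domtblout writer round-trips through the reader", {
  tbl <- withr::local_tempfile(fileext = ".domtbl")
  out <- data.frame(protein_id = c("pA", "pB"),
                    profile = c("PPR_DYW", "SMR"),
                    start = c(101L, 7L), end = c(194L, 91L),
                    score = c(55, 20.5), evalue = c(1e-10, 5.0))
  writeDomtblout(out, tbl)
  back <- readDomtblout(tbl)
  expect_identical(back$protein_id, out$protein_id)
  expect_identical(back$motif_class, c("DYW", "SMR"))
  expect_identical(back$start, out$start)
  expect_identical(back$end, out$end)
  expect_equal(back$evalue, out$evalue)
})

test_that("similarity tables parse 12 columns and reject others", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines("g1\tg2\t90.0\t100\t10\t0\t1\t100\t1\t100\t1e-50\t200", tsv)
  hits <- readSimilarityTab(tsv)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$query_id, "g1")
  expect_equal(hits$evalue, 1e-50)
  expect_equal(hits$bitscore, 200)

  writeLines(character(0), tsv)
  expect_identical(nrow(readSimilarityTab(tsv)), 0L)

  writeLines("g1\tg2\t90.0\t100\t10\t0\t1\t100\t1\t100\t1e-50", tsv)
  expect_error(readSimilarityTab(tsv), "line 1")
})
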