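# Shared fixtures, generated in code at test time.

# One default synthetic dataset, generated once per test run and shared
# by the simulator, duplication and acceptance tests.
.sharedSimEnv <- new.env(parent = emptyenv())
sharedSim <- function() {
  if (is.null(.sharedSimEnv$ds)) {
    dir <- file.path(tempdir(), "pprscape-shared-sim")
    .sharedSimEnv$ds <- generateDataset(SimulationConfig(seed = 42L), dir)
    .sharedSimEnv$res <- analyzePprGenome(
      .sharedSimEnv$ds$paths$gff, .sharedSimEnv$ds$paths$domtbl,
      .sharedSimEnv$ds$paths$similarity, species = "synthetic")
  }
  list(ds = .sharedSimEnv$ds, res = .sharedSimEnv$res)
}

# A small hand-written GFF3 annotation: two genes, the second with two
# transcripts whose CDS lengths differ (300 vs 450).
writeTinyGff <- function(path, exonOutside = FALSE, badExon = FALSE) {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t2500\t.\t+\t.\tID=gA;Name=gA",
    "chr1\ttest\tmRNA\t1000\t2500\t.\t+\t.\tID=gA.1;Parent=gA",
    paste0("chr1\ttest\texon\t",
           if (exonOutside) "900" else "1000",
           "\t1398\t.\t+\t.\tID=gA.1.e1;Parent=gA.1"),
    "chr1\ttest\texon\t1600\t1899\t.\t+\t.\tID=gA.1.e2;Parent=gA.1",
    "chr1\ttest\texon\t2200\t2500\t.\t+\t.\tID=gA.1.e3;Parent=gA.1",
    "chr1\ttest\tCDS\t1000\t1398\t.\t+\t0\tID=gA.1.c1;Parent=gA.1",
    "chr1\ttest\tCDS\t1600\t1899\t.\t+\t0\tID=gA.1.c2;Parent=gA.1",
    "chr1\ttest\tCDS\t2200\t2499\t.\t+\t0\tID=gA.1.c3;Parent=gA.1",
    "chr1\ttest\tgene\t5000\t6500\t.\t-\t.\tID=gB;Name=gB",
    "chr1\ttest\tmRNA\t5000\t6000\t.\t-\t.\tID=gB.2;Parent=gB",
    "chr1\ttest\texon\t5000\t5299\t.\t-\t.\tID=gB.2.e1;Parent=gB.2",
    "chr1\ttest\tCDS\t5000\t5299\t.\t-\t0\tID=gB.2.c1;Parent=gB.2",
    "chr1\ttest\tmRNA\t5000\t6500\t.\t-\t.\tID=gB.1;Parent=gB",
    if (badExon)
      "chr1\ttest\texon\t5500\t5400\t.\t-\t.\tID=gB.1.e1;Parent=gB.1"
    else
      "chr1\ttest\texon\t5000\t5449\t.\t-\t.\tID=gB.1.e1;Parent=gB.1",
    "chr1\ttest\tCDS\t5000\t5449\t.\t-\t0\tID=gB.1.c1;Parent=gB.1")
  writeLines(lines, path)
  path
}

# Motif hit table builder
mkHits <- function(protein_id, motif_class, start, end,
                   score = 50, evalue = 1e-8) {
  data.frame(protein_id = protein_id, motif_class = motif_class,
             start = as.integer(start), end = as.integer(end),
             score = score, evalue = evalue)
}

# Similarity hit builder
mkSim <- function(query, subject, evalue, bitscore = 200) {
  data.frame(query_id = query, subject_id = subject, pct_identity = 90,
             aln_length = 100L, mismatches = 10L, gap_opens = 0L,
             q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
             evalue = evalue, bitscore = bitscore)
}
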