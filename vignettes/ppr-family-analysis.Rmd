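---
title: "Genome-wide PPR gene-family analysis with pprscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide PPR gene-family analysis with pprscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprscape)
```

## The problem

Pentatricopeptide repeat (PPR) proteins are sequence-specific RNA-binding
proteins built from tandem arrays of a degenerate ~35-residue helical
repeat. Land-plant genomes carry hundreds of PPR genes, most of them
intronless, targeted to mitochondria or chloroplasts, and expanded by
gene duplication. A genome-wide family survey asks a standard series of
questions: which proteins are PPR proteins, which subfamily and subgroup
does each belong to, how are the genes structured and distributed over
chromosomes, which copies arose by tandem versus segmental duplication,
how long ago did those duplications happen, and how do the genes map
onto related genomes.

`pprscape` implements that whole workflow as composable functions, and —
because the questions are only meaningful if the pipeline can be shown
to answer them correctly — pairs it with a synthetic-genome simulator
that plants every feature the pipeline is supposed to find, with known
ground truth.

## Identification and classification model

Identification works on motif-level evidence: per-domain hits from an
external profile search (HMMER3 `domtblout` tables are parsed with
`readDomtblout()`, using alignment coordinates and the per-domain
independent E-value) or from the built-in PSSM scanner
(`scanProteinPssm()`), which slides per-class log-odds matrices built
from the consensus library over the protein. Two thresholds mirror
standard practice: a permissive screen (E-value <= 10,
`filterHits()`) and a confidence requirement (at least one hit with
E-value < 1.0) inside `identifyPprProteins()`. A protein additionally
needs at least two repeat-class motifs (P/L/S/L2) after overlap
resolution: PPR proteins are defined by tandem repetition, and two
chained repeats is the weakest reading of "tandem". Scanner hits carry
bit scores rather than calibrated E-values (null-model fitting is out
of scope), so they are screened by score (default floor 8 bits) and
count as confident.

Overlapping hits are resolved by `chainArchitecture()`: greedy
selection in descending score order, ties broken by smaller start and
then class name, keeping a hit only if it overlaps every kept hit by at
most 3 residues. The classification rules then read directly off the
resolved architecture:

* subfamily **P** — repeat content is pure P; **PLS** — at least one
  L, S or L2 variant is present;
* subgroup (PLS subfamily only): **DYW** if a DYW domain is present
  (absolute precedence — DYW proteins carry E/E+ upstream and remain
  DYW), else **E/E+** if an E or E+ domain is present, else **PLS**;
* RRM, LAGLIDADG and SMR are auxiliary annotations, never subfamily
  evidence: a P-class protein with a fused LAGLIDADG domain stays
  subfamily P.

The E versus E+ distinction is taken from the profile names in the
input (two separate profiles, two separate library consensi); no
structural split rule is guessed, because the biological distinction —
the E+ extension is not always present — is not algorithmic.

## Duplication detection

Tandem arrays follow the distance rule used in plant family surveys:
per chromosome, consecutive family genes whose intergenic gap
(downstream start − upstream end − 1) is strictly below 100 kb are
linked, regardless of strand; maximal runs of two or more genes are
arrays. Intervening non-family genes do not break an array (the rule is
purely metric), and runs longer than seven members are kept whole with
an `oversize` flag — the 2–7 range seen in real families is an
observation, not a constraint.

Segmental duplication needs two kinds of evidence. Candidate duplicate
pairs come from `topHitsFilter()`: per query, the five best similarity
hits, of which those with E-value < 1e-5 survive, symmetrized to
unordered pairs. Collinearity comes from `detectCollinearBlocks()`:
genes are reduced to ordinal ranks along their chromosomes, and anchors
(homologous gene pairs, typically including non-family background
genes) are chained by the longest strictly monotone subsequence per
chromosome pair — run both increasing and decreasing to catch inverted
blocks — with consecutive rank gaps capped at 25 and a minimum of 5
anchors per block; anchors consumed by a block are removed and the
search repeats. This is a deliberately transparent stand-in for
database-backed collinearity pipelines whose exact procedure is not
specifiable; the block semantics (ordered runs of homologous pairs) are
the same. `callSegmentalPairs()` then accepts a candidate pair if both
genes fall inside one block's rank spans, excluding tandem co-members:
tandem takes precedence, so the two duplicate sets are disjoint.

Cross-genome orthology uses reciprocal best hits (`rbhOrthologs()`,
best = lowest E-value, ties by bit score then subject id) and
`syntenyTable()` reports, per source chromosome, the percentage of
mapped genes whose ortholog lies on each target chromosome. Percentages
are over *mapped* genes (rows sum to 100); published tables that include
unmapped genes will show smaller row sums.

## Ka/Ks estimation and dating

The divergence machinery is classical Nei–Gojobori (1986) counting,
chosen over ML codon models because it is the fully specifiable
estimator behind the single Ka/Ks value per pair that survey papers
report:

* `ng86Sites()` — for each sense codon, the fraction of the nine
  single-nucleotide changes that are synonymous, summed per position
  (`s`), with `n = 3 − s`. Changes to stop codons count as
  nonsynonymous, which keeps `s + n = 3` exactly.
* `ng86Differences()` — differences between two codons averaged with
  equal weight over all orderings of the single-nucleotide steps;
  orderings that pass through a stop codon are excluded, falling back
  to all orderings when none survive.
* `jcCorrect()` — Jukes–Cantor multiple-hit correction
  `d = −(3/4)·ln(1 − 4p/3)`; proportions at or beyond 0.75 are
  saturated and carry no finite distance.
* `computeKaKs()` — sites averaged over the two sequences, differences
  summed per column, proportions corrected; `omega = Ka/Ks` only when
  both distances are valid and `Ks > 0`.

Codon alignments are built PAL2NAL-style: global protein alignment
(`alignProteins()`, BLOSUM62, gap open 10 / extend 0.5 — the classical
ClustalW-type parameterization) back-translated onto the coding
sequences by `backtranslate()`, dropping gap columns and stop-codon
columns, after verifying the CDS translation equals the protein.

Dating uses the molecular clock `T = Ks / (2λ)` with λ = 6.5e-9
synonymous substitutions per site per year, the conventional grass
clock; λ is a parameter of `estimateTime()`, not a constant. Under this
clock a mean segmental Ks of 5.81 dates to ≈ 446.9 Mya.

Three numerical policies deserve explicit statement:

* **Saturation.** Pairs with `p >= 0.75` are flagged and excluded from
  group means by default. Published family surveys sometimes retain
  heavily saturated pairs (a tandem mean Ks above 20 is only possible
  that way); `computeKaKs(..., keepSaturated = TRUE)` reproduces that
  behaviour by reporting the raw proportion where the correction is
  undefined. It is off by default because a corrected distance does not
  exist there.
* **Group means.** `summarizePairs()` averages per-pair values and
  reports per-pair times averaged over the valid pairs. Because the
  clock is linear in Ks, the mean of per-pair times necessarily equals
  the clock applied to the mean Ks *over the same pairs*; when a
  published mean time and a published mean Ks disagree under every λ,
  the two numbers were computed over different pair sets (e.g. with and
  without saturated pairs), not by a different formula. The summary
  therefore always reports its exclusion counts alongside the means.
* **Rounding.** All reported percentages are rounded half away from
  zero to two decimals. Published per-chromosome percentages are not
  always reproducible from their own printed counts (99/486 is 20.37,
  not 20.49); the package does exact arithmetic and does not guess a
  corrected denominator.

## What the simulator emulates — and what it does not

`generateDataset()` builds a multi-chromosome genome in which every
downstream observable is planted:

* PPR genes assembled from a seeded consensus library
  (`buildDefaultMotifLibrary()`: P 35, L 36, S 31, L2 35, E 34, E+ 31,
  DYW 94 ending in the literal D-Y-W, RRM 80, LAGLIDADG 60, SMR 85
  residues; per-position substitution probability 0.05) with mixed
  P / PLS / E-E+ / DYW architectures and a few auxiliary-domain
  fusions;
* tandem arrays of sizes 2–4 with 30 kb spacing (inside the 100 kb
  rule), other family genes kept > 110 kb apart so array recovery has
  an exact expected answer;
* segmental pairs inside collinear blocks of eight duplicated
  background-gene anchors, with per-pair target Ks of 0.1–0.5 and
  ω = 0.2;
* intron counts drawn with 78% intronless (the typical plant PPR
  fraction), remainder spread over 1, 2–5 and ≥ 6;
* motif truth hits at planted coordinates with two-point E-values
  (1e-10 confident, 5.0 marginal decoys on background genes), and a
  similarity table with duplicate/anchor/self hits plus sub-threshold
  decoys.

The codon-level duplicate divergence is simulated by a site-wise
process (`evolveCdsPair()`): single-nucleotide changes proposed at
κ-weighted rates (κ = 2), accepted with relative rate 1 if synonymous,
ω if nonsynonymous, 0 if creating a stop. The branch length is
parameterized directly as a synonymous-event quota per NG86 synonymous
site (Poisson around `Ks/2 · S` per branch), so the planted Ks lives on
exactly the scale the estimator measures — the clean property the
recovery tests need, deliberately avoiding rate-matrix normalization
subtleties that would only blur what "truth" means.

The simulator does **not** emulate: indels in coding sequence (so
alignment-quality effects on Ka/Ks are untested), recombination or gene
conversion between duplicates, realistic intergenic composition or
splice-site signal, profile-search score noise (truth hits carry exact
coordinates), or partially diverged pseudo-genes. Passing the
end-to-end tests therefore demonstrates that the pipeline logic is
correct on clean evidence at realistic family sizes — not that a real
profile search at these thresholds would achieve the same sensitivity
on a real proteome.

## Default problem sizes and reproducibility

The default `SimulationConfig()` uses 4 chromosomes of 3 Mb, 40
background genes per chromosome, 14 singleton PPR architectures, 3
tandem arrays (sizes 2, 3, 4), 6 segmental pairs on blocks of 8
anchors, and a fixed master seed; these sizes were chosen so a full
dataset-plus-pipeline run completes in well under a minute while still
containing every feature class several times over. All randomness —
library construction, sequence assembly, codon evolution, placement —
derives from the config seed, and a fixed seed reproduces every output
file byte for byte. Parameter-recovery checks use 50 replicate pairs of
300 codons per target Ks, which bounds the Monte-Carlo error of the
mean Ks at roughly 2% while keeping the whole run in seconds.

## Worked example

```{r example, eval = FALSE}
cfg <- SimulationConfig(seed = 42L)
ds <- generateDataset(cfg, tempfile("sim"))
res <- analyzePprGenome(ds$paths$gff, ds$paths$domtbl,
                        ds$paths$similarity, species = "synthetic")
res$census
#>     species total  P PLS_total PLS EEplus DYW
#> 1 synthetic    35 13        22   4      7  11
res$intron_bins
nrow(res$tandem_arrays)        # members across the 3 planted arrays
res$segmental_pairs            # all 6 planted pairs, with block ids
```

## Known limitations

* Published headline censuses (hundreds of genes per species) depend on
  specific proteome releases and profile versions and cannot be
  reproduced from first principles; the package validates the rules,
  not the downloads.
* The collinearity chaining is rank-based and greedy; it recovers
  clean planted blocks exactly but is not a substitute for
  likelihood-based synteny tools on rearrangement-dense real genomes.
* NG86 with Jukes–Cantor correction ignores transition/transversion
  bias in *estimation* (the simulator includes it in *generation*;
  the residual bias is small and covered by the recovery tolerances).
* E versus E+ subgroup resolution is only as good as the input profile
  annotation.
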