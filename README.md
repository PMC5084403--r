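# pprscape

Genome-wide analysis of the pentatricopeptide-repeat (PPR) gene family
in R, Bioconductor style.

PPR proteins are organellar RNA-binding proteins built from tandem
arrays of a degenerate ~35-residue helical repeat; plant genomes carry
hundreds of PPR genes, mostly intronless and heavily shaped by gene
duplication. `pprscape` implements the full comparative-genomics survey
workflow for such a family:

* **Identification & classification** — parse motif hits (HMMER3
  `domtblout` dialect) or scan proteins with built-in consensus PSSMs;
  screen at E ≤ 10, require ≥ 2 repeat-class (P/L/S/L2) motifs after
  overlap resolution plus one confident hit (E < 1.0); chain motifs
  into an ordered architecture and assign the **P**/**PLS** subfamily
  and the **PLS**/**E-E+**/**DYW** subgroup (DYW precedence is
  absolute), with RRM/LAGLIDADG/SMR as auxiliary annotations.
* **Structure & distribution** — intron counts from the
  representative transcript (longest CDS), the 0 / 1 / 2–5 / ≥6 intron
  bins, per-chromosome counts and two-decimal percentages.
* **Duplication** — tandem arrays by the strict < 100 kb
  intergenic-gap rule; segmental pairs from top-5, E < 1e-5 similarity
  candidates confirmed by rank-based collinear-block chaining (longest
  monotone anchor subsequence, ≥ 5 anchors, rank gap ≤ 25); reciprocal
  best-hit orthologs and per-chromosome synteny percentage tables.
* **Ka/Ks & dating** — Nei–Gojobori (1986) site and pathway-averaged
  difference counting with Jukes–Cantor correction,

      Ks = -(3/4) ln(1 - 4 ps / 3),   omega = Ka / Ks,

  over PAL2NAL-style codon alignments (BLOSUM62 global protein
  alignment back-translated onto the CDS), and molecular-clock dating
  **T = Ks / (2λ)** with the conventional grass rate
  λ = 6.5 × 10⁻⁹ synonymous substitutions/site/year.
* **Synthetic genomes with ground truth** — `generateDataset()` plants
  PPR architectures, tandem arrays, collinear duplicate blocks and
  codon-level diverged CDS pairs (site-wise κ/ω process with a known
  synonymous branch length) and emits genome/protein/CDS FASTA, GFF3,
  a motif table, a similarity table and a truth table, so every stage
  of the pipeline is testable end to end without downloads.

## Worked example

```r
library(pprscape)

cfg <- SimulationConfig(seed = 42L)       # 4 chromosomes, 35 PPR genes,
ds  <- generateDataset(cfg, tempfile())   # 3 tandem arrays, 6 segmental pairs
res <- analyzePprGenome(ds$paths$gff, ds$paths$domtbl,
                        ds$paths$similarity, species = "synthetic")

res$census
#>     species total  P PLS_total PLS EEplus DYW
#> 1 synthetic    35 13        22   4      7  11
```

All 35 planted PPR genes are identified (no background gene passes the
two-repeats-plus-confidence rule), 13 are pure-P architectures and 22
are PLS-subfamily, of which 11 carry a DYW domain. Structure and
duplication read off the same object:

```r
res$intron_bins
#>   bin count percentage
#> 1   0    28      80.00
#> 2   1     4      11.43
#> 3 2-5     1       2.86
#> 4 >=6     2       5.71

res$segmental_pairs
#>        gene_a      gene_b  dup_type evalue block_id
#> 1 ppr_seg01_a ppr_seg01_b segmental  1e-80    CB001
#> ...                                  (all 6 planted pairs, 0 false calls)
```

Dating a duplicate pair set works from Ks: a mean segmental Ks of 5.81
gives `estimateTime(5.81)` ≈ 446.92 Mya under the default grass clock.

The truth table `ds$truth` records every planted architecture,
subfamily, intron count, array membership, duplicate partner and target
Ks, which is how the test suite scores recovery (100% of arrays, 100%
of segmental pairs with zero false calls, 100% correct
subfamily/subgroup assignments at the default configuration).

## Documentation

The methods vignette (`vignettes/ppr-family-analysis.Rmd`) describes
the identification thresholds, the chaining and classification rules,
the collinearity model, the NG86/Jukes–Cantor estimator and its
saturation policy, what the simulator does and does not emulate, and
the package's numerical conventions.
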