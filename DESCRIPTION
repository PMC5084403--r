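Package: pprscape
Title: Genome-Wide Pentatricopeptide-Repeat Gene Family Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Motif-based identification and classification of
    pentatricopeptide repeat (PPR) proteins into the P and PLS subfamilies
    and the PLS, E/E+ and DYW subgroups; gene-structure and chromosomal
    distribution statistics; tandem-array and segmental-duplication
    detection via top-hit filtering and collinear-block chaining;
    reciprocal-best-hit ortholog mapping with per-chromosome synteny
    tables; Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor
    correction and molecular-clock dating of duplication events. Includes
    a synthetic-genome simulator that plants PPR architectures, tandem
    arrays, collinear duplicate blocks and codon-level diverged CDS pairs
    with known ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'pprscape-package.R'
    'utils.R'
    'AllClasses.R'
    'genome-io.R'
    'kaks.R'
    'synthetic-genome.R'
    'motif-annotation.R'
    'classification.R'
    'structure-stats.R'
    'duplication.R'
    'pipeline.R'
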