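# Synthetic genomes with planted PPR architectures, tandem arrays,
# collinear duplicate blocks and codon-level diverged CDS pairs. The
# generator's outputs use exactly the formats the readers in genome-io.R
# parse, and every planted feature is recorded in a truth table so the
# downstream pipeline can be scored against known ground truth.

#' Build the default motif consensus library
#'
#' Deterministically samples one consensus sequence per motif class at
#' the canonical lengths (P 35, L 36, S 31, L2 35, E 34, E+ 31, DYW 94
#' ending in the literal Asp-Tyr-Trp tripeptide, RRM 80, LAGLIDADG 60,
#' SMR 85). The caller's RNG stream is left untouched.
#'
#' @param seed Integer seed; the same seed always yields the same
#'   library.
#' @param epsilon Per-position substitution probability applied when
#'   instances are sampled from the consensus (single value or named
#'   per-class vector), in `[0, 0.5)`.
#' @return A [MotifLibrary].
#' @export
buildDefaultMotifLibrary <- function(seed = 1L, epsilon = 0.05) {
  cons <- withSeed(seed, {
    out <- vapply(names(.MOTIF_LENGTHS), function(cls) {
      paste(sample(.AA20, .MOTIF_LENGTHS[[cls]], replace = TRUE),
            collapse = "")
    }, character(1))
    len <- nchar(out[["DYW"]])
    out[["DYW"]] <- paste0(substr(out[["DYW"]], 1L, len - 3L), "DYW")
    out
  })
  if (is.null(names(epsilon)))
    epsilon <- setNames(rep_len(epsilon, length(cons)), names(cons))
  new("MotifLibrary", consensus = cons, epsilon = epsilon)
}

# Sample one degenerate instance of a consensus: each position is
# substituted with probability eps, uniformly among the 19 other residues.
.mutateConsensus <- function(cons, eps) {
  chars <- strsplit(cons, "")[[1]]
  hit <- runif(length(chars)) < eps
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(.AA20, a), 1L), character(1))
  paste(chars, collapse = "")
}

#' Assemble a PPR protein from an ordered motif architecture
#'
#' Concatenates sampled motif instances (consensus with per-position
#' substitution probability `epsilon` from the library) separated by
#' 0 to `linkerMax` random linker residues, and returns the exact
#' planted motif coordinates. Uses the current RNG stream.
#'
#' @param architecture Ordered character vector of motif classes, e.g.
#'   `c("P","L","S","E","Eplus","DYW")`.
#' @param library A [MotifLibrary].
#' @param linkerMax Maximum linker length between motifs (default 5).
#' @return List with `seq` (protein string) and `coords` (data.frame
#'   `motif_class`, `start`, `end`, 1-based inclusive).
#' @export
assemblePprProtein <- function(architecture, library, linkerMax = 5L) {
  if (!length(architecture)) stop("architecture must be non-empty")
  unknown <- setdiff(architecture, names(library@consensus))
  if (length(unknown))
    stop("unknown motif class(es): ", paste(unknown, collapse = ", "))
  pieces <- character(0)
  rows <- vector("list", length(architecture))
  pos <- 0L
  for (i in seq_along(architecture)) {
    cls <- architecture[i]
    if (i > 1L && linkerMax > 0L) {
      nl <- sample.int(linkerMax + 1L, 1L) - 1L
      if (nl > 0L) {
        pieces <- c(pieces, paste(sample(.AA20, nl, TRUE), collapse = ""))
        pos <- pos + nl
      }
    }
    inst <- .mutateConsensus(library@consensus[[cls]],
                             library@epsilon[[cls]])
    pieces <- c(pieces, inst)
    rows[[i]] <- data.frame(motif_class = cls, start = pos + 1L,
                            end = pos + nchar(inst))
    pos <- pos + nchar(inst)
  }
  list(seq = paste(pieces, collapse = ""),
       coords = do.call(rbind, rows))
}

# ---- codon-level evolution -------------------------------------------

.cdsToCodonIdx <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  cd <- .codonData()
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  if (any(cd$aa[codons] == "*"))
    stop("internal stop codon at codon ",
         which(cd$aa[codons] == "*")[1L])
  unname(cd$idx[codons])
}

.codonIdxToCds <- function(state) {
  paste(.codonData()$codons[state], collapse = "")
}

# Per-codon single-nucleotide change weights under the kappa/omega model:
# transitions weighted kappa, synonymous changes weight 1, nonsynonymous
# weight omega, changes to stop codons weight 0.
.changeWeights <- function(omega, kappa) {
  cd <- .codonData()
  w <- ifelse(cd$tsn, kappa, 1) *
    ifelse(cd$syn, 1, ifelse(cd$stp, 0, omega))
  w
}

# Evolve one branch for a synonymous branch length ksBranch (synonymous
# substitutions per NG86 synonymous site). The synonymous event quota is
# Poisson(ksBranch * S) with S the ancestor's synonymous site count;
# events are drawn from the weighted change distribution until the quota
# of synonymous events is reached, so nonsynonymous events accrue in the
# omega-controlled proportion along the way.
.evolveBranch <- function(state, ksBranch, omega, kappa) {
  cd <- .codonData()
  W <- .changeWeights(omega, kappa)
  S <- sum(cd$sSites[cd$codons[state]])
  quota <- if (ksBranch > 0) rpois(1L, ksBranch * S) else 0L
  nsyn <- 0L
  nnon <- 0L
  if (quota > 0L) {
    siteW <- rowSums(W)[state]
    guard <- 0L
    maxEvents <- 1000L * (quota + 10L)
    while (nsyn < quota) {
      guard <- guard + 1L
      if (guard > maxEvents)
        stop("substitution process failed to reach its synonymous quota")
      tot <- sum(siteW)
      if (tot <= 0)
        stop("no substitutions are possible under this model")
      site <- sample.int(length(state), 1L, prob = siteW)
      i <- state[site]
      j <- sample.int(9L, 1L, prob = W[i, ])
      if (cd$syn[i, j]) nsyn <- nsyn + 1L else nnon <- nnon + 1L
      state[site] <- cd$nbr[i, j]
      siteW[site] <- sum(W[state[site], ])
    }
  }
  list(state = state, n_syn = nsyn, n_nonsyn = nnon)
}

#' Evolve a duplicate CDS pair to a target synonymous divergence
#'
#' Simulates two descendants of an ancestral coding sequence, each
#' evolved independently for half the target synonymous branch length,
#' under a site-wise codon process: candidate single-nucleotide changes
#' are proposed at kappa-weighted nucleotide rates and accepted with
#' relative rate 1 if synonymous, `omega` if nonsynonymous, 0 if they
#' would create a stop codon. The branch length is parameterized
#' directly in synonymous substitutions per NG86 synonymous site, so the
#' planted Ks is on exactly the scale the NG86 estimator measures.
#'
#' @param ancestralCds Coding sequence (length divisible by 3, no
#'   internal stops; a terminal stop is not expected).
#' @param targetKs Total synonymous divergence between the two
#'   descendants (`>= 0`).
#' @param omega Nonsynonymous/synonymous acceptance ratio (Ka/Ks).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @return List with `cds_a`, `cds_b` and the realized per-branch
#'   substitution counts `n_syn`, `n_nonsyn` (length-2 vectors).
#' @export
evolveCdsPair <- function(ancestralCds, targetKs, omega, kappa = 2) {
  if (targetKs < 0) stop("targetKs must be >= 0")
  if (omega < 0) stop("omega must be >= 0")
  state <- .cdsToCodonIdx(ancestralCds)
  if (targetKs == 0) {
    cds <- .codonIdxToCds(state)
    return(list(cds_a = cds, cds_b = cds,
                n_syn = c(0L, 0L), n_nonsyn = c(0L, 0L)))
  }
  a <- .evolveBranch(state, targetKs / 2, omega, kappa)
  b <- .evolveBranch(state, targetKs / 2, omega, kappa)
  list(cds_a = .codonIdxToCds(a$state), cds_b = .codonIdxToCds(b$state),
       n_syn = c(a$n_syn, b$n_syn), n_nonsyn = c(a$n_nonsyn, b$n_nonsyn))
}

# ---- sequence helpers -------------------------------------------------

.aaCodonTable <- function() {
  cd <- .codonData()
  split(cd$sense, cd$aa[cd$sense])
}

# Reverse-translate a protein by sampling a codon per residue.
.revTranslate <- function(protein) {
  tab <- .aaCodonTable()
  chars <- strsplit(protein, "")[[1]]
  paste(vapply(chars, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue: ", a)
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

.randomCds <- function(nCodons) {
  sense <- .codonData()$sense
  paste(c("ATG", sense[sample.int(length(sense), nCodons - 1L,
                                  replace = TRUE)]), collapse = "")
}

.translateCds <- function(cds, trimStop = TRUE) {
  # no.init.codon: the literal codon table, no initiator-Met rewriting
  aa <- as.character(translate(DNAStringSet(cds),
                               no.init.codon = TRUE,
                               if.fuzzy.codon = "error"))
  if (trimStop) aa <- sub("\\*$", "", aa)
  aa
}

.revcomp <- function(x)
  as.character(reverseComplement(DNAStringSet(x)))

.randomDna <- function(n) {
  if (n <= 0L) return("")
  paste(.NUCS[sample.int(4L, n, replace = TRUE)], collapse = "")
}

# ---- simulation configuration ----------------------------------------

#' @rdname SimulationConfig-class
#' @export
defaultArchitecturePlan <- function() {
  pls <- c("P", "L", "S")
  list(rep("P", 10L), rep("P", 8L), rep("P", 6L), rep("P", 12L),
       rep(pls, 4L), c(rep(pls, 3L), "L2"),
       c(rep(pls, 3L), "E"), c(rep(pls, 2L), "E", "Eplus"),
       c(rep(pls, 3L), "E", "Eplus", "DYW"),
       c(rep(pls, 4L), "E", "Eplus", "DYW"),
       c(rep(pls, 2L), "E", "DYW"),
       c(rep("P", 6L), "LAGLIDADG"),
       c(rep("P", 8L), "SMR"),
       c(rep("P", 5L), "RRM"))
}

#' SimulationConfig: parameters of the synthetic genome
#'
#' Describes one simulated multi-chromosome genome: how many chromosomes
#' and how long, the planted PPR architectures, the tandem-array plan
#' (array sizes 2-7, members spaced under the 100 kb tandem rule), the
#' segmental plan (duplicate pairs placed inside collinear blocks of
#' duplicated background anchors, with per-pair target Ks and omega),
#' background gene counts, the intron-count distribution (defaulting to
#' 78% intronless, matching typical plant PPR families), and the codon
#' model's transition/transversion ratio. A fixed seed makes every
#' output byte-identical across runs.
#'
#' @slot nChromosomes,chromLength Genome shape (chromosome count, bp).
#' @slot architecturePlan List of motif-class vectors, one singleton PPR
#'   gene each; see [defaultArchitecturePlan()].
#' @slot tandemArraySizes Integer sizes of planted tandem arrays.
#' @slot tandemSpacing Intra-array intergenic gap in bp (< 100000).
#' @slot nSegmentalPairs,segmentalKs,segmentalOmega,blockAnchors
#'   Segmental plan: number of pairs, per-pair target Ks (recycled),
#'   omega, and background anchor pairs per collinear block.
#' @slot backgroundGenesPerChrom Background (non-PPR) genes per
#'   chromosome.
#' @slot intronZeroProb Probability that a gene is intronless.
#' @slot kappa Transition/transversion ratio of the codon process.
#' @slot epsilon Motif degeneracy passed to the motif library.
#' @slot seed Integer master seed.
#' @export
setClass("SimulationConfig",
         representation(nChromosomes = "integer", chromLength = "numeric",
                        architecturePlan = "list",
                        tandemArraySizes = "integer",
                        tandemSpacing = "numeric",
                        nSegmentalPairs = "integer",
                        segmentalKs = "numeric",
                        segmentalOmega = "numeric",
                        blockAnchors = "integer",
                        backgroundGenesPerChrom = "integer",
                        intronZeroProb = "numeric",
                        kappa = "numeric", epsilon = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nChromosomes < 1L) msg <- c(msg, "need >= 1 chromosome")
  if (any(object@tandemArraySizes < 2L))
    msg <- c(msg, "tandem arrays must have >= 2 members")
  if (object@tandemSpacing >= 1e5)
    msg <- c(msg, "tandemSpacing must be < 100000 bp")
  if (any(object@segmentalKs <= 0))
    msg <- c(msg, "segmental target Ks must be > 0")
  if (object@intronZeroProb < 0 || object@intronZeroProb > 1)
    msg <- c(msg, "intronZeroProb must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nChromosomes,chromLength,architecturePlan,tandemArraySizes,tandemSpacing,nSegmentalPairs,segmentalKs,segmentalOmega,blockAnchors,backgroundGenesPerChrom,intronZeroProb,kappa,epsilon,seed
#'   See the class slots.
#' @return A `SimulationConfig`.
#' @export
SimulationConfig <- function(nChromosomes = 4L, chromLength = 3e6,
                             architecturePlan = defaultArchitecturePlan(),
                             tandemArraySizes = c(2L, 3L, 4L),
                             tandemSpacing = 30000,
                             nSegmentalPairs = 6L,
                             segmentalKs = c(0.1, 0.2, 0.3, 0.3, 0.4, 0.5),
                             segmentalOmega = 0.2,
                             blockAnchors = 8L,
                             backgroundGenesPerChrom = 40L,
                             intronZeroProb = 0.78,
                             kappa = 2, epsilon = 0.05, seed = 42L) {
  new("SimulationConfig",
      nChromosomes = as.integer(nChromosomes), chromLength = chromLength,
      architecturePlan = architecturePlan,
      tandemArraySizes = as.integer(tandemArraySizes),
      tandemSpacing = tandemSpacing,
      nSegmentalPairs = as.integer(nSegmentalPairs),
      segmentalKs = segmentalKs, segmentalOmega = segmentalOmega,
      blockAnchors = as.integer(blockAnchors),
      backgroundGenesPerChrom = as.integer(backgroundGenesPerChrom),
      intronZeroProb = intronZeroProb,
      kappa = kappa, epsilon = epsilon, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nChromosomes, "chromosomes x",
      format(object@chromLength, big.mark = ","), "bp;",
      length(object@architecturePlan), "singleton PPR genes;",
      length(object@tandemArraySizes), "tandem arrays;",
      object@nSegmentalPairs, "segmental pairs; seed", object@seed, "\n")
})

# Subfamily/subgroup implied by a planted architecture (the simulator's
# own bookkeeping, independent of the classifier under test).
.plantedSubfamily <- function(arch) {
  if (any(arch %in% c("L", "S", "L2"))) "PLS" else "P"
}
.plantedSubgroup <- function(arch) {
  if (.plantedSubfamily(arch) == "P") return("none")
  if ("DYW" %in% arch) return("DYW")
  if (any(arch %in% c("E", "Eplus"))) return("E/E+")
  "PLS"
}

.drawIntronCount <- function(zeroProb) {
  u <- runif(1)
  if (u < zeroProb) return(0L)
  # remaining mass split 10:8:4 over {1}, {2..5}, {6..8}
  rest <- (u - zeroProb) / (1 - zeroProb)
  if (rest < 10 / 22) 1L
  else if (rest < 18 / 22) sample(2:5, 1L)
  else sample(6:8, 1L)
}

# ---- dataset generation ----------------------------------------------

#' Generate a synthetic genome dataset with known ground truth
#'
#' Produces, under `outdir`: `genome.fa` (chromosome sequences),
#' `genes.gff3` (gene/mRNA/exon/CDS), `proteins.fa`, `cds.fa` (every
#' protein is the standard-code translation of its CDS; CDS carry a
#' terminal stop codon), `motifs.domtblout` (planted motif coordinates:
#' confident hits at E-value 1e-10 on PPR genes, marginal decoy hits at
#' 5.0 on background genes), `similarity.tsv` (12-column hits for
#' duplicate pairs, tandem co-members, collinear-block anchors, self
#' hits, plus sub-threshold decoys) and `truth.tsv` (the per-gene truth
#' table). All planted tandem arrays satisfy the < 100 kb rule and all
#' planted segmental pairs lie inside planted collinear blocks of
#' duplicated background anchors.
#'
#' @param config A [SimulationConfig].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth`
#'   (the truth data.frame), `library` (the [MotifLibrary] used) and
#'   `config`.
#' @export
generateDataset <- function(config = SimulationConfig(),
                            outdir = tempfile("pprsim")) {
  validObject(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lib <- buildDefaultMotifLibrary(seed = config@seed,
                                  epsilon = config@epsilon)
  withSeed(config@seed + 1L, {
    sim <- .simulateGenes(config, lib)
    placed <- .placeGenes(sim$genes, sim$groups, config)
    .writeDataset(placed, sim, config, lib, outdir)
  })
}

# Build every gene's sequences and truth attributes (no coordinates yet).
.simulateGenes <- function(config, lib) {
  nChrom <- config@nChromosomes
  genes <- list()      # list of single-gene records
  groups <- list()     # grouped placement units (arrays, blocks)
  addGene <- function(rec) {
    genes[[rec$gene_id]] <<- rec
    rec$gene_id
  }
  pprRecord <- function(id, arch, role, chrom) {
    asm <- assemblePprProtein(arch, lib)
    cdsBody <- .revTranslate(asm$seq)
    list(gene_id = id, chrom = chrom, role = role,
         architecture = paste(arch, collapse = ","),
         subfamily = .plantedSubfamily(arch),
         subgroup = .plantedSubgroup(arch),
         cds = paste0(cdsBody, "TAA"), protein = asm$seq,
         motif_coords = asm$coords,
         intron_count = .drawIntronCount(config@intronZeroProb),
         tandem_array = NA_character_, partner = NA_character_,
         dup_type = NA_character_, true_ks = NA_real_,
         true_omega = NA_real_, block_id = NA_character_)
  }
  bgRecord <- function(id, chrom, cds = NULL) {
    if (is.null(cds)) cds <- .randomCds(sample(120:300, 1L))
    list(gene_id = id, chrom = chrom, role = "background",
         architecture = NA_character_, subfamily = NA_character_,
         subgroup = NA_character_,
         cds = paste0(cds, "TAA"), protein = .translateCds(cds, FALSE),
         motif_coords = NULL,
         intron_count = .drawIntronCount(config@intronZeroProb),
         tandem_array = NA_character_, partner = NA_character_,
         dup_type = NA_character_, true_ks = NA_real_,
         true_omega = NA_real_, block_id = NA_character_)
  }

  # background genes
  for (ch in seq_len(nChrom))
    for (i in seq_len(config@backgroundGenesPerChrom))
      addGene(bgRecord(sprintf("bg%02d_%03d", ch, i),
                       sprintf("chr%d", ch)))

  # singleton PPR genes, cycled over chromosomes
  plan <- config@architecturePlan
  for (i in seq_along(plan)) {
    ch <- sprintf("chr%d", (i - 1L) %% nChrom + 1L)
    id <- addGene(pprRecord(sprintf("ppr_s%02d", i), plan[[i]],
                            "ppr_single", ch))
    groups[[length(groups) + 1L]] <- list(kind = "single", ids = id,
                                          chrom = ch)
  }

  # tandem arrays: members evolved from a common ancestor so co-members
  # are genuine duplicates
  arrayArchs <- list(rep("P", 9L),
                     c(rep(c("P", "L", "S"), 3L), "E"),
                     c(rep(c("P", "L", "S"), 3L), "E", "Eplus", "DYW"))
  for (ai in seq_along(config@tandemArraySizes)) {
    size <- config@tandemArraySizes[ai]
    arch <- arrayArchs[[(ai - 1L) %% length(arrayArchs) + 1L]]
    ch <- sprintf("chr%d", (ai - 1L) %% nChrom + 1L)
    arrId <- sprintf("tarr%02d", ai)
    anc <- pprRecord(sprintf("%s_m1", arrId), arch, "ppr_tandem", ch)
    anc$tandem_array <- arrId
    anc$dup_type <- "tandem"
    ids <- addGene(anc)
    ancBody <- sub("TAA$", "", anc$cds)
    for (m in 2:size) {
      memBody <- .evolveBranch(.cdsToCodonIdx(ancBody), 0.05,
                               0.2, config@kappa)$state
      mem <- anc
      mem$gene_id <- sprintf("%s_m%d", arrId, m)
      mem$cds <- paste0(.codonIdxToCds(memBody), "TAA")
      mem$protein <- .translateCds(.codonIdxToCds(memBody), FALSE)
      mem$intron_count <- .drawIntronCount(config@intronZeroProb)
      mem$partner <- if (m == 2L) ids[1L] else NA_character_
      ids <- c(ids, addGene(mem))
    }
    groups[[length(groups) + 1L]] <- list(kind = "array", ids = ids,
                                          chrom = ch, array_id = arrId)
  }

  # segmental pairs inside collinear blocks of duplicated background
  # anchors: block k puts its A side (anchors + one PPR duplicate) on
  # one chromosome and the B side, in the same order, on another.
  segArchIdx <- c(9L, 1L, 5L, 10L, 7L, 4L)
  ksPlan <- rep_len(config@segmentalKs, config@nSegmentalPairs)
  for (k in seq_len(config@nSegmentalPairs)) {
    chA <- (k - 1L) %% nChrom + 1L
    chB <- k %% nChrom + 1L
    if (chB == chA) chB <- chA %% nChrom + 1L
    blkId <- sprintf("blk%02d", k)
    arch <- plan[[segArchIdx[(k - 1L) %% length(segArchIdx) + 1L]]]
    pprAnc <- pprRecord(sprintf("ppr_seg%02d_a", k), arch, "ppr_segmental",
                        sprintf("chr%d", chA))
    pair <- evolveCdsPair(sub("TAA$", "", pprAnc$cds), ksPlan[k],
                          config@segmentalOmega, config@kappa)
    gA <- pprAnc
    gA$cds <- paste0(pair$cds_a, "TAA")
    gA$protein <- .translateCds(pair$cds_a, FALSE)
    gA$block_id <- blkId
    gB <- gA
    gB$gene_id <- sprintf("ppr_seg%02d_b", k)
    gB$chrom <- sprintf("chr%d", chB)
    gB$cds <- paste0(pair$cds_b, "TAA")
    gB$protein <- .translateCds(pair$cds_b, FALSE)
    gB$intron_count <- .drawIntronCount(config@intronZeroProb)
    gB$partner <- gA$gene_id
    gB$dup_type <- "segmental"
    gB$true_ks <- ksPlan[k]
    gB$true_omega <- config@segmentalOmega
    idA <- addGene(gA)
    idB <- addGene(gB)

    idsA <- character(0)
    idsB <- character(0)
    for (j in seq_len(config@blockAnchors)) {
      ancBody <- .randomCds(sample(120:300, 1L))
      apair <- evolveCdsPair(ancBody, 0.1, 0.3, config@kappa)
      ra <- bgRecord(sprintf("anc%02d_%02d_a", k, j),
                     sprintf("chr%d", chA), apair$cds_a)
      rb <- bgRecord(sprintf("anc%02d_%02d_b", k, j),
                     sprintf("chr%d", chB), apair$cds_b)
      ra$role <- "anchor"
      rb$role <- "anchor"
      ra$block_id <- blkId
      rb$block_id <- blkId
      rb$partner <- ra$gene_id
      rb$dup_type <- "anchor"
      idsA <- c(idsA, addGene(ra))
      idsB <- c(idsB, addGene(rb))
    }
    mid <- ceiling(config@blockAnchors / 2)
    orderA <- append(idsA, idA, after = mid)
    orderB <- append(idsB, idB, after = mid)
    groups[[length(groups) + 1L]] <-
      list(kind = "block_side", ids = orderA,
           chrom = sprintf("chr%d", chA), block_id = blkId)
    groups[[length(groups) + 1L]] <-
      list(kind = "block_side", ids = orderB,
           chrom = sprintf("chr%d", chB), block_id = blkId)
  }

  # plain background genes become their own placement units
  for (g in genes)
    if (g$role == "background")
      groups[[length(groups) + 1L]] <- list(kind = "single",
                                            ids = g$gene_id,
                                            chrom = g$chrom)
  list(genes = genes, groups = groups)
}

# Assign genomic coordinates: shuffle placement units per chromosome,
# walk a cursor with short gaps between ordinary genes, keep tandem
# co-members at the configured sub-100 kb spacing, and force >= 110 kb
# between PPR genes that are not co-members of the same array so that
# tandem detection recovers exactly the planted arrays.
.placeGenes <- function(genes, groups, config) {
  margin <- 110000
  cursor <- setNames(rep(50000, config@nChromosomes),
                     sprintf("chr%d", seq_len(config@nChromosomes)))
  lastPprEnd <- setNames(rep(-Inf, config@nChromosomes), names(cursor))
  placements <- list()

  placeOne <- function(g, start) {
    m <- g$intron_count
    L <- nchar(g$cds)
    sizes <- rep(3L, m + 1L)
    extra <- L - sum(sizes)
    if (m > 0L) {
      alloc <- as.vector(rmultinom(1L, extra, rep(1, m + 1L)))
      sizes <- sizes + alloc
    } else sizes <- L
    intrLen <- if (m > 0L) sample(100:500, m, replace = TRUE) else integer(0)
    exStart <- integer(m + 1L)
    exEnd <- integer(m + 1L)
    pos <- start
    for (e in seq_len(m + 1L)) {
      exStart[e] <- pos
      exEnd[e] <- pos + sizes[e] - 1L
      pos <- exEnd[e] + if (e <= m) intrLen[e] + 1L else 1L
    }
    strand <- sample(c("+", "-"), 1L)
    list(gene_id = g$gene_id, chrom = g$chrom, start = start,
         end = exEnd[m + 1L], strand = strand,
         exon_start = exStart, exon_end = exEnd)
  }

  for (grp in sample(seq_along(groups))) {
    u <- groups[[grp]]
    ch <- u$chrom
    ids <- u$ids
    spacing <- if (u$kind == "array") config@tandemSpacing else NA
    for (j in seq_along(ids)) {
      g <- genes[[ids[j]]]
      isPpr <- g$role != "background" && g$role != "anchor"
      start <- cursor[[ch]] + sample(2000:8000, 1L)
      if (u$kind == "array" && j > 1L)
        start <- cursor[[ch]] + spacing       # intergenic gap = spacing - 1
      else if (isPpr)
        start <- max(start, lastPprEnd[[ch]] + margin)
      p <- placeOne(g, as.integer(start))
      placements[[g$gene_id]] <- p
      cursor[[ch]] <- p$end
      if (isPpr) lastPprEnd[[ch]] <- p$end
    }
  }
  over <- names(cursor)[cursor > config@chromLength]
  if (length(over))
    stop("genes exceed chromosome length on: ",
         paste(over, collapse = ", "))
  placements
}

.writeDataset <- function(placements, sim, config, lib, outdir) {
  genes <- sim$genes
  ids <- names(placements)
  ord <- order(vapply(placements, `[[`, character(1), "chrom"),
               vapply(placements, `[[`, numeric(1), "start"))
  ids <- ids[ord]

  # chromosome sequences assembled from random filler + gene bodies
  chromNames <- sprintf("chr%d", seq_len(config@nChromosomes))
  chromSeq <- setNames(vector("list", length(chromNames)), chromNames)
  chromPos <- setNames(rep(0L, length(chromNames)), chromNames)
  for (id in ids) {
    p <- placements[[id]]
    g <- genes[[id]]
    ch <- p$chrom
    gap <- p$start - chromPos[[ch]] - 1L
    body <- .geneGenomicSeq(g, p)
    chromSeq[[ch]] <- c(chromSeq[[ch]], .randomDna(gap), body)
    chromPos[[ch]] <- p$end
  }
  for (ch in chromNames) {
    tail <- config@chromLength - chromPos[[ch]]
    chromSeq[[ch]] <- paste(c(chromSeq[[ch]], .randomDna(tail)),
                            collapse = "")
  }

  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gff = file.path(outdir, "genes.gff3"),
    proteins = file.path(outdir, "proteins.fa"),
    cds = file.path(outdir, "cds.fa"),
    domtbl = file.path(outdir, "motifs.domtblout"),
    similarity = file.path(outdir, "similarity.tsv"),
    truth = file.path(outdir, "truth.tsv"))

  writeFasta(DNAStringSet(unlist(chromSeq)), paths$genome)
  writeFasta(AAStringSet(setNames(
    vapply(ids, function(id) sub("\\*$", "", genes[[id]]$protein),
           character(1)), ids)), paths$proteins)
  writeFasta(DNAStringSet(setNames(
    vapply(ids, function(id) genes[[id]]$cds, character(1)), ids)),
    paths$cds)

  # GFF3
  feat <- do.call(rbind, lapply(ids, function(id) {
    p <- placements[[id]]
    tx <- paste0(id, ".1")
    nEx <- length(p$exon_start)
    rbind(
      data.frame(chrom = p$chrom, type = "gene", start = p$start,
                 end = p$end, strand = p$strand,
                 attributes = sprintf("ID=%s;Name=%s", id, id)),
      data.frame(chrom = p$chrom, type = "mRNA", start = p$start,
                 end = p$end, strand = p$strand,
                 attributes = sprintf("ID=%s;Parent=%s", tx, id)),
      data.frame(chrom = p$chrom, type = "exon", start = p$exon_start,
                 end = p$exon_end, strand = p$strand,
                 attributes = sprintf("ID=%s.exon%d;Parent=%s", tx,
                                      seq_len(nEx), tx)),
      data.frame(chrom = p$chrom, type = "CDS", start = p$exon_start,
                 end = p$exon_end, strand = p$strand,
                 attributes = sprintf("ID=%s.cds%d;Parent=%s", tx,
                                      seq_len(nEx), tx)))
  }))
  writeGff3(feat, paths$gff)

  # motif truth table: confident planted hits on PPR genes, marginal
  # two-point decoys (E-value 5.0) on a few background genes
  hitRows <- list()
  for (id in ids) {
    g <- genes[[id]]
    if (is.null(g$motif_coords)) next
    co <- g$motif_coords
    prof <- ifelse(co$motif_class %in% c(.REPEAT_CLASSES, .CTERM_CLASSES,
                                         "PPR_generic"),
                   paste0("PPR_", co$motif_class), co$motif_class)
    prof[co$motif_class == "PPR_generic"] <- "PPR"
    hitRows[[id]] <- data.frame(protein_id = id, profile = prof,
                                start = co$start, end = co$end,
                                score = 55.0, evalue = 1e-10)
  }
  bgIds <- ids[vapply(ids, function(id)
    genes[[id]]$role == "background", logical(1))]
  decoy2 <- head(bgIds, 3L)                 # two marginal repeat hits
  decoy1 <- head(setdiff(bgIds, decoy2), 3L)  # one marginal hit
  for (id in decoy2) {
    len <- nchar(genes[[id]]$protein)
    hitRows[[paste0(id, "_d")]] <- data.frame(
      protein_id = id, profile = "PPR_P",
      start = c(5L, 60L), end = c(39L, 94L),
      score = 6.0, evalue = 5.0)
  }
  for (id in decoy1)
    hitRows[[paste0(id, "_d")]] <- data.frame(
      protein_id = id, profile = "PPR_P", start = 10L, end = 44L,
      score = 6.0, evalue = 5.0)
  writeDomtblout(do.call(rbind, hitRows), paths$domtbl)

  # similarity table
  simRows <- list()
  addHit <- function(q, s, ev, ident = 90) {
    la <- nchar(genes[[q]]$protein)
    simRows[[length(simRows) + 1L]] <<- data.frame(
      query_id = q, subject_id = s, pct_identity = ident,
      aln_length = la, mismatches = round(la * (100 - ident) / 100),
      gap_opens = 0L, q_start = 1L, q_end = la, s_start = 1L,
      s_end = nchar(genes[[s]]$protein), evalue = ev,
      bitscore = round(50 - 10 * log10(ev + 1e-300)))
  }
  addPair <- function(a, b, ev, ident = 90) {
    addHit(a, b, ev, ident)
    addHit(b, a, ev, ident)
  }
  for (id in ids) addHit(id, id, 0)
  for (id in ids) {
    g <- genes[[id]]
    if (!is.na(g$partner) && g$dup_type %in% c("segmental", "anchor"))
      addPair(id, g$partner, 1e-80, 85)
  }
  # full pairwise hits inside each tandem array
  arrKey <- vapply(ids, function(id) {
    a <- genes[[id]]$tandem_array
    if (is.na(a)) "" else a
  }, character(1))
  arrays <- split(ids[arrKey != ""], arrKey[arrKey != ""])
  for (mem in arrays) {
    if (length(mem) < 2L) next
    cmb <- utils::combn(mem, 2L)
    for (q in seq_len(ncol(cmb))) addPair(cmb[1L, q], cmb[2L, q], 1e-100, 92)
  }
  # decoy similarity below the 1e-5 candidate threshold
  pprIds <- ids[vapply(ids, function(id)
    startsWith(genes[[id]]$role, "ppr"), logical(1))]
  for (q in head(pprIds, 8L))
    addPair(q, bgIds[match(q, pprIds)], 1e-3, 35)
  writeSimilarityTab(do.call(rbind, simRows), paths$similarity)

  # truth table
  truth <- do.call(rbind, lapply(ids, function(id) {
    g <- genes[[id]]
    p <- placements[[id]]
    data.frame(gene_id = id, chrom = p$chrom, start = p$start,
               end = p$end, strand = p$strand, role = g$role,
               architecture = g$architecture, subfamily = g$subfamily,
               subgroup = g$subgroup, intron_count = g$intron_count,
               tandem_array = g$tandem_array, partner = g$partner,
               dup_type = g$dup_type, true_ks = g$true_ks,
               true_omega = g$true_omega, block_id = g$block_id)
  }))
  write.table(truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(list(paths = paths, truth = truth, library = lib,
                 config = config))
}

# Genomic (plus-strand) sequence of one gene: exon chunks of the
# genomic-oriented CDS interleaved with random introns. For minus-strand
# genes the spliced plus-strand exon concatenation is the reverse
# complement of the CDS.
.geneGenomicSeq <- function(g, p) {
  oriented <- if (p$strand == "+") g$cds else .revcomp(g$cds)
  sizes <- p$exon_end - p$exon_start + 1L
  stopifnot(sum(sizes) == nchar(oriented))
  off <- cumsum(c(0L, sizes))
  parts <- character(0)
  for (e in seq_along(sizes)) {
    parts <- c(parts, substr(oriented, off[e] + 1L, off[e + 1L]))
    if (e < length(sizes)) {
      ilen <- p$exon_start[e + 1L] - p$exon_end[e] - 1L
      parts <- c(parts, .randomDna(ilen))
    }
  }
  paste(parts, collapse = "")
}

#' Mirror a dataset's PPR genes as a second, orthologous species
#'
#' Builds the cross-species inputs for reciprocal-best-hit orthology and
#' synteny tabulation: every PPR gene of the source dataset gets a 1:1
#' ortholog in a pseudo-species whose chromosomes follow `chromMap`, and
#' both directions of similarity hits are emitted (strong mutual best
#' hits plus weaker second-best decoys).
#'
#' @param truth Truth table from [generateDataset()].
#' @param chromMap Named character vector mapping source chromosome
#'   names to target chromosome names.
#' @param prefix Prefix for ortholog gene ids.
#' @return List with `hits_ab`, `hits_ba` (similarity data.frames),
#'   `chrom_a`, `chrom_b` (named gene-to-chromosome maps) and
#'   `ortholog_map` (named vector, source gene -> ortholog id).
#' @export
mirrorOrthologSpecies <- function(truth, chromMap, prefix = "orth_") {
  ppr <- truth[startsWith(truth$role, "ppr"), ]
  if (!all(ppr$chrom %in% names(chromMap)))
    stop("chromMap must cover every chromosome carrying a PPR gene")
  orth <- setNames(paste0(prefix, ppr$gene_id), ppr$gene_id)
  mkHit <- function(q, s, ev)
    data.frame(query_id = q, subject_id = s, pct_identity = 88,
               aln_length = 400L, mismatches = 48L, gap_opens = 0L,
               q_start = 1L, q_end = 400L, s_start = 1L, s_end = 400L,
               evalue = ev, bitscore = round(50 - 10 * log10(ev + 1e-300)))
  ab <- mkHit(ppr$gene_id, unname(orth), 1e-80)
  ba <- mkHit(unname(orth), ppr$gene_id, 1e-80)
  # weaker cross hits so best-hit selection is actually exercised
  if (nrow(ppr) > 1L) {
    shifted <- unname(orth)[c(2:nrow(ppr), 1L)]
    ab <- rbind(ab, mkHit(ppr$gene_id, shifted, 1e-20))
    ba <- rbind(ba, mkHit(shifted, ppr$gene_id, 1e-20))
  }
  list(hits_ab = ab, hits_ba = ba,
       chrom_a = setNames(ppr$chrom, ppr$gene_id),
       chrom_b = setNames(unname(chromMap[ppr$chrom]), unname(orth)),
       ortholog_map = orth)
}
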