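# End-to-end convenience wrapper: from annotation + motif + similarity
# files to identification, classification, census, structure statistics
# and duplication calls.

#' Run the full PPR family analysis on one genome
#'
#' Reads the gene annotation, motif hits and all-vs-all similarity
#' table, then runs the whole identification pipeline: E-value
#' screening, PPR identification, architecture chaining and
#' subfamily/subgroup classification, the family census, intron and
#' chromosomal statistics, tandem-array detection, and segmental
#' duplication calling on collinear blocks.
#'
#' @param gff Path to the GFF3 annotation.
#' @param domtbl Path to the motif domain table (domtblout dialect).
#' @param similarity Path to the 12-column similarity table, or `NULL`
#'   to skip duplication analysis.
#' @param params A [ScanParams].
#' @param species Label used in the census.
#' @param nameMap Profile-name map for [readDomtblout()].
#' @return List with elements `models` ([GeneModels]), `hits` (screened
#'   motif hits), `ppr_ids`, `calls`, `census`, `intron_bins`,
#'   `chrom_distribution`, `tandem_arrays`, `candidates`, `blocks`,
#'   `segmental_pairs`.
#' @export
analyzePprGenome <- function(gff, domtbl, similarity = NULL,
                             params = ScanParams(), species = "genome",
                             nameMap = defaultMotifNameMap()) {
  models <- readGff3(gff)
  hits <- filterHits(readDomtblout(domtbl, nameMap), params)
  pprIds <- identifyPprProteins(hits, params)
  calls <- classifyProteins(hits[hits$protein_id %in% pprIds, ,
                                 drop = FALSE], params)
  census <- pprCensus(calls, species)
  geneTab <- as.data.frame(models)
  pprTab <- geneTab[geneTab$gene_id %in% pprIds, , drop = FALSE]
  introns <- countIntrons(models)
  res <- list(models = models, hits = hits, ppr_ids = pprIds,
              calls = calls, census = census,
              intron_bins = intronBins(unname(introns[pprTab$gene_id])),
              chrom_distribution = chromosomeDistribution(pprTab),
              tandem_arrays = findTandemArrays(pprTab),
              candidates = NULL, blocks = NULL, segmental_pairs = NULL)
  if (!is.null(similarity)) {
    simHits <- readSimilarityTab(similarity)
    allPairs <- topHitsFilter(simHits)
    ranks <- geneRanks(geneTab)
    coll <- detectCollinearBlocks(allPairs, ranks)
    cand <- allPairs[allPairs$gene_a %in% pprIds &
                       allPairs$gene_b %in% pprIds, , drop = FALSE]
    res$candidates <- cand
    res$blocks <- coll$blocks
    res$segmental_pairs <- callSegmentalPairs(cand, coll$blocks, ranks,
                                              res$tandem_arrays)
  }
  res
}
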