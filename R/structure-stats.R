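# Gene-structure statistics: intron counts from the representative
# transcript, intron-count bins, and chromosomal distribution.

#' Intron counts from representative transcripts
#'
#' The intron count of a gene is the exon count of its representative
#' transcript minus one; intron-rich plant PPR genes reach 26 introns,
#' but most have none.
#'
#' @param genes A [GeneModels] object.
#' @return Named integer vector of intron counts (one per gene).
#' @export
countIntrons <- function(genes) {
  stopifnot(is(genes, "GeneModels"))
  repTx <- representativeTx(genes)
  n <- vapply(repTx, function(tx) length(genes@exons[[tx]]), integer(1))
  if (any(n == 0L))
    stop("representative transcript with zero exons for gene(s): ",
         paste(names(repTx)[n == 0L], collapse = ", "))
  setNames(n - 1L, names(repTx))
}

#' Intron-count bin summary
#'
#' Bins genes by intron count into the conventional survey bins
#' 0, 1, 2-5 and >= 6 introns, with counts and two-decimal percentages
#' (summing to 100 within rounding).
#'
#' @param genes A [GeneModels] object or an integer vector of intron
#'   counts.
#' @return data.frame with columns `bin`, `count`, `percentage` plus an
#'   attribute `total`.
#' @export
intronBins <- function(genes) {
  counts <- if (is(genes, "GeneModels")) countIntrons(genes)
            else as.integer(genes)
  total <- length(counts)
  bins <- c(`0` = sum(counts == 0L), `1` = sum(counts == 1L),
            `2-5` = sum(counts >= 2L & counts <= 5L),
            `>=6` = sum(counts >= 6L))
  pct <- if (total) categoryPercentage(unname(bins), total) else rep(0, 4L)
  out <- data.frame(bin = names(bins), count = unname(bins),
                    percentage = pct)
  attr(out, "total") <- total
  out
}

#' Per-chromosome gene counts and percentages
#'
#' @param genes A [GeneModels] object or a gene table with columns
#'   `gene_id`, `chrom`.
#' @return data.frame `chrom`, `count`, `percentage` (two decimals),
#'   sorted by chromosome; zero rows for empty input.
#' @export
chromosomeDistribution <- function(genes) {
  tab <- .geneTable(genes)
  if (!nrow(tab))
    return(data.frame(chrom = character(), count = integer(),
                      percentage = numeric()))
  counts <- table(tab$chrom)
  data.frame(chrom = names(counts), count = as.integer(counts),
             percentage = categoryPercentage(as.integer(counts),
                                             nrow(tab)),
             row.names = NULL)
}
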