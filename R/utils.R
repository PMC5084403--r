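# Shared internal helpers.

# Half-away-from-zero rounding; base round() rounds half to even, which is
# not how gene-family surveys print percentages.
roundHalfUp <- function(x, digits = 2L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage of a category, rounded to two decimals
#'
#' Computes `100 * k / n` rounded half-away-from-zero to two decimal
#' places, the form in which family surveys print category fractions
#' (e.g. 382 intronless genes of 486 gives 78.60).
#'
#' @param k Count in the category (`0 <= k <= n`).
#' @param n Total count (`> 0`).
#' @return Numeric percentage with two decimals.
#' @examples
#' categoryPercentage(382, 486)  # 78.60
#' categoryPercentage(112, 243)  # 46.09
#' @export
categoryPercentage <- function(k, n) {
  if (length(n) != 1L || !is.finite(n) || n <= 0)
    stop("'n' must be a single positive count")
  if (any(k < 0) || any(k > n))
    stop("'k' must satisfy 0 <= k <= n")
  roundHalfUp(100 * k / n, 2L)
}

# Run expr with a private RNG stream, restoring the caller's stream after.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

.MOTIF_LENGTHS <- c(P = 35L, L = 36L, S = 31L, L2 = 35L, E = 34L,
                    Eplus = 31L, DYW = 94L, RRM = 80L, LAGLIDADG = 60L,
                    SMR = 85L)

# Repeat-forming motif classes; presence of L/S/L2 defines the PLS subfamily.
.REPEAT_CLASSES <- c("P", "L", "S", "L2")
.CTERM_CLASSES  <- c("E", "Eplus", "DYW")
.AUX_CLASSES    <- c("RRM", "LAGLIDADG", "SMR", "other")
.MOTIF_CLASSES  <- c(.REPEAT_CLASSES, .CTERM_CLASSES,
                     "PPR_generic", "RRM", "LAGLIDADG", "SMR", "other")
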