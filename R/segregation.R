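#' Chi-square goodness-of-fit test for Mendelian segregation
#'
#' Tests observed phenotype counts against an expected Mendelian ratio with
#' the uncorrected Pearson chi-square statistic (no Yates continuity
#' correction): expected_i = total * ratio_i / sum(ratio), chi2 =
#' sum((obs_i - exp_i)^2 / exp_i), and p the upper tail of the chi-square
#' distribution with classes - 1 degrees of freedom.
#'
#' @param observed non-negative integer counts per phenotype class (a named
#'   vector such as `c(AB = 80, B = 28)`); total must be positive.
#' @param ratio positive integers of the expected ratio, same length and
#'   order as `observed` (e.g. `c(3, 1)` for dominant selfing).
#' @return a [SegregationTest-class].
#' @examples
#' chiSquareSegregation(c(AB = 80, B = 28), c(3, 1))
#' @export
chiSquareSegregation <- function(observed, ratio) {
  if (length(observed) != length(ratio))
    stop("observed and ratio must have the same number of classes")
  if (length(observed) < 2L)
    stop("at least two phenotype classes required")
  if (any(observed < 0) || sum(observed) <= 0)
    stop("observed counts must be non-negative with a positive total")
  if (any(ratio <= 0))
    stop("ratio terms must be positive")
  total <- sum(observed)
  expected <- total * ratio / sum(ratio)
  if (any(expected == 0)) stop("expected count of zero")
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  observed <- stats::setNames(as.numeric(observed), names(observed))
  new("SegregationTest", observed = observed, ratio = as.numeric(ratio),
      expected = expected, chi2 = chi2, df = df, p = p)
}

setMethod("show", "SegregationTest", function(object) {
  k <- length(object@observed)
  nm <- names(object@observed)
  if (is.null(nm)) nm <- paste0("class", seq_len(k))
  cat("Mendelian segregation chi-square test\n")
  cat("  ratio   :", paste(object@ratio, collapse = ":"), "\n")
  cat("  observed:", paste(sprintf("%s=%g", nm, object@observed), collapse = ", "),
      sprintf(" (total %g)\n", sum(object@observed)))
  cat("  expected:", paste(sprintf("%.2f", object@expected), collapse = ", "), "\n")
  cat(sprintf("  chi2 = %.4g, df = %d, p = %.4g\n",
              object@chi2, object@df, object@p))
})

#' @describeIn chiSquareSegregation statistic accessor.
#' @param x a `SegregationTest`.
#' @export
segChi2 <- function(x) x@chi2

#' @describeIn chiSquareSegregation p-value accessor.
#' @export
segP <- function(x) x@p
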