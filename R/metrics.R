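#' Prediction-accuracy metrics
#'
#' The standard performance measures for age prediction models, all in
#' years on the input scale:
#' \describe{
#'   \item{`mad_error()`}{mean absolute deviation, `mean(|predicted -
#'     chronological|)`.}
#'   \item{`see_error()`}{standard error of the estimate,
#'     `sqrt(sum((predicted - chronological)^2) / denom)`. The default
#'     denominator is `n` (the RMSE form: the clocks are applied
#'     out-of-sample, so no degrees of freedom are spent); `n - 2` is the
#'     regression-residual convention.}
#'   \item{`pcp()`}{percentage of correct predictions: percent of samples
#'     with `|predicted - chronological| <= threshold` (boundary
#'     inclusive).}
#'   \item{`pearson_r()`}{Pearson product-moment correlation after pairwise
#'     removal of missing values.}
#' }
#' For any data `mad_error(p, c) <= see_error(p, c, "n")` (mean-absolute vs
#' root-mean-square inequality).
#'
#' @param predicted,chronological Numeric vectors of equal length, years.
#' @param denominator `"n"` (default) or `"n_minus_2"`.
#' @param threshold Positive error tolerance in years.
#' @return A single number (years, percent, or correlation).
#' @name accuracy_metrics
#' @examples
#' mad_error(c(22, 36, 56), c(24, 32, 50))   # mean of 2, 4, 6
#' see_error(c(23, 26), c(20, 30))           # sqrt(25/2)
#' pcp(c(20, 25, 30), c(25, 25, 25), threshold = 5)
NULL

.check_pair <- function(predicted, chronological, min_n = 1L) {
  if (length(predicted) != length(chronological)) {
    stop("predicted and chronological must have equal length")
  }
  keep <- !is.na(predicted) & !is.na(chronological)
  if (sum(keep) < min_n) {
    stop("need at least ", min_n, " complete prediction pairs, got ",
         sum(keep))
  }
  list(p = predicted[keep], c = chronological[keep])
}

#' @rdname accuracy_metrics
#' @export
mad_error <- function(predicted, chronological) {
  v <- .check_pair(predicted, chronological)
  mean(abs(v$p - v$c))
}

#' @rdname accuracy_metrics
#' @export
see_error <- function(predicted, chronological,
                      denominator = c("n", "n_minus_2")) {
  denominator <- match.arg(denominator)
  v <- .check_pair(predicted, chronological)
  n <- length(v$p)
  denom <- if (denominator == "n") n else n - 2L
  if (denom <= 0) {
    stop("SEE with denominator n - 2 needs at least 3 pairs, got ", n)
  }
  sqrt(sum((v$p - v$c)^2) / denom)
}

#' @rdname accuracy_metrics
#' @export
pcp <- function(predicted, chronological, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  v <- .check_pair(predicted, chronological)
  100 * mean(abs(v$p - v$c) <= threshold)
}

#' @rdname accuracy_metrics
#' @param x,y Numeric vectors for `pearson_r()`.
#' @export
pearson_r <- function(x, y) {
  v <- .check_pair(x, y, min_n = 3L)
  if (stats::sd(v$p) == 0 || stats::sd(v$c) == 0) {
    stop("correlation undefined: constant vector")
  }
  stats::cor(v$p, v$c, method = "pearson")
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of most
#' printed tables), unlike `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
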