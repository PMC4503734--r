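# Chi-squared goodness-of-fit and paired t tests with the df conventions
# used throughout the analysis: k categories -> df = k - 1 even when the
# expected counts do not sum to the observed total (unnormalised
# expectations), and paired t with df = n - 1, two-sided p.

#' Chi-squared goodness of fit against fixed expectations
#'
#' Pearson statistic `sum((O - E)^2 / E)` with `df = k - 1` and an
#' upper-tail p-value. The expected vector is used as supplied — it need
#' not sum to the observed total (e.g. three-band expectations summing to
#' 0.95 of the total give a df = 2 test). No continuity correction.
#'
#' @param observed non-negative count vector (length k >= 2).
#' @param expected positive real vector of the same length.
#' @return an object of class `"chisq_gof"`: list with `statistic`, `df`,
#'   `p`, `observed`, `expected`.
#' @examples
#' chisq_gof(c(30, 10, 10), c(25, 12.5, 10))  # X2 = 1.5, df = 2
#' @export
chisq_gof <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected lengths differ", call. = FALSE)
  if (length(observed) < 2L)
    stop("need at least 2 categories", call. = FALSE)
  if (any(!is.finite(expected)) || any(expected <= 0))
    stop("expected counts must all be positive", call. = FALSE)
  if (any(!is.finite(observed)) || any(observed < 0))
    stop("observed counts must be non-negative", call. = FALSE)
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = observed, expected = expected),
            class = "chisq_gof")
}

#' @export
print.chisq_gof <- function(x, ...) {
  cat(sprintf("Chi-squared goodness of fit: X2 = %.3f, df = %d, P = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Paired t test
#'
#' Two-sided paired t on differences `d = x - y`: `t = mean(d) /
#' (sd(d) / sqrt(n))` with the sample (n - 1) standard deviation and
#' `df = n - 1`. All-zero differences give `t = 0, p = 1`; zero variance
#' with a non-zero mean is a degenerate-variance error.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return an object of class `"paired_t"`: list with `t`, `df`, `p`, `n`,
#'   `mean_diff`.
#' @examples
#' paired_t(c(1, 2, 3), c(0, 0, 0))  # t = 3.4641, df = 2
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (any(!is.finite(d))) stop("non-finite differences", call. = FALSE)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) {
      return(structure(list(t = 0, df = n - 1L, p = 1, n = n, mean_diff = 0),
                       class = "paired_t"))
    }
    stop("zero variance of differences with non-zero mean", call. = FALSE)
  }
  tval <- m / (s / sqrt(n))
  structure(list(t = tval, df = n - 1L,
                 p = 2 * stats::pt(abs(tval), n - 1L, lower.tail = FALSE),
                 n = n, mean_diff = m),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.3f, df = %d, P = %.4g (n = %d, mean diff = %.3f)\n",
              x$t, x$df, x$p, x$n, x$mean_diff))
  invisible(x)
}

#' Closed-form power of a two-sided paired t test
#'
#' Noncentral-t power for detecting a mean paired difference `delta` when
#' the differences have standard deviation `sd_diff`.
#'
#' @param delta true mean difference.
#' @param sd_diff standard deviation of the paired differences.
#' @param n number of pairs.
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @export
paired_t_power <- function(delta, sd_diff, n, alpha = 0.05) {
  ncp <- abs(delta) / (sd_diff / sqrt(n))
  crit <- stats::qt(1 - alpha / 2, n - 1)
  stats::pt(crit, n - 1, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-crit, n - 1, ncp = ncp, lower.tail = TRUE)
}

#' Percentage share of a count within a total
#'
#' Report utility for simple printed-count arithmetic, e.g. the share of
#' loud-calls attributable to subordinates, as a percentage.
#'
#' @param count numerator count.
#' @param total denominator count (> 0).
#' @return `100 * count / total`.
#' @examples
#' percent_share(249, 1044)  # 23.85...
#' @export
percent_share <- function(count, total) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  100 * count / total
}
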