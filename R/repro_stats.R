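# Agreement and variability statistics: Bland-Altman, interscan coefficient
# of variation, normal tolerance intervals, paired comparisons.

#' Bland-Altman agreement analysis
#'
#' Bias (mean paired difference) and 95% limits of agreement
#' (bias +/- 1.96 x sample SD of the differences) for paired measurements.
#'
#' @param x,y paired measurements of equal length, n >= 2.
#' @return list with \code{bias}, \code{loa_low}, \code{loa_high},
#'   \code{sd_diff}, \code{pearson_r}, \code{n}.
#' @examples
#' bland_altman(c(50, 55, 60), c(49, 56, 59))
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 2) stop("need n >= 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  r <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else
    NA_real_
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, pearson_r = r, n = length(x))
}

#' Interscan coefficient of variation
#'
#' Test-retest variability defined as the ratio of the standard deviation of
#' the interscan difference to the mean of the measurement:
#' \code{100 * SD(scan1 - scan2) / mean(c(scan1, scan2))}. The pooled mean of
#' both scans is used as "the mean of the measurement" (switchable to the
#' first scan's mean).
#'
#' @param scan1,scan2 per-subject values from the two visits, paired.
#' @param mean_of one of \code{"pooled"} (default) or \code{"scan1"}.
#' @return CoV in percent (>= 0).
#' @export
cov_interscan <- function(scan1, scan2, mean_of = c("pooled", "scan1")) {
  mean_of <- match.arg(mean_of)
  if (length(scan1) != length(scan2)) stop("scans must be paired")
  if (length(scan1) < 2) stop("need n >= 2 pairs")
  m <- if (mean_of == "pooled") mean(c(scan1, scan2)) else mean(scan1)
  if (m <= 0) stop("mean measurement must be positive")
  100 * stats::sd(scan1 - scan2) / m
}

#' Two-sided normal tolerance factor
#'
#' Factor k such that \code{mean +/- k * SD} of a normal sample of size n is
#' a two-sided tolerance interval containing at least \code{coverage} of the
#' population with probability \code{confidence}. Computed with the
#' Howe/Wald-Wolfowitz approximation using the exact chi-square quantile,
#' \deqn{k = z_{(1+P)/2} \sqrt{\nu (1 + 1/n) / \chi^2_{1-\gamma,\nu}},}
#' accurate to better than 1% for n >= 10. As n grows, k decreases toward
#' the known-parameter normal quantile.
#'
#' @param n sample size (>= 2).
#' @param coverage population proportion P in (0, 1).
#' @param confidence confidence level gamma in (0, 1).
#' @return the factor k.
#' @export
tolerance_factor <- function(n, coverage = 0.90, confidence = 0.95) {
  if (n < 2) stop("need n >= 2")
  if (coverage <= 0 || coverage >= 1 || confidence <= 0 || confidence >= 1)
    stop("coverage and confidence must be in (0, 1)")
  z <- stats::qnorm((1 + coverage) / 2)
  nu <- n - 1
  z * sqrt(nu * (1 + 1 / n) / stats::qchisq(1 - confidence, nu))
}

#' Normal tolerance interval
#'
#' Two-sided interval covering a stated fraction of a normal population.
#' With known parameters (\code{known_params = TRUE}) the interval is
#' \code{mean +/- z * SD} with z the (1 + coverage)/2 normal quantile and
#' covers exactly \code{coverage} of the distribution. From a sample, the
#' interval is \code{mean(x) +/- k * sd(x)} with the tolerance factor
#' \code{\link{tolerance_factor}}, and covers at least \code{coverage} of the
#' population with probability \code{confidence}.
#'
#' @param x sample vector (when \code{known_params = FALSE}, n >= 2), or,
#'   when \code{known_params = TRUE}, a vector \code{c(mean, sd)}.
#' @param coverage population proportion to cover.
#' @param confidence confidence level (ignored when parameters are known).
#' @param known_params TRUE if \code{x} holds the true mean and SD.
#' @return numeric \code{c(low, high)} with attributes \code{"k"},
#'   \code{"coverage"}, \code{"confidence"}.
#' @examples
#' tolerance_interval(c(55, 5), known_params = TRUE)   # mean +/- 1.645 SD
#' @export
tolerance_interval <- function(x, coverage = 0.90, confidence = 0.95,
                               known_params = FALSE) {
  if (coverage <= 0 || coverage >= 1 || confidence <= 0 || confidence >= 1)
    stop("coverage and confidence must be in (0, 1)")
  if (known_params) {
    if (length(x) != 2) stop("known_params: x must be c(mean, sd)")
    if (x[2] < 0) stop("sd must be >= 0")
    k <- stats::qnorm((1 + coverage) / 2)
    m <- x[1]; s <- x[2]
  } else {
    if (length(x) < 2) stop("need a sample of n >= 2")
    k <- tolerance_factor(length(x), coverage, confidence)
    m <- mean(x); s <- stats::sd(x)
  }
  out <- c(low = m - k * s, high = m + k * s)
  attr(out, "k") <- k
  attr(out, "coverage") <- coverage
  attr(out, "confidence") <- confidence
  out
}

#' Paired comparison with confidence interval
#'
#' Paired t machinery for the package's comparison tables: mean difference,
#' 95% confidence interval, t statistic and p value. Zero-variance
#' differences are reported as the degenerate boundary case (CI collapsed on
#' the mean difference; p = 0 for a nonzero difference, 1 otherwise) rather
#' than as an error.
#'
#' @param x,y paired measurements, n >= 2.
#' @param conf_level confidence level of the CI.
#' @return list with \code{mean_difference}, \code{ci}, \code{t_statistic},
#'   \code{p_value}, \code{n}.
#' @export
paired_compare <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 2) stop("need n >= 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    m <- mean(d)
    return(list(mean_difference = m, ci = c(m, m),
                t_statistic = if (m == 0) 0 else Inf * sign(m),
                p_value = if (m == 0) 1 else 0, n = n))
  }
  tt <- stats::t.test(x, y, paired = TRUE, conf.level = conf_level)
  list(mean_difference = unname(tt$estimate), ci = as.numeric(tt$conf.int),
       t_statistic = unname(tt$statistic), p_value = tt$p.value, n = n)
}

#' Regression of segmental T2 on wall thickness and motion
#'
#' Plumbing for the mechanism analysis: an ordinary multiple linear
#' regression of segmental T2 (or T2 bias) on wall thickness, diastolic
#' motion, and their interaction, returning the fitted \code{lm} object. Used
#' to check the sign pattern (thinner walls and more motion raise apparent
#' T2).
#'
#' @param data data.frame with columns \code{t2_ms}, \code{thickness_mm},
#'   \code{motion_mm}.
#' @return an \code{lm} fit of
#'   \code{t2_ms ~ thickness_mm * motion_mm}.
#' @export
t2_bias_regression <- function(data) {
  stopifnot(all(c("t2_ms", "thickness_mm", "motion_mm") %in% names(data)))
  stats::lm(t2_ms ~ thickness_mm * motion_mm, data = data)
}
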