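# Resampling machinery: pooled-bootstrap group-difference tests, percentile
# confidence intervals, and Benjamini-Hochberg multiple-testing correction.

stat_fun <- function(stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (stat == "median") stats::median else mean
}

#' Bootstrap test for a difference of medians (or means) between two groups
#'
#' Builds the null by resampling from the pooled groups at the original
#' group sizes and compares the observed difference against the null
#' distribution of resampled differences. Two-sided by default; the
#' one-sided variant counts only null differences at or above the observed
#' one.
#'
#' @param a,b numeric samples (each >= 2 values).
#' @param stat \code{"median"} or \code{"mean"}.
#' @param n_boot null resamples (default 10000).
#' @param seed integer seed.
#' @param alternative \code{"two.sided"} (default) or \code{"greater"}.
#' @return object of class \code{bootstrap_result}: observed_stat (the
#'   difference a - b), p_value (resolution floor 1/n_boot), ci_low/ci_high
#'   (95 percent percentile CI of the difference under resampling within
#'   groups), n_boot, seed.
#' @export
bootstrap_group_difference <- function(a, b, stat = c("median", "mean"),
                                       n_boot = 10000, seed = 1,
                                       alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  f <- stat_fun(stat)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 samples")
  obs <- f(a) - f(b)
  pool <- sort(c(a, b))
  na <- length(a); nb <- length(b)
  # canonical group order so the resampling stream (hence the two-sided p)
  # is identical under swapping a and b; sgn maps back to the a - b scale
  key <- function(g) paste(c(length(g), sort(g)), collapse = ",")
  sgn <- if (key(a) <= key(b)) 1 else -1
  n1 <- if (sgn == 1) na else nb
  n2 <- if (sgn == 1) nb else na
  set.seed(seed)
  null_diff <- sgn * vapply(seq_len(n_boot), function(i) {
    f(sample(pool, n1, replace = TRUE)) - f(sample(pool, n2, replace = TRUE))
  }, numeric(1))
  exceed <- if (alternative == "two.sided") sum(abs(null_diff) >= abs(obs))
            else sum(null_diff >= obs)
  # within-group resampling for the CI of the observed difference
  ci_diff <- vapply(seq_len(n_boot), function(i) {
    f(sample(a, na, replace = TRUE)) - f(sample(b, nb, replace = TRUE))
  }, numeric(1))
  ci <- stats::quantile(ci_diff, c(0.025, 0.975), names = FALSE)
  structure(list(observed_stat = obs, p_value = max(exceed, 1L) / n_boot,
                 ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
                 seed = seed, stat = match.arg(stat),
                 alternative = alternative),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> diff of %ss = %.4g, p = %.4g (%s), 95%% CI [%.4g, %.4g]\n",
              x$stat, x$observed_stat, x$p_value, x$alternative,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Percentile bootstrap confidence interval of a statistic
#'
#' @param x numeric sample (>= 2 values).
#' @param stat \code{"median"} or \code{"mean"}.
#' @param n_boot resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return numeric vector c(low, high).
#' @export
bootstrap_ci <- function(x, stat = c("median", "mean"), n_boot = 10000,
                         level = 0.95, seed = 1) {
  f <- stat_fun(stat)
  if (length(x) < 2) stop("need at least 2 samples")
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i)
    f(sample(x, length(x), replace = TRUE)), numeric(1))
  a <- (1 - level) / 2
  stats::quantile(boot, c(a, 1 - a), names = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up procedure at rate \code{q}; adjusted values are the BH
#' adjustments of \code{stats::p.adjust}.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param q target false discovery rate (default 0.05).
#' @return list with \code{adjusted} p-values and logical \code{rejected}
#'   flags, in input order.
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}
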