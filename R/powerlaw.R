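# Maximum-likelihood power-law fitting with Kolmogorov-Smirnov bootstrap
# plausibility (Clauset-style), for continuous injury areas and discrete
# in-degrees, plus box-counting fractal dimension of injury masks.

# Hurwitz zeta sum_{k>=0} (q+k)^(-a) via direct terms plus an
# Euler-Maclaurin tail; accurate to ~1e-10 for a > 1.05.
hurwitz_zeta <- function(a, q, nterms = 20) {
  k <- 0:(nterms - 1)
  head <- sum((q + k)^(-a))
  N <- q + nterms
  head + N^(1 - a) / (a - 1) + N^(-a) / 2 + a * N^(-a - 1) / 12 -
    a * (a + 1) * (a + 2) * N^(-a - 3) / 720
}

# Discrete power-law CDF P(X <= x) for support {xmin, xmin+1, ...}.
dpl_cdf <- function(x, alpha, xmin) {
  z0 <- hurwitz_zeta(alpha, xmin)
  vapply(x, function(xi) 1 - hurwitz_zeta(alpha, floor(xi) + 1) / z0, numeric(1))
}

# KS distance of a sample (>= xmin) against the fitted model.
ks_distance <- function(x, alpha, xmin, variant) {
  x <- sort(x)
  n <- length(x)
  if (variant == "continuous") {
    cdf <- 1 - (x / xmin)^(1 - alpha)
    max(abs(cdf - (seq_len(n) - 1) / n), abs(cdf - seq_len(n) / n))
  } else {
    ux <- unique(x)
    cdf_hi <- dpl_cdf(ux, alpha, xmin)
    cdf_lo <- dpl_cdf(ux - 1, alpha, xmin)   # model CDF just below each jump
    ecdf_hi <- cumsum(tabulate(match(x, ux))) / n      # ECDF at ux (right side)
    ecdf_lo <- c(0, ecdf_hi[-length(ecdf_hi)])
    max(abs(cdf_hi - ecdf_hi), abs(cdf_lo - ecdf_lo))
  }
}

# Closed-form start value for the discrete exponent (Clauset's
# approximation): 1 + n / sum log(x / (xmin - 1/2)).
alpha_discrete_start <- function(x, xmin) {
  1 + length(x) / sum(log(x / (xmin - 0.5)))
}

fit_alpha <- function(x, xmin, variant) {
  if (variant == "continuous") {
    s <- sum(log(x / xmin))
    if (s <= 0) stop("divergent estimate: all samples equal xmin")
    1 + length(x) / s
  } else {
    if (all(x == xmin)) stop("divergent estimate: all samples equal xmin")
    slog <- sum(log(x))
    nll <- function(a) length(x) * log(hurwitz_zeta(a, xmin)) + a * slog
    start <- alpha_discrete_start(x, xmin)
    lo <- max(1.01, start / 3); hi <- max(start * 3, 5)
    stats::optimize(nll, c(lo, hi))$minimum
  }
}

#' Fit a power law by maximum likelihood
#'
#' Continuous variant: closed-form MLE
#' \eqn{\hat\alpha = 1 + n [\sum \log(x_i/x_{min})]^{-1}}. Discrete variant:
#' numerical maximization of the zeta-normalized likelihood, started from the
#' closed-form approximation. When \code{xmin} is not supplied it is scanned
#' over candidate values and chosen to minimize the KS distance between the
#' tail data and the fitted model.
#'
#' @param x positive sample values (injury areas, in-degrees, ...).
#' @param variant \code{"continuous"} or \code{"discrete"}.
#' @param xmin optional fixed lower cutoff; scanned when NULL.
#' @param max_xmin_candidates cap on the number of scanned cutoffs.
#' @param min_tail minimum tail size required (default 10).
#' @return object of class \code{powerlaw_fit}: alpha_hat, xmin_hat, n_tail,
#'   ks_D, p_value (NA until \code{\link{ks_plausibility}}), plausible,
#'   variant, xmin_fixed, and the data (tail and body) used.
#' @export
fit_powerlaw <- function(x, variant = c("continuous", "discrete"), xmin = NULL,
                         max_xmin_candidates = 100, min_tail = 10) {
  variant <- match.arg(variant)
  x <- x[is.finite(x) & x > 0]
  xmin_fixed <- !is.null(xmin)
  if (xmin_fixed) {
    tail <- x[x >= xmin]
    if (length(tail) < min_tail)
      stop(sprintf("insufficient tail: %d samples >= xmin (need %d)",
                   length(tail), min_tail))
    alpha <- fit_alpha(tail, xmin, variant)
    D <- ks_distance(tail, alpha, xmin, variant)
  } else {
    cand <- sort(unique(x))
    cand <- cand[vapply(cand, function(xm) sum(x >= xm), numeric(1)) >= min_tail]
    if (!length(cand)) stop("insufficient tail for every candidate xmin")
    if (length(cand) > max_xmin_candidates)
      cand <- unique(stats::quantile(cand, seq(0, 1, length.out = max_xmin_candidates),
                                     type = 1, names = FALSE))
    best <- NULL
    for (xm in cand) {
      tail <- x[x >= xm]
      alpha_c <- tryCatch(fit_alpha(tail, xm, variant), error = function(e) NA)
      if (is.na(alpha_c)) next
      D_c <- ks_distance(tail, alpha_c, xm, variant)
      if (is.null(best) || D_c < best$D) best <- list(xm = xm, alpha = alpha_c, D = D_c)
    }
    if (is.null(best)) stop("no valid xmin candidate")
    xmin <- best$xm; alpha <- best$alpha; D <- best$D
    tail <- x[x >= xmin]
  }
  structure(list(alpha_hat = alpha, xmin_hat = xmin, n_tail = length(tail),
                 ks_D = D, p_value = NA_real_, plausible = NA,
                 variant = variant, xmin_fixed = xmin_fixed,
                 tail = tail, body = x[x < xmin]),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> %s: alpha_hat = %.4f, xmin = %g, n_tail = %d, KS D = %.4f\n",
              x$variant, x$alpha_hat, x$xmin_hat, x$n_tail, x$ks_D))
  if (!is.na(x$p_value))
    cat(sprintf("  bootstrap p = %.4f -> power law %s (p >= 0.1 rule)\n",
                x$p_value, if (x$plausible) "plausible" else "not plausible"))
  invisible(x)
}

#' @export
summary.powerlaw_fit <- function(object, ...) {
  print(object)
  invisible(unclass(object)[c("alpha_hat", "xmin_hat", "n_tail", "ks_D",
                              "p_value", "plausible", "variant")])
}

# draw n values from the fitted tail model
rpl_tail <- function(n, alpha, xmin, variant) {
  u <- stats::runif(n)
  if (variant == "continuous") {
    powerlaw_quantile(u, alpha, xmin)
  } else {
    # standard continuous approximation for discrete power-law generation
    round((xmin - 0.5) * (1 - u)^(-1 / (alpha - 1)) + 0.5)
  }
}

#' KS bootstrap plausibility of a power-law fit
#'
#' Semiparametric bootstrap: each replicate draws a sample of the original
#' size from the fitted model (tail draws from the fitted power law; when
#' xmin was scanned, below-cutoff values are resampled from the empirical
#' body with the observed body probability), refits with the same xmin
#' policy, and records its KS distance. The p-value is the fraction of
#' replicate distances at or above the observed one; p >= 0.1 means a power
#' law is a plausible fit.
#'
#' @param fit a \code{\link{powerlaw_fit}}.
#' @param n_boot bootstrap replicates (default 1000; < 100 warns).
#' @param seed integer seed.
#' @return the fit with \code{p_value}, \code{plausible} and \code{n_boot}
#'   filled in.
#' @export
ks_plausibility <- function(fit, n_boot = 1000, seed = 1) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  if (n_boot < 1) stop("n_boot must be positive")
  if (n_boot < 100) warning("n_boot < 100 gives an unstable p-value")
  set.seed(seed)
  n_tail <- fit$n_tail; n_body <- length(fit$body)
  n <- n_tail + n_body
  p_tail <- n_tail / n
  exceed <- 0L
  for (b in seq_len(n_boot)) {
    if (fit$xmin_fixed || n_body == 0) {
      xb <- rpl_tail(n_tail, fit$alpha_hat, fit$xmin_hat, fit$variant)
      rf <- tryCatch(fit_powerlaw(xb, fit$variant, xmin = fit$xmin_hat),
                     error = function(e) NULL)
    } else {
      nt <- stats::rbinom(1, n, p_tail)
      xb <- c(rpl_tail(nt, fit$alpha_hat, fit$xmin_hat, fit$variant),
              sample(fit$body, n - nt, replace = TRUE))
      rf <- tryCatch(fit_powerlaw(xb, fit$variant), error = function(e) NULL)
    }
    if (is.null(rf) || rf$ks_D >= fit$ks_D) exceed <- exceed + 1L
  }
  fit$p_value <- max(exceed, 1L) / n_boot
  fit$plausible <- fit$p_value >= 0.1
  fit$n_boot <- n_boot
  fit
}

#' Log-log histogram regression slope of a size distribution
#'
#' Companion to the MLE exponent: least-squares slope of log frequency
#' against log size over logarithmically spaced bins. Reported as a
#' positive exponent (the negated regression slope).
#'
#' @param x positive sample values.
#' @param nbins number of logarithmic bins.
#' @return list with \code{slope} and the bin table.
#' @export
powerlaw_hist_slope <- function(x, nbins = 20) {
  x <- x[x > 0]
  br <- exp(seq(log(min(x)), log(max(x)) + 1e-9, length.out = nbins + 1))
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  dens <- h$counts / diff(br)
  keep <- dens > 0
  fitlm <- stats::lm(log(dens[keep]) ~ log(h$mids[keep]))
  list(slope = -unname(stats::coef(fitlm)[2]),
       table = data.frame(mid = h$mids, density = dens))
}

#' @export
plot.powerlaw_fit <- function(x, ...) {
  s <- sort(x$tail)
  ccdf <- 1 - (seq_along(s) - 1) / length(s)
  graphics::plot(s, ccdf, log = "xy", xlab = "size", ylab = "CCDF",
                 main = sprintf("power-law fit (alpha = %.2f)", x$alpha_hat), ...)
  xs <- exp(seq(log(min(s)), log(max(s)), length.out = 100))
  graphics::lines(xs, (xs / x$xmin_hat)^(1 - x$alpha_hat), col = 2)
  invisible(x)
}

# -- box counting ------------------------------------------------------------

#' Box-counting fractal dimension of an injury mask
#'
#' Overlays the lobe bounding box with a grid of boxes whose size shrinks by
#' powers of \code{base} (2 by default), counts boxes containing at least one
#' injured pixel, and regresses log(count) on log(1/size). The slope is the
#' fractal dimension d_f of the injured set in the lobe plane.
#'
#' @param injury_mask logical matrix, TRUE on injured pixels.
#' @param lobe_mask optional logical lobe mask restricting and anchoring the
#'   grid (defaults to the whole image).
#' @param base grid refinement factor.
#' @param min_box smallest box size used.
#' @return object of class \code{fractal_estimate}: df, intercept,
#'   box_sizes, counts, r_squared.
#' @export
box_counting_dimension <- function(injury_mask, lobe_mask = NULL, base = 2,
                                   min_box = 1) {
  if (!is.null(lobe_mask)) injury_mask <- injury_mask & lobe_mask
  idx <- which(injury_mask)
  if (!length(idx)) stop("no injured pixels inside the lobe mask")
  if (is.null(lobe_mask)) lobe_mask <- array(TRUE, dim(injury_mask))
  lidx <- which(lobe_mask)
  r0 <- min((lidx - 1L) %% nrow(lobe_mask))
  c0 <- min((lidx - 1L) %/% nrow(lobe_mask))
  h <- max((lidx - 1L) %% nrow(lobe_mask)) - r0 + 1
  w <- max((lidx - 1L) %/% nrow(lobe_mask)) - c0 + 1
  r <- (idx - 1L) %% nrow(injury_mask) - r0
  c <- (idx - 1L) %/% nrow(injury_mask) - c0
  sizes <- base^(floor(log(max(h, w), base)):0)
  sizes <- sizes[sizes >= min_box]
  counts <- vapply(sizes, function(s) {
    length(unique((r %/% s) * (w %/% s + 1) + (c %/% s)))
  }, numeric(1))
  if (length(idx) == 1 || length(unique(counts)) == 1) {
    warning("degenerate box-count fit: constant counts")
    return(structure(list(df = 0, intercept = log(counts[1]),
                          box_sizes = sizes, counts = counts,
                          r_squared = NA_real_),
                     class = "fractal_estimate"))
  }
  fitlm <- stats::lm(log(counts) ~ log(1 / sizes))
  structure(list(df = unname(stats::coef(fitlm)[2]),
                 intercept = unname(stats::coef(fitlm)[1]),
                 box_sizes = sizes, counts = counts,
                 r_squared = stats::cor(log(counts), log(1 / sizes))^2),
            class = "fractal_estimate")
}

#' @export
print.fractal_estimate <- function(x, ...) {
  cat(sprintf("<fractal_estimate> df = %.4f (R^2 = %.4f) over box sizes %s\n",
              x$df, x$r_squared, paste(x$box_sizes, collapse = ", ")))
  invisible(x)
}

#' @export
plot.fractal_estimate <- function(x, ...) {
  graphics::plot(log(1 / x$box_sizes), log(x$counts),
                 xlab = "log(1/box size)", ylab = "log(count)",
                 main = sprintf("box counting: df = %.3f", x$df), ...)
  graphics::abline(x$intercept, x$df, col = 2)
  invisible(x)
}

#' Serialize a power-law fit to JSON
#'
#' @param fit \code{\link{powerlaw_fit}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit)[c("alpha_hat", "xmin_hat", "n_tail",
                                      "ks_D", "p_value", "plausible", "variant")],
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
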