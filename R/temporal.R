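# Simulated injury-event times: because histology is terminal, event order
# is unobservable; times are assigned at random (exponential inter-injury
# intervals, Poisson-process style) and the analysis is repeated over an
# ensemble so every reported quantity carries its simulation variability.

#' Randomly assign event times to injury nodes
#'
#' Nodes receive a uniformly random order; event times are cumulative sums
#' of i.i.d. exponential inter-injury intervals with the given mean (first
#' event at its sampled interval from zero). Sizes and times are
#' independent by construction.
#'
#' @param nodes \code{\link{injury_nodes}}.
#' @param mean_interval_s mean inter-injury interval in seconds (default 2).
#' @param seed integer seed.
#' @return object of class \code{temporal_assignment}: data frame (id, time)
#'   in node order, with the event order as an attribute.
#' @export
assign_times <- function(nodes, mean_interval_s = 2, seed = 1) {
  if (mean_interval_s <= 0) stop("mean_interval_s must be positive")
  n <- nrow(nodes)
  if (n == 0) {
    return(structure(data.frame(id = integer(0), time = numeric(0)),
                     order = integer(0), mean_interval_s = mean_interval_s,
                     seed = seed, class = c("temporal_assignment", "data.frame")))
  }
  set.seed(seed)
  ord <- sample.int(n)
  t_sorted <- cumsum(stats::rexp(n, rate = 1 / mean_interval_s))
  times <- numeric(n)
  times[ord] <- t_sorted
  structure(data.frame(id = nodes$id, time = times),
            order = nodes$id[ord], mean_interval_s = mean_interval_s,
            seed = seed, class = c("temporal_assignment", "data.frame"))
}

#' Build the time-extended nearest-neighbor correlation network
#'
#' The pairwise weight gains the elapsed time between events,
#' C * l^df * t_ij * dm * m_parent^(-alpha) with t_ij = t_child - t_parent.
#' Candidate parents are restricted to strictly earlier events; each
#' non-earliest node links to its minimizing earlier parent and the earliest
#' event is the root.
#'
#' @param nodes \code{\link{injury_nodes}}.
#' @param assignment \code{\link{assign_times}} result over the same ids.
#' @param params \code{\link{model_params}}.
#' @return timed \code{injury_network}; edges carry \code{dt} (elapsed
#'   seconds) in addition to the weight.
#' @export
build_time_network <- function(nodes, assignment, params) {
  if (!identical(sort(nodes$id), sort(assignment$id)))
    stop("assignment ids do not match nodes")
  n <- nrow(nodes)
  t <- assignment$time[match(nodes$id, assignment$id)]
  if (n < 2) {
    net <- new_network(nodes, data.frame(child = integer(0), parent = integer(0),
                                         weight = numeric(0), dt = numeric(0)),
                       timed = TRUE, params = params)
    net$times <- t
    return(net)
  }
  D <- as.matrix(stats::dist(cbind(nodes$row, nodes$col)))
  if (any(D[upper.tri(D)] == 0))
    stop("degenerate geometry: coincident centroids")
  B <- params$C * params$delta_m * D^params$df * nodes$area^(-params$alpha)
  # ties in time broken by order index (probability zero under continuous draws)
  rank_t <- order(order(t, nodes$id))
  child <- parent <- integer(n - 1)
  weight <- dt <- numeric(n - 1)
  e <- 0L
  for (j in seq_len(n)) {
    earlier <- which(rank_t < rank_t[j])
    if (!length(earlier)) next
    w <- B[earlier, j] * (t[j] - t[earlier])
    b <- argmin_parent(w, nodes$area[earlier], nodes$id[earlier])
    e <- e + 1L
    child[e] <- nodes$id[j]
    parent[e] <- nodes$id[earlier[b]]
    weight[e] <- w[b]
    dt[e] <- t[j] - t[earlier[b]]
  }
  net <- new_network(nodes, data.frame(child = child, parent = parent,
                                       weight = weight, dt = dt),
                     timed = TRUE, params = params)
  net$times <- t
  net
}

# deterministic replicate seeds below 2^31 from a master seed
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(2^30, n)
}

#' Run an ensemble of temporal simulations
#'
#' Repeats the random time assignment and time-extended network build
#' \code{n_reps} times (replicate seeds derived deterministically from the
#' master seed) and fits a discrete power law to each replicate's in-degree
#' distribution.
#'
#' @param nodes \code{\link{injury_nodes}}.
#' @param params \code{\link{model_params}}.
#' @param n_reps ensemble size (default 100).
#' @param mean_interval_s mean inter-injury interval in seconds.
#' @param seed master seed.
#' @param fit_indegree fit a discrete power law (xmin = 1) to each
#'   replicate's positive in-degrees.
#' @param plausibility_boot if > 0, run \code{\link{ks_plausibility}} with
#'   this many bootstrap replicates on each in-degree fit.
#' @return object of class \code{temporal_ensemble}: lists \code{networks},
#'   \code{assignments}, \code{fits}, plus the replicate seeds.
#' @export
ensemble_run <- function(nodes, params, n_reps = 100, mean_interval_s = 2,
                         seed = 1, fit_indegree = TRUE, plausibility_boot = 0) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  seeds <- derive_seeds(seed, n_reps)
  networks <- assignments <- fits <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    a <- assign_times(nodes, mean_interval_s, seed = seeds[r])
    net <- build_time_network(nodes, a, params)
    assignments[[r]] <- a
    networks[[r]] <- net
    if (fit_indegree) {
      k <- in_degree_distribution(net)
      f <- tryCatch(fit_powerlaw(k[k > 0], "discrete", xmin = 1),
                    error = function(e) NULL)
      if (!is.null(f) && plausibility_boot > 0)
        f <- ks_plausibility(f, n_boot = plausibility_boot, seed = seeds[r])
      fits[[r]] <- f
    }
  }
  structure(list(networks = networks, assignments = assignments, fits = fits,
                 seeds = seeds, mean_interval_s = mean_interval_s,
                 n_reps = n_reps),
            class = "temporal_ensemble")
}

#' @export
print.temporal_ensemble <- function(x, ...) {
  g <- vapply(x$fits, function(f) if (is.null(f)) NA_real_ else f$alpha_hat,
              numeric(1))
  cat(sprintf("<temporal_ensemble> %d replicates, median in-degree exponent %.3f\n",
              x$n_reps, stats::median(g, na.rm = TRUE)))
  invisible(x)
}

#' Compare the timed in-degree exponent against the time-free one
#'
#' Bootstraps the ensemble of per-replicate in-degree exponents (gamma) and
#' reports the difference of the ensemble median from the time-free
#' network's exponent, with a percentile CI and a two-sided bootstrap p for
#' the difference being zero.
#'
#' @param no_time_fit \code{\link{powerlaw_fit}} of the time-free in-degrees.
#' @param ensemble_fits list of per-replicate fits (or a
#'   \code{temporal_ensemble}).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return list: gamma_median, alpha_no_time, difference, ci (length 2),
#'   p_value, degenerate flag.
#' @export
compare_gamma <- function(no_time_fit, ensemble_fits, n_boot = 10000, seed = 1) {
  if (inherits(ensemble_fits, "temporal_ensemble"))
    ensemble_fits <- ensemble_fits$fits
  g <- vapply(Filter(Negate(is.null), ensemble_fits),
              function(f) f$alpha_hat, numeric(1))
  if (!length(g)) stop("ensemble contains no usable fits")
  a0 <- no_time_fit$alpha_hat
  obs <- stats::median(g) - a0
  degenerate <- length(g) < 2
  if (degenerate) warning("single-replicate ensemble: CI is degenerate")
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b)
    stats::median(sample(g, length(g), replace = TRUE)) - a0, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  p <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  list(gamma_median = stats::median(g), alpha_no_time = a0, difference = obs,
       ci = ci, p_value = p, degenerate = degenerate, n_boot = n_boot)
}

#' Overlap of top-central nodes between time-free and timed analyses
#'
#' For each fraction f on the grid, the overlap is the share of the top
#' \code{top_frac_no_time} time-free nodes found within the top f timed
#' nodes, averaged over the ensemble with a percentile bootstrap CI. The
#' chance line equals f: the overlap expected if timed scores were
#' unrelated to the time-free ranking.
#'
#' @param no_time_scores \code{centrality_scores} of the time-free network.
#' @param ensemble_scores list of \code{centrality_scores}, one per
#'   replicate, over identical node ids.
#' @param top_frac_no_time fraction defining the time-free top set
#'   (e.g. 0.005 or 0.01).
#' @param grid fractions f at which overlap is evaluated.
#' @param n_boot bootstrap resamples over replicates.
#' @param seed integer seed.
#' @return data frame of class \code{overlap_curve}: fraction, overlap,
#'   ci_lo, ci_hi, chance.
#' @export
centrality_overlap <- function(no_time_scores, ensemble_scores,
                               top_frac_no_time = 0.005,
                               grid = c(0.005, 0.01, 0.02, 0.04, 0.08, 0.16,
                                        0.32, 0.64, 1),
                               n_boot = 1000, seed = 1) {
  base_ids <- top_fraction(no_time_scores, top_frac_no_time)
  per_rep <- matrix(NA_real_, length(ensemble_scores), length(grid))
  for (r in seq_along(ensemble_scores)) {
    sc <- ensemble_scores[[r]]
    if (!setequal(sc$id, no_time_scores$id))
      stop("ensemble scores cover different node ids")
    for (k in seq_along(grid)) {
      top_t <- top_fraction(sc, grid[k])
      per_rep[r, k] <- length(intersect(base_ids, top_t)) / length(base_ids)
    }
  }
  mean_ov <- colMeans(per_rep)
  set.seed(seed)
  ci <- apply(per_rep, 2, function(col) {
    if (length(col) < 2) return(c(col, col))
    boot <- vapply(seq_len(n_boot), function(b)
      mean(sample(col, length(col), replace = TRUE)), numeric(1))
    stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  })
  out <- data.frame(fraction = grid, overlap = mean_ov,
                    ci_lo = ci[1, ], ci_hi = ci[2, ], chance = grid)
  class(out) <- c("overlap_curve", "data.frame")
  out
}

#' @export
plot.overlap_curve <- function(x, ...) {
  graphics::plot(x$fraction, x$overlap, type = "b", ylim = c(0, 1),
                 xlab = "top fraction of timed scores",
                 ylab = "overlap with time-free top set", ...)
  graphics::lines(x$fraction, x$chance, lty = 2)
  graphics::arrows(x$fraction, x$ci_lo, x$fraction, x$ci_hi,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

# exponentially growing time bins covering (first, t_max]
make_time_bins <- function(t_max, t_start = 1, growth = 2) {
  if (growth <= 1) stop("bin growth factor must exceed 1")
  edges <- t_start
  while (edges[length(edges)] <= t_max)
    edges <- c(edges, edges[length(edges)] * growth)
  edges
}

#' Magnitude-stratified secondary-injury ("aftershock") rate curves
#'
#' Every network edge is a secondary injury event at elapsed time
#' t_child - t_parent after its primary. Events are pooled per replicate and
#' per primary-magnitude class (integer bins of log10 area, reference size
#' 1), counted in exponentially growing time bins, and divided by the bin
#' width to give rates per second; the ensemble mean and percentile
#' bootstrap CI are reported per bin, plus an aggregate curve over all
#' magnitudes.
#'
#' @param ensemble \code{temporal_ensemble} (or list of timed networks).
#' @param bin_growth exponential bin growth factor (default 2).
#' @param t_start left edge of the first bin in seconds.
#' @param bin_edges optional explicit bin edges overriding the above.
#' @param normalize \code{"pooled"} (default: events of a class are pooled,
#'   so curves conserve total event counts) or \code{"per_primary"} (rates
#'   divided by the number of candidate primaries in the class, making
#'   magnitude classes of different abundance comparable).
#' @param n_boot bootstrap resamples over replicates.
#' @param seed integer seed.
#' @return data frame of class \code{rate_curves}: magnitude_class ("all" or
#'   an integer), bin_lo, bin_hi, rate, ci_lo, ci_hi.
#' @export
secondary_event_rates <- function(ensemble, bin_growth = 2, t_start = 1,
                                  bin_edges = NULL,
                                  normalize = c("pooled", "per_primary"),
                                  n_boot = 1000, seed = 1) {
  normalize <- match.arg(normalize)
  nets <- if (inherits(ensemble, "temporal_ensemble")) ensemble$networks
          else ensemble
  if (!length(nets)) stop("empty ensemble")
  pull <- function(net) {
    if (!nrow(net$edges)) return(NULL)
    m <- net$nodes$area[match(net$edges$parent, net$nodes$id)]
    data.frame(dt = net$edges$dt, mag = floor(log10(m)))
  }
  evs <- lapply(nets, pull)
  all_dt <- unlist(lapply(evs, function(e) e$dt))
  if (is.null(bin_edges)) {
    if (!length(all_dt)) bin_edges <- c(t_start, t_start * bin_growth)
    else {
      t0 <- t_start
      while (t0 > min(all_dt)) t0 <- t0 / bin_growth
      bin_edges <- t0 * bin_growth^(0:ceiling(log(max(all_dt) / t0, bin_growth)))
      if (bin_edges[length(bin_edges)] <= max(all_dt))
        bin_edges <- c(bin_edges, bin_edges[length(bin_edges)] * bin_growth)
    }
  }
  nb <- length(bin_edges) - 1
  widths <- diff(bin_edges)
  classes <- sort(unique(unlist(lapply(evs, function(e) e$mag))))
  groups <- c(list(all = NULL), stats::setNames(as.list(classes), classes))
  set.seed(seed)
  out <- NULL
  node_mags <- floor(log10(nets[[1]]$nodes$area))
  for (gname in names(groups)) {
    cls <- groups[[gname]]
    divisor <- if (normalize == "pooled") 1
               else if (is.null(cls)) max(1, length(node_mags))
               else max(1, sum(node_mags == cls))
    rates <- t(vapply(evs, function(e) {
      if (is.null(e)) return(numeric(nb))
      d <- if (is.null(cls)) e$dt else e$dt[e$mag == cls]
      d <- d[d >= bin_edges[1] & d <= bin_edges[nb + 1]]
      h <- graphics::hist(d, breaks = bin_edges, plot = FALSE,
                          right = FALSE)$counts
      h / widths / divisor
    }, numeric(nb)))
    mean_r <- colMeans(rates)
    ci <- apply(rates, 2, function(col) {
      if (length(col) < 2) return(c(col, col))
      boot <- vapply(seq_len(n_boot), function(b)
        mean(sample(col, length(col), replace = TRUE)), numeric(1))
      stats::quantile(boot, c(0.025, 0.975), names = FALSE)
    })
    out <- rbind(out, data.frame(magnitude_class = gname,
                                 bin_lo = bin_edges[-(nb + 1)],
                                 bin_hi = bin_edges[-1],
                                 rate = mean_r, ci_lo = ci[1, ], ci_hi = ci[2, ]))
  }
  rownames(out) <- NULL
  class(out) <- c("rate_curves", "data.frame")
  out
}

#' @export
plot.rate_curves <- function(x, ...) {
  cls <- unique(x$magnitude_class)
  cols <- seq_along(cls)
  pos <- x$rate > 0
  graphics::plot(NA, xlim = range(sqrt(x$bin_lo * x$bin_hi)),
                 ylim = range(x$rate[pos]), log = "xy",
                 xlab = "time since primary event (s)",
                 ylab = "secondary event rate (1/s)", ...)
  for (i in seq_along(cls)) {
    sub <- x[x$magnitude_class == cls[i] & x$rate > 0, ]
    graphics::lines(sqrt(sub$bin_lo * sub$bin_hi), sub$rate, type = "b",
                    col = cols[i], pch = 16)
  }
  graphics::legend("bottomleft", legend = cls, col = cols, lty = 1, pch = 16,
                   title = "magnitude", cex = 0.8)
  invisible(x)
}
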