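# Synthetic lobes: power-law sized, disk-shaped injury regions placed in an
# elliptical lobe mask, so every downstream stage of the pipeline can be
# exercised without histology.

#' Sample injury sizes from a continuous power law
#'
#' Draws sizes from the Pareto density p(x) proportional to x^(-alpha) for
#' x >= xmin via the inverse CDF, x = xmin * (1 - u)^(-1/(alpha - 1)) with u
#' uniform on [0, 1).
#'
#' @param n number of draws.
#' @param alpha power-law exponent, must exceed 1 (the tail is not
#'   normalizable otherwise).
#' @param xmin lower bound of support (> 0).
#' @param seed optional integer seed; when given the draw is reproducible.
#' @return numeric vector of length \code{n}, all values >= \code{xmin}.
#' @export
sample_powerlaw_sizes <- function(n, alpha, xmin = 1, seed = NULL) {
  if (alpha <= 1) stop("alpha must be > 1: the power-law tail is not normalizable")
  if (xmin <= 0) stop("xmin must be positive")
  if (n < 0) stop("n must be non-negative")
  if (n == 0) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  powerlaw_quantile(u, alpha, xmin)
}

# shared inverse CDF
powerlaw_quantile <- function(u, alpha, xmin) {
  xmin * (1 - u)^(-1 / (alpha - 1))
}

#' Specification of a synthetic lobe
#'
#' @param width_px,height_px image dimensions in pixels.
#' @param n_injuries number of injury blobs to place.
#' @param alpha power-law exponent (> 1) for blob pixel areas.
#' @param xmin_px minimum blob area in pixels (>= 1).
#' @param placement \code{"uniform"} or \code{"clustered"}.
#' @param cluster_strength non-negative; probability that a new blob is
#'   seeded near an existing one rather than uniformly (0 = uniform).
#' @param min_gap_px minimum boundary-to-boundary gap between blobs.
#' @param air_fraction fraction of non-injured lobe pixels labelled air
#'   rather than other tissue.
#' @param seed integer seed.
#' @return An object of class \code{lobe_spec}.
#' @export
lobe_spec <- function(width_px = 512, height_px = 512, n_injuries = 50,
                      alpha = 2, xmin_px = 100, placement = c("uniform", "clustered"),
                      cluster_strength = 0, min_gap_px = 2,
                      air_fraction = 0.3, seed = 1) {
  placement <- match.arg(placement)
  if (alpha <= 1) stop("alpha must be > 1")
  if (xmin_px < 1) stop("xmin_px must be >= 1")
  if (n_injuries < 0 || min_gap_px < 0 || cluster_strength < 0)
    stop("n_injuries, min_gap_px and cluster_strength must be non-negative")
  structure(list(width_px = width_px, height_px = height_px,
                 n_injuries = n_injuries, alpha = alpha, xmin_px = xmin_px,
                 placement = placement, cluster_strength = cluster_strength,
                 min_gap_px = min_gap_px, air_fraction = air_fraction,
                 seed = seed),
            class = "lobe_spec")
}

#' Generate a synthetic lobe label image with ground truth
#'
#' Injury blobs are rasterized disks whose areas follow the power law of the
#' spec. Placement is rejection-sampled inside an elliptical lobe mask:
#' uniform, or (when clustered) biased toward existing blobs. Remaining lobe
#' pixels are assigned air or other tissue; pixels outside the lobe are
#' background.
#'
#' @param spec a \code{\link{lobe_spec}}.
#' @param max_attempts rejection-sampling attempts per blob before failing.
#' @return list with \code{image} (a \code{\link{label_image}}), \code{mask}
#'   (logical lobe mask) and \code{truth} (data frame id, row, col, area,
#'   radius; 0-based centroid coordinates of the placed disk centers).
#' @export
generate_lobe_image <- function(spec, max_attempts = 10000) {
  stopifnot(inherits(spec, "lobe_spec"))
  set.seed(spec$seed)
  W <- spec$width_px; H <- spec$height_px
  # elliptical lobe inscribed with a small margin
  rr <- matrix(seq_len(H) - (H + 1) / 2, H, W)
  cc <- matrix(seq_len(W) - (W + 1) / 2, H, W, byrow = TRUE)
  mask <- (rr / (0.48 * H))^2 + (cc / (0.48 * W))^2 <= 1

  areas <- round(sample_powerlaw_sizes(spec$n_injuries, spec$alpha, spec$xmin_px))
  areas <- pmax(areas, 1)
  radii <- sqrt(areas / pi)
  # place large blobs first: easier packing, same marginal statistics
  ord <- order(areas, decreasing = TRUE)
  centers <- matrix(NA_real_, spec$n_injuries, 2)
  placed_r <- numeric(0)
  in_idx <- which(mask)
  for (k in seq_along(ord)) {
    b <- ord[k]
    r <- radii[b]
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      if (spec$placement == "clustered" && k > 1 &&
          stats::runif(1) < spec$cluster_strength / (1 + spec$cluster_strength)) {
        j <- sample.int(k - 1, 1)
        anchor <- centers[ord[j], ]
        sd <- placed_r[j] + r + spec$min_gap_px + 10
        cand <- anchor + stats::rnorm(2, sd = sd)
      } else {
        i <- in_idx[sample.int(length(in_idx), 1)]
        cand <- c((i - 1) %% H, (i - 1) %/% H) + stats::runif(2) - 0.5
      }
      ri <- round(cand[1]) + 1; ci <- round(cand[2]) + 1
      if (ri < 1 || ri > H || ci < 1 || ci > W || !mask[ri, ci]) next
      # conservative check that the whole disk fits inside the lobe ellipse
      dr <- abs(cand[1] - (H - 1) / 2) + r
      dc <- abs(cand[2] - (W - 1) / 2) + r
      if ((dr / (0.48 * H))^2 + (dc / (0.48 * W))^2 > 1) next
      if (k > 1) {
        prev <- centers[ord[seq_len(k - 1)], , drop = FALSE]
        d <- sqrt((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2)
        if (any(d < placed_r + r + spec$min_gap_px)) next
      }
      centers[b, ] <- cand
      placed_r <- c(placed_r, r)
      ok <- TRUE
      break
    }
    if (!ok) stop(sprintf("could not place blob %d (area %d px) after %d attempts",
                          b, areas[b], max_attempts))
  }

  g <- matrix(CLASS_CODES[["background"]], H, W)
  if (any(mask)) {
    n_in <- sum(mask)
    cls <- ifelse(stats::runif(n_in) < spec$air_fraction,
                  CLASS_CODES[["air"]], CLASS_CODES[["other"]])
    g[mask] <- cls
  }
  true_area <- integer(spec$n_injuries)
  if (spec$n_injuries > 0) {
    r0 <- matrix(0:(H - 1), H, W)
    c0 <- matrix(0:(W - 1), H, W, byrow = TRUE)
    for (b in seq_len(spec$n_injuries)) {
      sel <- (r0 - centers[b, 1])^2 + (c0 - centers[b, 2])^2 <= radii[b]^2
      true_area[b] <- sum(sel)
      g[sel] <- CLASS_CODES[["injury"]]
    }
  }
  truth <- data.frame(id = seq_len(spec$n_injuries),
                      row = centers[, 1], col = centers[, 2],
                      area = true_area, radius = radii)
  list(image = label_image(g), mask = mask, truth = truth)
}

#' Sample a ground-truth injury node set without rasterization
#'
#' Convenience generator for network-level simulation studies: node areas
#' follow the requested power law and centroids are placed uniformly (or
#' cluster-seeded) in a rectangle, with no image in between. The returned
#' table has the same columns as \code{\link{extract_injury_nodes}} output.
#'
#' @param n number of nodes.
#' @param alpha power-law exponent for areas.
#' @param xmin minimum area.
#' @param width,height extent of the placement rectangle (pixel units).
#' @param placement \code{"uniform"} or \code{"clustered"}.
#' @param cluster_strength probability weight for clustered seeding.
#' @param seed integer seed.
#' @return \code{injury_nodes} data frame: id, row, col, area, magnitude.
#' @export
sample_injury_nodes <- function(n, alpha = 2, xmin = 100,
                                width = 5000, height = 5000,
                                placement = c("uniform", "clustered"),
                                cluster_strength = 5, seed = 1) {
  placement <- match.arg(placement)
  set.seed(seed)
  u <- stats::runif(n)
  area <- powerlaw_quantile(u, alpha, xmin)
  row <- numeric(n); col <- numeric(n)
  for (k in seq_len(n)) {
    if (placement == "clustered" && k > 1 &&
        stats::runif(1) < cluster_strength / (1 + cluster_strength)) {
      j <- sample.int(k - 1, 1)
      row[k] <- min(max(row[j] + stats::rnorm(1, sd = height / 50), 0), height)
      col[k] <- min(max(col[j] + stats::rnorm(1, sd = width / 50), 0), width)
    } else {
      row[k] <- stats::runif(1, 0, height)
      col[k] <- stats::runif(1, 0, width)
    }
  }
  injury_nodes(data.frame(id = seq_len(n), row = row, col = col, area = area))
}

#' Deterministic toy label image with a documented island manifest
#'
#' A fixed 120 x 220 image used for exact post-processing tests. Manifest
#' (all blocks are axis-aligned rectangles of 'injured' pixels on an 'other'
#' background):
#' \itemize{
#'   \item island A: 9 x 11 = 99 px at rows 10-18, cols 10-20 (below the
#'     100-px noise floor);
#'   \item island B: 10 x 10 = 100 px at rows 45-54, cols 10-19 (exactly at
#'     the floor);
#'   \item island C: 10 x 15 = 150 px at rows 80-89, cols 10-24;
#'   \item islands D1/D2: two 10 x 10 squares at rows 100-109, cols 60-69 and
#'     cols 74-83 -- separated by a 4-px gap, bridged by the default
#'     morphological merge;
#'   \item island E: isolated 12 x 12 square at rows 20-31, cols 150-161.
#' }
#' Row/col positions above are 0-based pixel indices.
#'
#' @return A \code{\link{label_image}}; identical on every call.
#' @export
generate_toy_fixture <- function() {
  g <- matrix(CLASS_CODES[["other"]], 120, 220)
  put <- function(g, rows, cols) {
    g[rows + 1, cols + 1] <- CLASS_CODES[["injury"]]
    g
  }
  g <- put(g, 10:18, 10:20)     # A: 99 px
  g <- put(g, 45:54, 10:19)     # B: 100 px
  g <- put(g, 80:89, 10:24)     # C: 150 px
  g <- put(g, 100:109, 60:69)   # D1
  g <- put(g, 100:109, 74:83)   # D2 (gap of 4 columns)
  g <- put(g, 20:31, 150:161)   # E: 144 px
  label_image(g)
}

#' Write ground-truth nodes to CSV
#'
#' @param truth data frame with columns id, row, col, area (and optionally
#'   time).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
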