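# Post-processing of pixel-classified histology: background exclusion, lobe
# mask construction, noise-island filtering, morphological merging of nearby
# injured regions, node extraction, morphometry and segmentation scoring.

#' Injury node table constructor
#'
#' @param df data frame with columns id, row, col, area (0-based centroid
#'   coordinates in pixel units, area in pixels). A magnitude column
#'   (log10 of area relative to a reference size of 1, in analogy to the
#'   Richter scale) is added if absent.
#' @return data frame of class \code{injury_nodes}.
#' @export
injury_nodes <- function(df) {
  need <- c("id", "row", "col", "area")
  if (!all(need %in% names(df))) stop("injury_nodes needs columns id, row, col, area")
  if (anyDuplicated(df$id)) stop("node ids must be unique")
  if (is.null(df$magnitude)) df$magnitude <- log10(df$area)
  class(df) <- c("injury_nodes", "data.frame")
  df
}

#' @export
print.injury_nodes <- function(x, ...) {
  cat(sprintf("<injury_nodes> %d nodes, total area %.0f px, magnitude range [%.2f, %.2f]\n",
              nrow(x), sum(x$area),
              if (nrow(x)) min(x$magnitude) else NA, if (nrow(x)) max(x$magnitude) else NA))
  NextMethod()
}

#' Exclude bright slide background by k-means clustering of intensity
#'
#' Clusters grayscale intensities into \code{k} groups and marks the
#' brightest-mean cluster(s) as background (bare slide and artifacts outside
#' the lung are brighter than stained tissue).
#'
#' @param intensity numeric matrix of grayscale intensities.
#' @param k number of clusters (>= 2).
#' @param n_background how many of the brightest clusters to drop.
#' @param seed seed for the k-means initialization.
#' @return logical matrix, TRUE on retained (tissue) pixels.
#' @export
exclude_background <- function(intensity, k = 2, n_background = 1, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  v <- as.numeric(intensity)
  if (diff(range(v)) == 0)
    stop("degenerate clustering: intensity image is constant")
  set.seed(seed)
  # spread initial centers over the intensity range for determinism
  centers <- stats::quantile(v, probs = seq(0, 1, length.out = k), names = FALSE)
  if (anyDuplicated(centers)) centers <- jitter(centers, amount = 1e-9)
  km <- stats::kmeans(v, centers = matrix(centers, ncol = 1))
  bright <- order(km$centers[, 1], decreasing = TRUE)[seq_len(n_background)]
  keep <- !(km$cluster %in% bright)
  matrix(keep, nrow(intensity), ncol(intensity))
}

#' Build lobe masks from contiguous 'other'-tissue regions
#'
#' Connected components of 'other' pixels are grouped when their minimum
#' boundary-to-boundary Euclidean distance is at most \code{gap_px}; groups
#' further apart become separate masks. Masks smaller than \code{min_area_px}
#' are discarded as artifact, then interior holes (large airways, enclosed
#' air and injury) are filled.
#'
#' @param image a \code{\link{label_image}}.
#' @param gap_px grouping distance in pixels.
#' @param min_area_px minimum mask area in pixels.
#' @return list of logical lobe masks (possibly empty, with a warning).
#' @export
build_lobe_masks <- function(image, gap_px = 100, min_area_px = 100000) {
  seeds <- as_grid(image) == CLASS_CODES[["other"]]
  if (!any(seeds)) stop("image contains no 'other' pixels to seed lobe masks")
  lab <- label_components8(seeds)
  # regions merge iff boundary distance <= gap: grow each by gap/2 and join
  dm <- EBImage::imageData(EBImage::distmap(matrix(as.numeric(!seeds),
                                                   nrow(seeds), ncol(seeds))))
  grown <- seeds | (dm <= gap_px / 2)
  glab <- label_components8(grown)
  comp_ids <- sort(unique(lab[lab > 0]))
  group_of <- vapply(comp_ids, function(i) glab[which(lab == i)[1]], numeric(1))
  masks <- list()
  for (g in unique(group_of)) {
    m <- matrix(FALSE, nrow(seeds), ncol(seeds))
    for (i in comp_ids[group_of == g]) m[lab == i] <- TRUE
    if (sum(m) < min_area_px) next
    m <- EBImage::imageData(EBImage::fillHull(m)) > 0
    masks[[length(masks) + 1]] <- m
  }
  if (!length(masks)) warning("no lobe mask survived the size filter")
  masks
}

#' Remove injured islands below the noise floor
#'
#' 8-connected components of 'injured' pixels with area strictly below
#' \code{min_px} are reassigned to 'other' tissue.
#'
#' @param image a \code{\link{label_image}}.
#' @param min_px noise floor in pixels (default 100).
#' @return filtered \code{\link{label_image}}.
#' @export
filter_small_islands <- function(image, min_px = 100) {
  if (min_px < 1) stop("min_px must be >= 1")
  if (min_px == 1) return(image)
  g <- as_grid(image)
  inj <- g == CLASS_CODES[["injury"]]
  if (!any(inj)) return(image)
  lab <- label_components8(inj)
  area <- tabulate(lab[lab > 0])
  small <- which(area < min_px)
  if (length(small)) g[lab %in% small] <- CLASS_CODES[["other"]]
  label_image(g, pixel_size_um = attr(image, "pixel_size_um"))
}

# Euclidean disk structuring element of the given diameter (odd).
disk_kernel <- function(diameter_px) {
  if (diameter_px < 1 || diameter_px %% 2 == 0)
    stop("disk diameter must be odd and >= 1")
  r <- (diameter_px - 1) / 2
  d <- seq(-r, r)
  k <- outer(d^2, d^2, "+") <= r^2
  matrix(as.numeric(k), diameter_px, diameter_px)
}

#' Merge injured regions in close proximity
#'
#' Dilates the 'injured' mask \code{iterations} times and then erodes it
#' \code{iterations} times with a disk-shaped structuring element of width
#' \code{disk_diameter_px} (one large morphological closing), bridging gaps
#' between nearby injured regions. With \code{mode = "closing"} the
#' dilate-erode pair is instead applied \code{iterations} times in sequence,
#' which bridges smaller gaps. Non-injury classes are restored outside the
#' final injured mask; the image is padded internally so the closing is not
#' clipped at the border.
#'
#' @param image a \code{\link{label_image}}.
#' @param disk_diameter_px odd disk width in pixels (default 5, radius 2).
#' @param iterations number of dilation (then erosion) passes (default 5).
#' @param mode \code{"sequential"} (default: all dilations, then all
#'   erosions) or \code{"closing"} (repeated single closings).
#' @return merged \code{\link{label_image}}.
#' @export
merge_close_injuries <- function(image, disk_diameter_px = 5, iterations = 5,
                                 mode = c("sequential", "closing")) {
  mode <- match.arg(mode)
  if (iterations == 0) return(image)
  g <- as_grid(image)
  inj <- g == CLASS_CODES[["injury"]]
  if (!any(inj)) return(image)
  kern <- disk_kernel(disk_diameter_px)
  pad <- iterations * (disk_diameter_px - 1) / 2 + 1
  big <- matrix(0, nrow(g) + 2 * pad, ncol(g) + 2 * pad)
  big[pad + seq_len(nrow(g)), pad + seq_len(ncol(g))] <- as.numeric(inj)
  if (mode == "sequential") {
    for (i in seq_len(iterations)) big <- EBImage::dilate(big, kern)
    for (i in seq_len(iterations)) big <- EBImage::erode(big, kern)
  } else {
    for (i in seq_len(iterations)) {
      big <- EBImage::dilate(big, kern)
      big <- EBImage::erode(big, kern)
    }
  }
  closed <- EBImage::imageData(big)[pad + seq_len(nrow(g)),
                                    pad + seq_len(ncol(g))] > 0
  g[closed] <- CLASS_CODES[["injury"]]
  label_image(g, pixel_size_um = attr(image, "pixel_size_um"))
}

#' Extract injury nodes from a processed label image
#'
#' One node per 8-connected component of 'injured' pixels that intersects
#' the lobe mask. Centroids are unweighted means of pixel coordinates
#' (0-based, origin at the top-left pixel center); ids are assigned in scan
#' order of component discovery.
#'
#' @param image a \code{\link{label_image}}, after filtering and merging.
#' @param mask optional logical lobe mask; defaults to the whole image.
#' @return \code{\link{injury_nodes}} data frame (id, row, col, area,
#'   magnitude).
#' @export
extract_injury_nodes <- function(image, mask = NULL) {
  g <- as_grid(image)
  inj <- g == CLASS_CODES[["injury"]]
  lab <- label_components8(inj)
  st <- component_stats(lab)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(g))) stop("mask shape must match image")
    keep_ids <- unique(lab[lab > 0 & mask])
    st <- st[st$id %in% keep_ids, , drop = FALSE]
    st$id <- seq_len(nrow(st))
  }
  injury_nodes(st[, c("id", "row", "col", "area")])
}

#' Class-composition morphometry within a lobe mask
#'
#' @param image a \code{\link{label_image}}.
#' @param mask logical lobe mask.
#' @return named numeric vector of fractions (injury, air, other) over
#'   in-mask tissue/air pixels; sums to 1.
#' @export
class_fractions <- function(image, mask) {
  g <- as_grid(image)
  if (!identical(dim(mask), dim(g))) stop("mask shape must match image")
  v <- g[mask]
  v <- v[v != CLASS_CODES[["background"]]]
  if (!length(v)) stop("mask contains no classified pixels")
  c(injury = mean(v == CLASS_CODES[["injury"]]),
    air = mean(v == CLASS_CODES[["air"]]),
    other = mean(v == CLASS_CODES[["other"]]))
}

#' Score automated classification against manually scored pixels
#'
#' One-vs-rest sensitivity and specificity per class and overall accuracy,
#' for sampled pixels scored by a human reviewer.
#'
#' @param predicted,truth equal-length vectors of class labels; integer
#'   codes (1 = injury, 2 = air, 3 = other) or the class names.
#' @return object of class \code{confusion_summary}: counts matrix (rows =
#'   truth, cols = predicted), per-class sensitivity and specificity,
#'   accuracy. Classes absent from \code{truth} get sensitivity NA.
#' @export
confusion_summary <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  lev <- c("injury", "air", "other")
  norm <- function(x) {
    if (is.numeric(x)) x <- lev[x]
    factor(x, levels = lev)
  }
  p <- norm(predicted); t <- norm(truth)
  if (anyNA(p) || anyNA(t)) stop("labels must be injury/air/other (codes 1-3)")
  counts <- table(truth = t, predicted = p)
  n <- sum(counts)
  sens <- spec <- stats::setNames(numeric(3), lev)
  for (cl in lev) {
    tp <- counts[cl, cl]
    fn <- sum(counts[cl, ]) - tp
    fp <- sum(counts[, cl]) - tp
    tn <- n - tp - fn - fp
    sens[cl] <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    spec[cl] <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  }
  structure(list(counts = counts, sensitivity = sens, specificity = spec,
                 accuracy = sum(diag(counts)) / n, n = n),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> %d scored pixels, accuracy %.3f\n", x$n, x$accuracy))
  print(x$counts)
  cat("sensitivity:", sprintf("%s %.3f", names(x$sensitivity), x$sensitivity), "\n")
  cat("specificity:", sprintf("%s %.3f", names(x$specificity), x$specificity), "\n")
  invisible(x)
}

#' Run the standard post-processing chain on a label image
#'
#' Convenience wrapper: noise-island filter, morphological merge, node
#' extraction -- the order used throughout the analysis.
#'
#' @param image a \code{\link{label_image}}.
#' @param mask optional lobe mask.
#' @param min_px noise floor for the island filter.
#' @param disk_diameter_px,iterations merge parameters.
#' @return \code{\link{injury_nodes}}.
#' @export
process_label_image <- function(image, mask = NULL, min_px = 100,
                                disk_diameter_px = 5, iterations = 5) {
  img <- filter_small_islands(image, min_px = min_px)
  img <- merge_close_injuries(img, disk_diameter_px = disk_diameter_px,
                              iterations = iterations)
  extract_injury_nodes(img, mask)
}

#' Write an injury node table to CSV
#'
#' @param nodes \code{\link{injury_nodes}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_nodes <- function(nodes, path) {
  utils::write.csv(as.data.frame(nodes), path, row.names = FALSE)
  invisible(path)
}
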