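# Class codes for pixel-classified histology. Fixed across the package and in
# all on-disk label images.
CLASS_CODES <- c(background = 0L, injury = 1L, air = 2L, other = 3L)

#' Construct a pixel-class label image
#'
#' A label image is an integer matrix with one class code per pixel:
#' 0 = background (outside the lobe / slide artifact), 1 = injury
#' (atelectasis or airspace edema), 2 = air, 3 = other tissue.
#'
#' @param grid integer matrix of class codes.
#' @param pixel_size_um optional physical pixel edge length in micrometres.
#' @return An object of class \code{label_image} (an integer matrix with
#'   attributes).
#' @export
label_image <- function(grid, pixel_size_um = NULL) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  g <- grid
  storage.mode(g) <- "integer"
  bad <- !(g %in% CLASS_CODES)
  if (any(bad)) stop("label image contains codes outside {0,1,2,3}")
  structure(g, pixel_size_um = pixel_size_um, class = c("label_image", class(g)))
}

#' @export
print.label_image <- function(x, ...) {
  tab <- table(factor(as.vector(x), levels = CLASS_CODES,
                      labels = names(CLASS_CODES)))
  cat(sprintf("<label_image> %d x %d px\n", nrow(x), ncol(x)))
  print(tab)
  invisible(x)
}

# Strip the label_image class so arithmetic sees a plain integer matrix.
as_grid <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Read a label image from a single-channel PNG or TIFF file
#'
#' Pixel values are interpreted as 8-bit class codes (0--3).
#'
#' @param path file path.
#' @param pixel_size_um optional pixel size passed through to the result.
#' @return A \code{\link{label_image}}.
#' @export
read_label_image <- function(path, pixel_size_um = NULL) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) > 2) a <- a[, , 1]
  g <- t(round(a * 255))
  storage.mode(g) <- "integer"
  label_image(g, pixel_size_um = pixel_size_um)
}

#' Write a label image to a single-channel PNG or TIFF file
#'
#' Codes are stored as 8-bit gray values so the file round-trips exactly
#' through \code{\link{read_label_image}}.
#'
#' @param image a \code{\link{label_image}}.
#' @param path output path; the extension selects the format (png or tiff).
#' @return \code{path}, invisibly.
#' @export
write_label_image <- function(image, path) {
  g <- as_grid(image)
  EBImage::writeImage(EBImage::Image(t(g) / 255), path)
  invisible(path)
}

# -- connected components ----------------------------------------------------

# 8-connected labelling of a binary mask. EBImage::bwlabel is 4-connected;
# diagonal-touching 4-components are merged with union-find, then labels are
# renumbered by first occurrence in column-major scan order.
label_components8 <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  nlab <- max(lab)
  if (nlab > 1) {
    parent <- seq_len(nlab)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    nr <- nrow(lab); nc <- ncol(lab)
    # diagonal neighbor pairs: (r,c)-(r+1,c+1) and (r+1,c)-(r,c+1)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
    a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(nlab), find, integer(1))
      lab[lab > 0] <- roots[lab[lab > 0]]
    }
  }
  # renumber by scan-order first occurrence
  v <- as.vector(lab)
  ids <- unique(v[v > 0])
  if (length(ids)) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  storage.mode(lab) <- "integer"
  lab
}

# Areas and (0-based) centroids of labelled components, in label order.
component_stats <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) {
    return(data.frame(id = integer(), row = numeric(), col = numeric(),
                      area = integer()))
  }
  l <- lab[idx]
  r <- (idx - 1L) %% nrow(lab)       # 0-based row
  c <- (idx - 1L) %/% nrow(lab)      # 0-based col
  area <- as.vector(rowsum(rep(1L, length(l)), l))
  ids <- sort(unique(l))
  data.frame(id = ids,
             row = as.vector(rowsum(as.numeric(r), l)) / area,
             col = as.vector(rowsum(as.numeric(c), l)) / area,
             area = as.integer(area))
}
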