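# Nearest-neighbor correlation network over injury nodes, after the
# seismological event-correlation metric: the expected number of comparable
# injuries in the space (and optionally time) separating two regions. Each
# node links to the single candidate parent minimizing that expectation;
# small weights mean correlations unlikely to arise by chance.

#' Model parameters for the correlation weight
#'
#' The pairwise weight is C * l^df * (t) * dm * m_parent^(-alpha): the
#' expected number of injuries of comparable size within the distance l
#' (and elapsed time t, in the timed variant) separating two regions.
#' C and dm cancel in every argmin and percentile threshold and default
#' to 1; alpha and df are the per-lobe fits of the injury-size exponent
#' and box-counting fractal dimension.
#'
#' @param alpha injury-size power-law exponent of the lobe.
#' @param df box-counting fractal dimension of the lobe.
#' @param C positive scaling constant.
#' @param delta_m magnitude interval width.
#' @return object of class \code{model_params}.
#' @export
model_params <- function(alpha, df, C = 1, delta_m = 1) {
  if (C <= 0 || delta_m <= 0) stop("C and delta_m must be positive")
  structure(list(C = C, delta_m = delta_m, alpha = alpha, df = df),
            class = "model_params")
}

#' Pairwise correlation weight between a candidate parent and a child node
#'
#' @param parent,child single-row subsets of an \code{\link{injury_nodes}}
#'   table (or lists with row, col, area).
#' @param params \code{\link{model_params}}.
#' @return the scalar weight C * l^df * dm * m_parent^(-alpha), with l the
#'   Euclidean centroid distance in pixel units.
#' @export
pairwise_weight <- function(parent, child, params) {
  l <- sqrt((parent$row - child$row)^2 + (parent$col - child$col)^2)
  if (l == 0) stop("degenerate geometry: coincident centroids")
  params$C * l^params$df * params$delta_m * parent$area^(-params$alpha)
}

# argmin with ties broken toward larger parent area, then smaller id
argmin_parent <- function(w, area, ids) {
  ord <- order(w, -area, ids)
  ord[1]
}

new_network <- function(nodes, edges, timed = FALSE, params = NULL) {
  structure(list(nodes = nodes, edges = edges, timed = timed, params = params),
            class = "injury_network")
}

#' Build the time-free nearest-neighbor correlation network
#'
#' For every node j the single candidate parent i (any other node) that
#' minimizes the pairwise weight is attached; all other links are discarded.
#' Ties break toward the larger parent area, then the smaller id.
#'
#' @param nodes \code{\link{injury_nodes}} (>= 2 rows for any edges).
#' @param params \code{\link{model_params}}.
#' @return object of class \code{injury_network} with an edge table
#'   (child, parent, weight), one edge per node.
#' @export
build_network <- function(nodes, params) {
  n <- nrow(nodes)
  if (n < 2) {
    return(new_network(nodes, data.frame(child = integer(0), parent = integer(0),
                                         weight = numeric(0))))
  }
  D <- as.matrix(stats::dist(cbind(nodes$row, nodes$col)))
  if (any(D[upper.tri(D)] == 0))
    stop("degenerate geometry: coincident centroids")
  # W[i, j]: weight of candidate parent i for child j
  W <- params$C * params$delta_m * D^params$df * nodes$area^(-params$alpha)
  diag(W) <- Inf
  parent_idx <- vapply(seq_len(n), function(j)
    argmin_parent(W[, j], nodes$area, nodes$id), integer(1))
  edges <- data.frame(child = nodes$id,
                      parent = nodes$id[parent_idx],
                      weight = W[cbind(parent_idx, seq_len(n))])
  new_network(nodes, edges, params = params)
}

#' @export
print.injury_network <- function(x, ...) {
  cat(sprintf("<injury_network> %d nodes, %d edges%s\n", nrow(x$nodes),
              nrow(x$edges), if (x$timed) " (timed)" else ""))
  invisible(x)
}

#' Threshold a network at a percentile of its edge weights
#'
#' Removes edges whose weight exceeds the cutoff n_c at the given percentile
#' of the edge-weight distribution (linear interpolation between order
#' statistics); smaller weights mean stronger correlations, so raising the
#' percentile retains more, weaker links.
#'
#' @param net \code{injury_network} with at least one edge.
#' @param percentile cutoff percentile, 0-100.
#' @return thresholded \code{injury_network}; all nodes retained.
#' @export
threshold_network <- function(net, percentile) {
  if (!nrow(net$edges)) stop("network has no edges")
  nc <- stats::quantile(net$edges$weight, percentile / 100, names = FALSE)
  out <- net
  out$edges <- net$edges[net$edges$weight <= nc, , drop = FALSE]
  out$threshold <- nc
  out
}

#' Per-node in-degrees of the correlation network
#'
#' The in-degree of node i is the number of nodes j whose selected parent is
#' i (the number of regions that correlate to it).
#'
#' @param net \code{injury_network}.
#' @return named integer vector over all node ids, in node-table order.
#' @export
in_degree_distribution <- function(net) {
  k <- table(factor(net$edges$parent, levels = net$nodes$id))
  stats::setNames(as.integer(k), net$nodes$id)
}

#' PageRank centrality of injury nodes
#'
#' Standard PageRank on the directed correlation network (dangling mass
#' redistributed uniformly). By default edges point child -> parent, so
#' rank flows toward the regions that other injuries correlate to; the
#' opposite orientation is available via \code{direction}.
#'
#' @param net \code{injury_network}.
#' @param damping damping factor in (0,1), default 0.85.
#' @param direction \code{"child_to_parent"} (default) or
#'   \code{"parent_to_child"}.
#' @return object of class \code{centrality_scores}: data frame (id, area,
#'   score) plus damping attribute. Scores sum to 1.
#' @export
pagerank_centrality <- function(net, damping = 0.85,
                                direction = c("child_to_parent", "parent_to_child")) {
  direction <- match.arg(direction)
  if (damping <= 0 || damping >= 1) stop("damping must be in (0,1)")
  ids <- as.character(net$nodes$id)
  el <- cbind(as.character(net$edges$child), as.character(net$edges$parent))
  if (direction == "parent_to_child") el <- el[, 2:1, drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2]),
    directed = TRUE,
    vertices = data.frame(name = ids))
  pr <- igraph::page_rank(g, damping = damping)$vector
  out <- data.frame(id = net$nodes$id, area = net$nodes$area,
                    score = unname(pr[ids]))
  structure(out, damping = damping, direction = direction,
            class = c("centrality_scores", "data.frame"))
}

#' Top-scoring fraction of nodes
#'
#' @param scores \code{centrality_scores}.
#' @param fraction fraction of nodes in (0, 1]; ceiling(fraction * N) nodes
#'   are returned.
#' @return integer vector of node ids, highest scores first; ties broken
#'   toward larger area, then smaller id.
#' @export
top_fraction <- function(scores, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- ceiling(fraction * nrow(scores))
  ord <- order(-scores$score, -scores$area, scores$id)
  scores$id[ord[seq_len(k)]]
}

#' Rescale centrality scores so the lobe maximum is 1
#'
#' Display normalization for comparing node ranks within a lobe.
#'
#' @param scores \code{centrality_scores}.
#' @return scores with a \code{score_norm} column added.
#' @export
normalize_centrality <- function(scores) {
  scores$score_norm <- scores$score / max(scores$score)
  scores
}

#' Export a network as a CSV edge list
#'
#' @param net \code{injury_network}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(net, path) {
  utils::write.csv(net$edges, path, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Node attributes row, col, area and magnitude and the edge weight are
#' preserved.
#'
#' @param net \code{injury_network}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("child", "parent", "weight")],
    directed = TRUE,
    vertices = net$nodes[, c("id", "row", "col", "area", "magnitude")])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @export
plot.injury_network <- function(x, scale_cex = 2, ...) {
  k <- in_degree_distribution(x)
  graphics::plot(x$nodes$col, -x$nodes$row, asp = 1,
                 cex = 0.5 + scale_cex * k / max(1, max(k)),
                 xlab = "col (px)", ylab = "-row (px)",
                 main = "injury correlation network", col = 4, ...)
  if (nrow(x$edges)) {
    ii <- match(x$edges$child, x$nodes$id)
    jj <- match(x$edges$parent, x$nodes$id)
    graphics::segments(x$nodes$col[ii], -x$nodes$row[ii],
                       x$nodes$col[jj], -x$nodes$row[jj], col = "darkgreen")
  }
  invisible(x)
}
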