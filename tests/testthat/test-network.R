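test_that("pairwise weight evaluates the correlation metric exactly", {
  par <- list(row = 0, col = 0, area = 4)
  chl <- list(row = 3, col = 4, area = 1)   # l = 5
  p <- model_params(alpha = 2, df = 2)
  expect_equal(pairwise_weight(par, chl, p), 25 / 16)   # 1.5625
  # df = 0: distance drops out
  p0 <- model_params(alpha = 2, df = 0)
  expect_equal(pairwise_weight(par, chl, p0), 1 / 16)
  # positive scaling of C scales weights, never argmins
  p2 <- model_params(alpha = 2, df = 2, C = 2)
  expect_equal(pairwise_weight(par, chl, p2), 2 * 25 / 16)
  expect_error(pairwise_weight(par, list(row = 0, col = 0, area = 1), p),
               "degenerate geometry")
})

test_that("collinear and two-node networks link as enumerated", {
  nodes <- injury_nodes(data.frame(id = 1:3, row = 0, col = c(0, 1, 3),
                                   area = 100))
  net <- build_network(nodes, model_params(alpha = 2, df = 1.5))
  edges <- net$edges[order(net$edges$child), ]
  expect_equal(edges$parent, c(2, 1, 2))   # ends pick the middle; middle picks nearer end
  two <- injury_nodes(data.frame(id = 1:2, row = c(0, 1), col = 0, area = 100))
  nt <- build_network(two, model_params(alpha = 2, df = 1.5))
  expect_setequal(paste(nt$edges$child, nt$edges$parent), c("1 2", "2 1"))
  one <- injury_nodes(data.frame(id = 1, row = 0, col = 0, area = 1))
  expect_equal(nrow(build_network(one, model_params(2, 1.5))$edges), 0)
})

test_that("network construction matches brute force on random instances", {
  for (s in 1:40) {
    n <- sample(3:50, 1)
    nodes <- random_nodes(n, seed = s)
    alpha <- runif(1, 1.5, 3); df <- runif(1, 0.5, 2)
    net <- build_network(nodes, model_params(alpha = alpha, df = df))
    bf <- bf_edges(nodes, alpha, df)
    got <- net$edges[order(net$edges$child), ]
    expect_equal(got$parent, bf$parent[order(bf$child)])
    expect_equal(got$weight, bf$weight[order(bf$child)], tolerance = 1e-12)
  }
})

test_that("edges are invariant to C, delta_m and global distance rescaling", {
  nodes <- random_nodes(40, seed = 77)
  base <- build_network(nodes, model_params(alpha = 2.2, df = 1.7))$edges
  scaled <- build_network(nodes, model_params(alpha = 2.2, df = 1.7,
                                              C = 13, delta_m = 0.4))$edges
  expect_equal(scaled$parent[order(scaled$child)], base$parent[order(base$child)])
  big <- nodes; big$row <- big$row * 3.7; big$col <- big$col * 3.7
  rescaled <- build_network(big, model_params(alpha = 2.2, df = 1.7))$edges
  expect_equal(rescaled$parent[order(rescaled$child)],
               base$parent[order(base$child)])
})

test_that("percentile thresholding keeps the strongest correlations", {
  nodes <- injury_nodes(data.frame(id = 1:5, row = c(0, 1, 2, 3, 10),
                                   col = 0, area = 100))
  net <- build_network(nodes, model_params(alpha = 2, df = 1))
  net$edges$weight <- c(1, 2, 3, 4, 5)   # fixed weights for the convention check
  expect_equal(nrow(threshold_network(net, 100)$edges), 5)
  w4 <- net; w4$edges <- net$edges[1:4, ]
  kept <- threshold_network(w4, 50)      # median of {1,2,3,4} = 2.5
  expect_equal(sort(kept$edges$weight), c(1, 2))
  mins <- threshold_network(net, 0)
  expect_equal(mins$edges$weight, 1)
  # retained-edge count is non-decreasing in the percentile
  counts <- vapply(c(0, 25, 50, 75, 100), function(p)
    nrow(threshold_network(net, p)$edges), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("hubs disproportionately retain correlations as thresholds rise", {
  # one giant region: a rich-get-richer instance where most nodes attach to it
  set.seed(5)
  nodes <- injury_nodes(data.frame(id = 1:60,
                                   row = runif(60, 0, 500),
                                   col = runif(60, 0, 500),
                                   area = c(5e4, (1 - runif(59))^(-2/3) * 100)))
  net <- build_network(nodes, model_params(alpha = 2, df = 1.8))
  k <- in_degree_distribution(net)
  hub <- names(which.max(k))
  for (p in c(25, 50, 75)) {
    thr <- threshold_network(net, p)
    hub_kept <- sum(thr$edges$parent == hub) / max(1, sum(net$edges$parent == hub))
    other_kept <- sum(thr$edges$parent != hub) / sum(net$edges$parent != hub)
    expect_gte(hub_kept, other_kept)
  }
})

test_that("in-degrees count correlating regions and conserve edge count", {
  nodes <- injury_nodes(data.frame(id = 1:6, row = c(0, 1, 1, -1, 2, -2),
                                   col = c(0, 1, -1, 1, 0, 0),
                                   area = c(1e6, rep(100, 5))))
  net <- build_network(nodes, model_params(alpha = 2, df = 1))
  k <- in_degree_distribution(net)
  expect_equal(sum(k), nrow(net$edges))
  expect_equal(unname(k["1"]), 5L)   # star: every small node picks the giant
  two <- build_network(injury_nodes(data.frame(id = 1:2, row = c(0, 1), col = 0,
                                               area = 10)),
                       model_params(2, 1))
  expect_equal(unname(in_degree_distribution(two)), c(1L, 1L))
})

test_that("PageRank respects conservation, bounds and symmetric fixed points", {
  nodes <- injury_nodes(data.frame(id = 1:4, row = 1:4, col = 0, area = 10))
  empty <- lunginjurynet:::new_network(nodes, data.frame(
    child = integer(0), parent = integer(0), weight = numeric(0)))
  sc <- pagerank_centrality(empty)
  expect_equal(sc$score, rep(0.25, 4))
  cyc <- lunginjurynet:::new_network(
    injury_nodes(data.frame(id = 1:3, row = 1:3, col = 0, area = 10)),
    data.frame(child = 1:3, parent = c(2, 3, 1), weight = 1))
  expect_equal(pagerank_centrality(cyc)$score, rep(1/3, 3), tolerance = 1e-9)
  net <- build_network(random_nodes(80, seed = 12), model_params(2, 1.8))
  sc2 <- pagerank_centrality(net, damping = 0.85)
  expect_equal(sum(sc2$score), 1, tolerance = 1e-9)
  expect_true(all(sc2$score >= 0.15 / 80 - 1e-12))
  expect_error(pagerank_centrality(net, damping = 1.2), "damping")
})

test_that("top-fraction selection is deterministic with documented ties", {
  nodes <- random_nodes(200, seed = 31)
  net <- build_network(nodes, model_params(2.5, 1.8))
  sc <- pagerank_centrality(net)
  expect_equal(length(top_fraction(sc, 0.005)), 1)   # ceil(0.005 * 200)
  expect_setequal(top_fraction(sc, 1), nodes$id)
  shuffled <- sc[sample(nrow(sc)), ]
  class(shuffled) <- class(sc)
  expect_equal(top_fraction(shuffled, 0.1), top_fraction(sc, 0.1))
  expect_error(top_fraction(sc, 0), "fraction")
})

test_that("network exports round-trip through edge list and GraphML", {
  net <- build_network(random_nodes(20, seed = 2), model_params(2, 1.5))
  csv <- tempfile(fileext = ".csv")
  write_edge_list(net, csv)
  back <- read.csv(csv)
  expect_equal(back$parent, net$edges$parent)
  gml <- tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 20)
  expect_equal(igraph::gsize(g), 20)
})
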