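test_that("time assignment is an exponential renewal sequence", {
  nodes <- random_nodes(200, seed = 1)
  a <- assign_times(nodes, mean_interval_s = 2, seed = 3)
  expect_setequal(a$id, nodes$id)
  t_ord <- a$time[match(attr(a, "order"), a$id)]
  expect_true(all(diff(t_ord) > 0))
  one <- assign_times(random_nodes(1, seed = 2), seed = 5)
  expect_equal(nrow(one), 1)
  expect_gt(one$time, 0)
  empty <- assign_times(injury_nodes(data.frame(id = integer(0),
                                                row = numeric(0),
                                                col = numeric(0),
                                                area = numeric(0))))
  expect_equal(nrow(empty), 0)
  expect_error(assign_times(nodes, mean_interval_s = 0), "positive")
})

test_that("sampled inter-injury intervals match the 2-second mean", {
  nodes <- sample_injury_nodes(10001, alpha = 2.5, xmin = 100, seed = 8)
  a <- assign_times(nodes, mean_interval_s = 2, seed = 12)
  gaps <- diff(sort(a$time))
  expect_equal(length(gaps), 10000)
  expect_lt(abs(mean(gaps) - 2), 0.06)   # 3 sigma / sqrt(n) with sigma = 2
})

test_that("timed networks respect causality and match brute force", {
  for (s in 1:30) {
    n <- sample(3:30, 1)
    nodes <- random_nodes(n, seed = 100 + s)
    a <- assign_times(nodes, seed = 200 + s)
    alpha <- runif(1, 1.5, 3); df <- runif(1, 0.5, 2)
    net <- build_time_network(nodes, a, model_params(alpha = alpha, df = df))
    t <- a$time[match(nodes$id, a$id)]
    expect_equal(nrow(net$edges), n - 1)          # one root
    expect_true(all(net$edges$dt > 0))            # parent precedes child
    bf <- bf_time_edges(nodes, t, alpha, df)
    got <- net$edges[order(net$edges$child), ]
    expect_equal(got$parent, bf$parent[order(bf$child)])
    expect_equal(got$weight, bf$weight[order(bf$child)], tolerance = 1e-12)
  }
})

test_that("under exchangeable geometry each event links to its predecessor", {
  # equilateral triangle, equal areas: t_ij alone decides the argmin
  nodes <- injury_nodes(data.frame(id = 1:3,
                                   row = c(0, 1, 0.5),
                                   col = c(0, 0, sqrt(3) / 2),
                                   area = 100))
  a <- assign_times(nodes, seed = 4)
  net <- build_time_network(nodes, a, model_params(alpha = 2, df = 1.5))
  ord <- attr(a, "order")
  expect_equal(nrow(net$edges), 2)
  for (k in 2:3) {
    e <- net$edges[net$edges$child == ord[k], ]
    expect_equal(e$parent, ord[k - 1])
  }
  # two events: later links to earlier, earlier is root
  two <- injury_nodes(data.frame(id = 1:2, row = c(0, 5), col = 0, area = 50))
  a2 <- assign_times(two, seed = 9)
  n2 <- build_time_network(two, a2, model_params(2, 1))
  first <- attr(a2, "order")[1]
  expect_equal(n2$edges$child, setdiff(1:2, first))
  expect_equal(n2$edges$parent, first)
})

test_that("ensembles are reproducible and derived from the master seed", {
  nodes <- random_nodes(60, seed = 3)
  p <- model_params(2.2, 1.8)
  e1 <- ensemble_run(nodes, p, n_reps = 4, seed = 7)
  e2 <- ensemble_run(nodes, p, n_reps = 4, seed = 7)
  expect_identical(e1$seeds, e2$seeds)
  expect_identical(e1$networks[[3]]$edges, e2$networks[[3]]$edges)
  single <- ensemble_run(nodes, p, n_reps = 1, seed = 7)
  direct <- build_time_network(nodes,
                               assign_times(nodes, 2, seed = single$seeds[1]), p)
  expect_identical(single$networks[[1]]$edges, direct$edges)
})

test_that("gamma comparison flags shifts and degenerate ensembles", {
  k <- c(rep(1, 30), rep(2, 8), rep(3, 4), 5, 9, 17)
  f <- fit_powerlaw(k, "discrete", xmin = 1)
  null_cmp <- compare_gamma(f, list(f, f, f, f, f), n_boot = 400, seed = 2)
  expect_equal(null_cmp$difference, 0)
  expect_equal(null_cmp$p_value, 1)
  shifted <- lapply(1:6, function(i) { g <- f; g$alpha_hat <- f$alpha_hat + 1 + 0.01 * i; g })
  s_cmp <- compare_gamma(f, shifted, n_boot = 400, seed = 3)
  expect_gt(s_cmp$ci[1], 0)   # CI excludes zero
  expect_warning(one <- compare_gamma(f, list(f), n_boot = 100, seed = 1),
                 "degenerate")
  expect_true(one$degenerate)
})

test_that("centrality overlap is exact for identical scores and full sets", {
  nodes <- random_nodes(300, seed = 14)
  net <- build_network(nodes, model_params(2.3, 1.8))
  sc <- pagerank_centrality(net)
  ov <- centrality_overlap(sc, list(sc, sc), top_frac_no_time = 0.01,
                           grid = c(0.01, 0.1, 1), n_boot = 50)
  expect_equal(ov$overlap, c(1, 1, 1))
  expect_equal(ov$chance, c(0.01, 0.1, 1))
  expect_true(all(diff(ov$overlap) >= 0))
  bad <- sc[-1, ]; class(bad) <- class(sc)
  expect_error(centrality_overlap(sc, list(bad)), "different node ids")
})

test_that("permuted scores fall on the chance line", {
  nodes <- random_nodes(400, seed = 4)
  net <- build_network(nodes, model_params(2.5, 1.8))
  sc <- pagerank_centrality(net)
  set.seed(9)
  sc$score <- runif(400)   # distinct scores so ties cannot mask the shuffle
  perm <- lapply(1:60, function(i) { s <- sc; s$score <- sample(s$score); s })
  grid <- c(0.1, 0.25, 0.5)
  ov <- centrality_overlap(sc, perm, top_frac_no_time = 0.05, grid = grid,
                           n_boot = 20)
  band <- 1.96 * sqrt(grid * (1 - grid) / (60 * ceiling(0.05 * 400))) + 0.02
  expect_true(all(abs(ov$overlap - grid) <= band))
})

test_that("rate curves reproduce the hand-counted decay construction", {
  nodes <- injury_nodes(data.frame(id = 1:5, row = c(0, 10, 20, 30, 40),
                                   col = 0, area = c(1000, 10, 10, 10, 10)))
  net <- lunginjurynet:::new_network(
    nodes, data.frame(child = 2:5, parent = 1, weight = 1, dt = c(1, 2, 4, 8)),
    timed = TRUE)
  rc <- secondary_event_rates(list(net), bin_edges = c(1, 2, 4, 8, 16),
                              n_boot = 10)
  agg <- rc[rc$magnitude_class == "all", ]
  expect_equal(agg$rate, c(1, 0.5, 0.25, 0.125))
  slope <- coef(lm(log(agg$rate) ~ log(sqrt(agg$bin_lo * agg$bin_hi))))[[2]]
  expect_equal(slope, -1, tolerance = 1e-10)
  # all four events sit in the magnitude-3 parent class
  m3 <- rc[rc$magnitude_class == "3", ]
  expect_equal(sum(m3$rate * (m3$bin_hi - m3$bin_lo)), 4)
})

test_that("rates conserve events, stay non-negative, and handle empties", {
  nodes <- random_nodes(80, seed = 21)
  ens <- ensemble_run(nodes, model_params(2.2, 1.8), n_reps = 5, seed = 31,
                      fit_indegree = FALSE)
  rc <- secondary_event_rates(ens, n_boot = 20)
  expect_true(all(rc$rate >= 0))
  expect_true(all(rc$ci_lo <= rc$rate + 1e-12 & rc$rate <= rc$ci_hi + 1e-12))
  agg <- rc[rc$magnitude_class == "all", ]
  per_rep <- sum(agg$rate * (agg$bin_hi - agg$bin_lo))
  expect_equal(per_rep, 79)   # mean events per replicate = N - 1
  expect_error(secondary_event_rates(list()), "empty")
})

test_that("larger primaries attract secondary events at higher rates", {
  set.seed(17)
  nodes <- injury_nodes(data.frame(
    id = 1:300, row = runif(300, 0, 4000), col = runif(300, 0, 4000),
    area = c(rep(5000, 6), rep(150, 294))))   # magnitude-3 vs magnitude-2 parents
  ens <- ensemble_run(nodes, model_params(2, 1.8), n_reps = 20, seed = 5,
                      fit_indegree = FALSE)
  rc <- secondary_event_rates(ens, normalize = "per_primary", n_boot = 20)
  m3 <- rc[rc$magnitude_class == "3", ]
  m2 <- rc[rc$magnitude_class == "2", ]
  shared <- intersect(m3$bin_lo[m3$rate > 0], m2$bin_lo[m2$rate > 0])
  expect_gt(length(shared), 2)
  expect_true(mean(m3$rate[match(shared, m3$bin_lo)] >
                   m2$rate[match(shared, m2$bin_lo)]) > 0.8)
})

test_that("timed ensembles stay scale-free when the static network is", {
  nodes <- sample_injury_nodes(400, alpha = 2, xmin = 100, seed = 23)
  alpha_hat <- fit_powerlaw(nodes$area, "continuous", xmin = 100)$alpha_hat
  p <- model_params(alpha_hat, 1.8)
  net <- build_network(nodes, p)
  k <- in_degree_distribution(net)
  f0 <- ks_plausibility(fit_powerlaw(k[k > 0], "discrete", xmin = 1),
                        n_boot = 100, seed = 1)
  ens <- ensemble_run(nodes, p, n_reps = 10, seed = 2, plausibility_boot = 100)
  plaus <- vapply(ens$fits, function(f) isTRUE(f$plausible), logical(1))
  if (f0$plausible) expect_gt(mean(plaus), 0.5)
})
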