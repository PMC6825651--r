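test_that("tanimoto matches the set formula and its edge cases", {
  expect_equal(tanimoto(c(1, 1, 1, 0), c(1, 1, 0, 1)), 0.5) # 2 / 4
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 0) # both empty, defined as 0
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("tanimoto is symmetric and 1 iff bitsets are identical", {
  set.seed(3)
  for (rep in 1:25) {
    a <- sample(0:1, 32, replace = TRUE)
    b <- sample(0:1, 32, replace = TRUE)
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    if (sum(a) > 0) expect_equal(tanimoto(a, a), 1)
    if (!identical(a, b)) expect_lt(tanimoto(a, b), 1)
  }
})

test_that("pairwise similarity matrix agrees with elementwise computation", {
  set.seed(5)
  fps <- matrix(sample(0:1, 6 * 24, replace = TRUE, prob = c(0.7, 0.3)), 6, 24,
                dimnames = list(paste0("m", 1:6), NULL))
  sim <- tanimoto_matrix(fps)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(sim[i, j], tanimoto(fps[i, ], fps[j, ]))
  expect_true(isSymmetric(sim))
  expect_equal(unname(diag(sim)), rep(1, 6))
})

test_that("graph construction respects the threshold and keeps all nodes", {
  # three molecules with pairwise Tc 0.4, 0.2, 0.6 approximately constructed
  fps <- rbind(a = c(rep(1, 5), rep(0, 7)),
               b = c(rep(1, 3), rep(0, 4), rep(1, 2), rep(0, 3)),
               c = c(rep(1, 2), rep(0, 7), rep(1, 3)))
  sim <- tanimoto_matrix(fps)
  g <- build_graph(fps, 0.3)
  expected <- sum(sim[upper.tri(sim)] >= 0.3)
  expect_equal(igraph::ecount(g), expected)
  expect_equal(igraph::vcount(g), 3)
  # threshold 0 -> complete graph
  g0 <- build_graph(fps, 0)
  expect_equal(igraph::ecount(g0), 3)
  # threshold above max similarity -> edgeless but all nodes retained
  gmax <- build_graph(fps, max(sim[upper.tri(sim)]) + 1e-9)
  expect_equal(igraph::ecount(gmax), 0)
  expect_equal(igraph::vcount(gmax), 3)
  expect_error(build_graph(fps[1, , drop = FALSE], 0.5), "at least 2")
  expect_error(build_graph(fps, 1.5), "t_alpha")
})

test_that("edges are monotone decreasing in the threshold", {
  bench <- generate_benchmark(benchmark_spec(n_modules = 2, per_module = 10,
                                             seed = 8))
  sim <- tanimoto_matrix(bench$molecules$fingerprints)
  edge_set <- function(t) {
    g <- build_graph(NULL, t, sim = sim)
    e <- igraph::ends(g, igraph::E(g))
    if (nrow(e) == 0) character(0) else paste(e[, 1], e[, 2])
  }
  thresholds <- c(0, 0.1, 0.3, 0.5, 0.7, 0.9)
  for (k in seq_len(length(thresholds) - 1)) {
    e1 <- edge_set(thresholds[k])
    e2 <- edge_set(thresholds[k + 1])
    expect_true(all(e2 %in% e1))
  }
})

test_that("average clustering matches hand counts and a brute-force oracle", {
  expect_equal(average_clustering(igraph::make_full_graph(5)), 1)
  expect_equal(average_clustering(igraph::make_star(4, mode = "undirected")), 0)
  # triangle plus a pendant on node 3: local ccs are 1, 1, 1/3, 0
  tri <- igraph::add_edges(igraph::make_full_graph(3) + igraph::make_empty_graph(1, directed = FALSE),
                           c(3, 4))
  expect_equal(average_clustering(tri), (1 + 1 + 1 / 3 + 0) / 4)
  expect_equal(average_clustering(tri), brute_average_clustering(tri))
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    g <- igraph::sample_gnp(n, stats::runif(1, 0.2, 0.9))
    expect_equal(average_clustering(g), brute_average_clustering(g))
  }
})

test_that("threshold scan uses one similarity computation and records ACC", {
  bench <- generate_benchmark(benchmark_spec(n_modules = 2, per_module = 10,
                                             seed = 2))
  scan <- threshold_scan(bench$molecules)
  expect_s3_class(scan, "threshold_scan")
  expect_equal(nrow(scan$table), 100)
  expect_equal(scan$table$acc[1], 1) # complete network at threshold 0
  expect_true(all(scan$table$acc >= 0 & scan$table$acc <= 1))
  expect_true(scan$t_star %in% scan$table$t_alpha)
  expect_error(threshold_scan(bench$molecules, grid = c(0.5, 0.2)), "increasing")
})

test_that("peak detection finds the first post-decline ACC maximum", {
  scan <- structure(list(table = data.frame(
    t_alpha = c(0, .1, .2, .3, .4, .5),
    acc = c(1.0, 0.4, 0.3, 0.6, 0.5, 0.2),
    n_modules = NA, n_singletons = NA), t_star = NA), class = "threshold_scan")
  expect_equal(optimal_threshold(scan), 0.3)
  # monotone decline has no recovery peak -> fallback with warning
  scan$table$acc <- seq(1, 0.5, length.out = 6)
  expect_warning(t_fb <- optimal_threshold(scan), "fallback")
  expect_true(t_fb > 0 && t_fb <= 0.5)
})

test_that("the selected threshold lands in the planted similarity gap", {
  bench <- generate_benchmark(benchmark_spec(seed = 19))
  sim <- tanimoto_matrix(bench$molecules$fingerprints)
  lab <- bench$truth$labels
  same <- outer(lab, lab, "==") & upper.tri(sim)
  diff <- !outer(lab, lab, "==") & upper.tri(sim)
  gap <- c(max(sim[diff]), min(sim[same]))
  expect_lt(gap[1], gap[2]) # generator honours its own gap
  scan <- threshold_scan(bench$molecules)
  expect_gt(scan$t_star, gap[1])
  expect_lte(scan$t_star, gap[2])
})

test_that("graphml and scan exports write readable files", {
  bench <- generate_benchmark(benchmark_spec(n_modules = 2, per_module = 6,
                                             seed = 4))
  g <- build_graph(bench$molecules$fingerprints, 0.3)
  f <- tempfile(fileext = ".graphml")
  export_graphml(g, f)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_true("tanimoto" %in% igraph::edge_attr_names(g2))
  # a 10-point grid is too coarse for a reliable peak; only the table matters
  scan <- suppressWarnings(threshold_scan(bench$molecules, grid = seq(0, 0.9, 0.1)))
  fs <- tempfile(fileext = ".csv")
  export_scan(scan, fs)
  expect_equal(nrow(utils::read.csv(fs)), 10)
})
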