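test_that("single-region fits recover exact linear and constant relations", {
  x <- seq(0, 1, length.out = 15)
  m <- fit_fixed(cbind(x = x), 2 * x, R = 1, lambda = 0)
  expect_equal(m$regions[[1]]$coefficients[["x"]], 2, tolerance = 1e-9)
  expect_equal(m$regions[[1]]$intercept, 0, tolerance = 1e-9)
  expect_equal(m$train_mae, 0, tolerance = 1e-12)
  # constant response: the L1 penalty zeroes every coefficient
  mc <- fit_fixed(cbind(x = x, z = stats::runif(15)), rep(5, 15),
                  R = 1, lambda = 0.05)
  expect_length(mc$regions[[1]]$coefficients, 0)
  expect_equal(mc$regions[[1]]$intercept, 5)
  expect_equal(mc$train_mae, 0)
})

test_that("two-region fits find the planted breakpoint and slopes", {
  x <- seq(0.025, 0.975, length.out = 20)
  y <- ifelse(x < 0.5, x + 1, 3 - x)
  m <- fit_fixed(cbind(D1 = x), y, feature = "D1", R = 2, lambda = 0)
  gap <- c(max(x[x < 0.5]), min(x[x >= 0.5]))
  expect_gte(m$breakpoints, gap[1])
  expect_lte(m$breakpoints, gap[2])
  expect_equal(m$regions[[1]]$coefficients[["D1"]], 1, tolerance = 1e-6)
  expect_equal(m$regions[[2]]$coefficients[["D1"]], -1, tolerance = 1e-6)
  expect_equal(m$train_mae, 0, tolerance = 1e-9)
  # matches the exhaustive split-enumeration oracle
  expect_equal(m$objective, two_region_oracle(x, y), tolerance = 1e-9)
  # the iterative fit reaches the same structure
  mf <- fit_oplra(cbind(D1 = x), y, lambda = 0)
  expect_equal(mf$R, 2)
  expect_equal(mf$breakpoints, m$breakpoints)
})

test_that("fixed-R optimum matches exhaustive enumeration on random instances", {
  set.seed(99)
  ctrl <- oplra_control(min_region_size = 1)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    x <- stats::runif(n)
    y <- stats::runif(n, 4, 9)
    m <- fit_fixed(cbind(D1 = x), y, feature = "D1", R = 2, lambda = 0,
                   control = ctrl)
    expect_equal(m$objective, two_region_oracle(x, y), tolerance = 1e-6)
  }
})

test_that("sizing and degenerate inputs raise typed errors", {
  x <- cbind(D1 = stats::runif(6))
  expect_error(fit_fixed(x, stats::runif(6), feature = "D1", R = 2,
                         lambda = 0), "sizing")
  expect_error(fit_fixed(x, stats::runif(6), feature = "nope", R = 2,
                         lambda = 0, control = oplra_control(min_region_size = 3)),
               "partition feature")
  # single sample: constant model equal to its activity
  m1 <- fit_oplra(cbind(D1 = 0.3), 6.25)
  expect_true(m1$constant)
  expect_equal(predict_piecewise(m1, c(D1 = 0.9)), 6.25)
})

test_that("region growth stops when the error improvement fades", {
  set.seed(17)
  x <- stats::runif(40)
  y_noise <- stats::rnorm(40, 6, 1) # no structure at all
  m <- fit_oplra(cbind(D1 = x), y_noise, lambda = 0.005)
  expect_lte(m$R, oplra_control()$r_max)
  # with structure, accepted models never increase the training error
  y2 <- ifelse(x < 0.33, 4 + 2 * x, ifelse(x < 0.66, 8 - 3 * x, 2 + 3 * x))
  m1 <- fit_fixed(cbind(D1 = x), y2, R = 1, lambda = 0)
  m2 <- fit_fixed(cbind(D1 = x), y2, feature = "D1", R = 2, lambda = 0)
  m3 <- fit_fixed(cbind(D1 = x), y2, feature = "D1", R = 3, lambda = 0)
  expect_lte(m2$train_mae, m1$train_mae + 1e-9)
  expect_lte(m3$train_mae, m2$train_mae + 1e-9)
})

test_that("stronger regularisation never adds nonzero coefficients", {
  set.seed(23)
  n <- 30
  X <- matrix(stats::runif(n * 5), n, 5, dimnames = list(NULL, paste0("D", 1:5)))
  y <- 3 * X[, 1] - 2 * X[, 3] + 5 + stats::rnorm(n, 0, 0.05)
  nz <- vapply(c(0, 0.005, 0.05, 0.1, 0.5, 2), function(lam) {
    m <- fit_fixed(X, y, R = 1, lambda = lam)
    sum(abs(m$regions[[1]]$coefficients) > 1e-8)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("planted breakpoints and slope signs are recovered under noise", {
  # one planted module of 60 samples, noise sd 0.1: the recovered breakpoint
  # must fall in the true split's sample gap with matching slope signs for
  # at least 9 of 10 seeds
  hits <- 0
  for (s in 1:10) {
    b <- generate_benchmark(benchmark_spec(n_modules = 1, per_module = 60,
                                           noise_sd = 0.1, seed = 400 + s))
    X <- b$molecules$descriptors
    m <- fit_oplra(X, unname(b$molecules$activity),
                   control = oplra_control(r_max = 2))
    feat <- b$truth$features[1]
    bp_true <- b$truth$breakpoints[[1]]
    if (!identical(m$partition_feature, feat) || length(m$breakpoints) != 1) next
    x <- X[, feat]
    gap <- c(max(x[x < bp_true]), min(x[x >= bp_true]))
    signs <- vapply(m$regions, function(r) {
      co <- r$coefficients[feat]
      if (is.na(co)) 0 else sign(co)
    }, numeric(1))
    if (m$breakpoints >= gap[1] && m$breakpoints <= gap[2] &&
        all(signs == sign(b$truth$regions[[1]]$slope)))
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("piecewise prediction follows the half-open region convention", {
  x <- seq(0.025, 0.975, length.out = 20)
  y <- ifelse(x < 0.5, x + 1, 3 - x)
  m <- fit_fixed(cbind(D1 = x), y, feature = "D1", R = 2, lambda = 0)
  expect_equal(predict_piecewise(m, c(D1 = 0.1)), 1.1, tolerance = 1e-6)
  expect_equal(predict_piecewise(m, c(D1 = 0.9)), 2.1, tolerance = 1e-6)
  # a value exactly at the breakpoint belongs to the upper region
  bp <- m$breakpoints
  expect_equal(predict_piecewise(m, c(D1 = bp)),
               m$regions[[2]]$intercept + m$regions[[2]]$coefficients[["D1"]] * bp)
  expect_error(predict_piecewise(m, c(D2 = 0.1)), "missing descriptor")
})

test_that("rule tables render readable breakpoint rules and equations", {
  x <- seq(0.025, 0.975, length.out = 20)
  m <- fit_fixed(cbind(D1 = x), ifelse(x < 0.5, x + 1, 3 - x),
                 feature = "D1", R = 2, lambda = 0)
  tab <- rule_table(m, module = "m01")
  expect_equal(nrow(tab), 2)
  expect_match(tab$rule[1], "D1 <")
  expect_match(tab$equation[1], "pIC50 = ")
  expect_output(print(m), "region")
})
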