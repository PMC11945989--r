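test_that("ordered-simplex projection matches the active-set QP oracle", {
  expect_equal(as.numeric(project_ordered_simplex(c(0.5, 0.5, 0.5))),
               rep(1 / 3, 3), tolerance = 1e-12)
  # already-feasible points are fixed
  expect_equal(as.numeric(project_ordered_simplex(c(0.6, 0.3, 0.1))),
               c(0.6, 0.3, 0.1), tolerance = 1e-12)
  expect_equal(as.numeric(project_ordered_simplex(c(0, 1))),
               oracle_ordered_simplex(c(0, 1)), tolerance = 1e-9)
  set.seed(21)
  for (i in 1:60) {
    q <- sample(2:6, 1)
    y <- rnorm(q, sd = sample(c(0.3, 1, 5), 1))
    th <- as.numeric(project_ordered_simplex(y))
    expect_lt(max(abs(th - oracle_ordered_simplex(y))), 1e-9)
    # feasibility and idempotence
    expect_equal(sum(th), 1, tolerance = 1e-12)
    expect_true(all(diff(th) <= 1e-12) && all(th >= -1e-12))
    expect_equal(as.numeric(project_ordered_simplex(th)), th,
                 tolerance = 1e-12)
  }
  expect_error(project_ordered_simplex(numeric(0)), "empty")
  expect_error(project_ordered_simplex(c(1, NA)), "non-finite")
})

test_that("monotone spline fit equals the constrained-QP oracle", {
  set.seed(31)
  for (i in 1:8) {
    n <- 120
    u <- runif(n)
    kn <- place_knots(u, 2)        # small basis keeps the oracle exhaustive
    Z <- sin(2 * pi * u) + rnorm(n, sd = 0.3)
    fit <- fit_monotone_spline(Z, u, kn)
    orc <- oracle_monotone_ls(Z, bspline_design(u, kn))
    expect_lt(abs(fit$rss - orc$rss), 1e-6)
    expect_true(all(diff(fit$coef) >= -1e-10))
    grid <- seq(0, 1, length.out = 500)
    expect_true(all(diff(eval_effect(fit, grid, scale = "u")) >= -1e-9))
  }
})

test_that("monotone fit is exact when the truth is increasing or constant", {
  set.seed(32)
  u <- runif(300)
  kn <- place_knots(u, 5)
  # noiseless increasing signal in the spline span: recovered exactly, and
  # the constraint is inactive so it matches the unconstrained fit
  Z <- 2 + 3 * u
  fm <- fit_monotone_spline(Z, u, kn)
  fu <- fit_unconstrained_spline(Z, u, kn)
  expect_lt(max(abs(fm$fitted - Z)), 1e-8)
  expect_lt(abs(fm$rss - fu$rss), 1e-9)
  # constant response is reproduced exactly
  fc <- fit_monotone_spline(rep(4.2, 300), u, kn)
  expect_equal(fc$fitted, rep(4.2, 300), tolerance = 1e-10)
})

test_that("monotone fit of a decreasing signal beats no constant and stays flat", {
  set.seed(33)
  u <- runif(200)
  kn <- place_knots(u, 3)
  Z <- 5 - 4 * u + rnorm(200, sd = 0.1)
  fit <- fit_monotone_spline(Z, u, kn)
  # best non-decreasing approximation of a decreasing trend: RSS at most the
  # constant fit's (equivalently the oracle's), never more
  expect_lte(fit$rss, sum((Z - mean(Z))^2) + 1e-9)
  orc <- oracle_monotone_ls(Z, bspline_design(u, kn))
  expect_lt(abs(fit$rss - orc$rss), 1e-6)
})

test_that("unconstrained spline fit nests low-order polynomial fits", {
  set.seed(34)
  n <- 500
  u <- runif(n)
  kn <- place_knots(u, knot_count(n))
  Z <- sin(2 * pi * u)
  fit <- fit_unconstrained_spline(Z, u, kn)
  rss_poly <- sum(lm(Z ~ poly(u, 3))$residuals^2)
  expect_lte(fit$rss, rss_poly)
  # exact reproduction of a signal already in the span
  B <- bspline_design(u, kn)
  Zin <- drop(B %*% seq_len(ncol(B)))
  expect_lt(fit_unconstrained_spline(Zin, u, kn)$rss, 1e-16)
  expect_error(fit_unconstrained_spline(Z[1:5], u[1:5], kn), "basis")
})

test_that("single-index fit recovers known weights with an identity link", {
  X <- ar1_block(2000, 2, seed = 41)
  th <- c(0.5, 0.3, 0.2)
  set.seed(42)
  Z <- drop(X %*% th) + rnorm(2000, sd = 0.05)
  sf <- fit_single_index(Z, X, monotone_g = TRUE)
  expect_lt(max(abs(as.numeric(sf$weights) - th)), 0.05)
  expect_true(sf$converged)
})

test_that("single-index fit with a single lag column is a pure spline fit", {
  X <- ar1_block(300, 0, seed = 43)
  Z <- 0.01 * drop(X) + rnorm(300, sd = 0.02)
  sf <- fit_single_index(Z, X, monotone_g = TRUE)
  expect_identical(as.numeric(sf$weights), 1)
  a <- select_scale(X)
  tr <- index_transform(0, a)
  u <- rescaled_beta_cdf(drop(X), tr)
  direct <- fit_monotone_spline(Z, u, place_knots(u, knot_count(300)), tr)
  expect_equal(sf$rss, direct$rss, tolerance = 1e-12)
})

test_that("single-index fit descends from any feasible start on pure noise", {
  X <- ar1_block(400, 3, seed = 44)
  set.seed(45)
  Z <- rnorm(400)
  init <- c(0.4, 0.3, 0.2, 0.1)
  a <- select_scale(X)
  tr <- index_transform(3, a)
  u0 <- rescaled_beta_cdf(drop(X %*% init), tr)
  rss0 <- fit_monotone_spline(Z, u0, place_knots(u0, knot_count(400)))$rss
  sf <- fit_single_index(Z, X, monotone_g = TRUE, init = init)
  expect_lte(sf$rss, rss0 + 1e-6)
  # weights remain feasible
  th <- as.numeric(sf$weights)
  expect_equal(sum(th), 1, tolerance = 1e-10)
  expect_true(all(diff(th) <= 1e-10) && all(th >= 0))
})
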