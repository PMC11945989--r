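test_that("rescaled centred Beta CDF matches quadrature, symmetry and bounds", {
  for (d in c(0, 1, 3, 7)) {
    for (a in c(0.5, 1, 30)) {
      tr <- index_transform(d, a)
      expect_equal(rescaled_beta_cdf(-a, tr), 0)
      expect_equal(rescaled_beta_cdf(a, tr), 1)
      expect_equal(rescaled_beta_cdf(0, tr), 0.5)
      v <- seq(-a, a, length.out = 11)
      # symmetry and monotonicity
      expect_equal(rescaled_beta_cdf(-v, tr), 1 - rescaled_beta_cdf(v, tr),
                   tolerance = 1e-12)
      expect_true(all(diff(rescaled_beta_cdf(v, tr)) >= 0))
      # agreement with adaptive quadrature of the density
      quad <- vapply(v, oracle_beta_cdf, numeric(1), d = d, a = a)
      expect_lt(max(abs(rescaled_beta_cdf(v, tr) - quad)), 1e-10)
    }
  }
  # spot value at the midpoint of the support: v = a/2, d = 1, a = 1
  tr <- index_transform(1, 1)
  expect_equal(rescaled_beta_cdf(0.5, tr), oracle_beta_cdf(0.5, 1, 1),
               tolerance = 1e-10)
})

test_that("index values beyond the scale are clamped to the boundary", {
  tr <- index_transform(2, 10)
  expect_equal(rescaled_beta_cdf(c(-50, 50), tr), c(0, 1))
  expect_equal(rescaled_beta_pdf(c(-50, -10, 10, 50), tr), rep(0, 4))
})

test_that("transform construction rejects invalid scale and lag order", {
  expect_error(index_transform(2, 0), "positive")
  expect_error(index_transform(2, -1), "positive")
  expect_error(index_transform(-1, 1), "integer")
})

test_that("index scale is the nearest-rank 95th percentile of row sup norms", {
  # sup norms exactly 1..100 -> nearest-rank 95th percentile is 95
  blk <- cbind(1:100, 0)
  expect_equal(select_scale(blk), 95)
  # hand-enumerated 2-row case: sup norms (3, 2); type-1 95th pct = 3
  expect_equal(select_scale(rbind(c(1, -3), c(2, 2))), 3)
  # constant single column
  expect_equal(select_scale(matrix(7, 10, 1)), 7)
  expect_error(select_scale(matrix(0, 10, 1)), "zero")
  expect_error(select_scale(matrix(1, 1, 1)), "2 rows")
})

test_that("knot count follows the floored sample-size rule with floor 5", {
  expect_identical(knot_count(2192), 5)
  expect_identical(knot_count(10), 5)
  expect_identical(knot_count(1e9), 43)
  expect_error(knot_count(1), "at least 2")
})

test_that("interior knots sit at equally spaced empirical quantiles", {
  u <- seq(0, 1, length.out = 101)
  kn <- place_knots(u, 3)
  expect_equal(kn$interior, c(0.25, 0.5, 0.75))
  expect_equal(kn$augmented[1:4], rep(0, 4))
  expect_equal(rev(kn$augmented)[1:4], rep(1, 4))
  # invariance under re-ordering: depends only on the empirical distribution
  set.seed(4)
  expect_equal(place_knots(sample(u), 3)$interior, kn$interior)
  # Beta(2,5) sample: knots near the closed-form quantiles
  set.seed(11)
  ub <- rbeta(10000, 2, 5)
  expect_lt(max(abs(place_knots(ub, 4)$interior - qbeta((1:4) / 5, 2, 5))),
            0.01)
})

test_that("degenerate knot placement collapses duplicates with a warning", {
  u <- rep(c(0.2, 0.8), each = 50)
  expect_warning(kn <- place_knots(u, 3), "collapsed")
  expect_true(all(diff(kn$interior) > 0))
})

test_that("B-spline design is a non-negative partition of unity", {
  set.seed(7)
  u <- c(0, 1, runif(200))
  kn <- place_knots(runif(500), 5)
  B <- bspline_design(u, kn)
  expect_equal(ncol(B), length(kn$interior) + 4)
  expect_true(all(B >= 0))
  expect_lt(max(abs(rowSums(B) - 1)), 1e-12)
  # boundary support: at u = 0 only the first basis function is active
  expect_equal(B[1, ], c(1, rep(0, ncol(B) - 1)))
  expect_error(bspline_design(c(-0.1, 0.5), kn), "0, 1")
})

test_that("B-spline design matches a direct Cox-de Boor recursion", {
  set.seed(9)
  kn <- place_knots(runif(300), 6)
  u <- c(0, 1, runif(50))
  B <- bspline_design(u, kn)
  O <- t(vapply(u, oracle_bspline_row, numeric(ncol(B)),
                knots = kn$augmented, ord = 4))
  expect_lt(max(abs(B - O)), 1e-12)
})
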