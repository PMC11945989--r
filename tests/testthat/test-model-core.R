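test_that("week design zeroes the default day and is balanced over weeks", {
  dates <- as.Date("2004-05-03") + 0:13          # two full weeks
  W <- build_week_design(dates)
  fridays <- weekdays(dates) == weekdays(as.Date("2004-05-07"))
  expect_true(all(W[fridays, ] == 0))
  expect_true(all(rowSums(W[!fridays, ]) == 1))
  expect_equal(unname(colSums(W)), rep(2, 6))
  # configurable default day
  W2 <- build_week_design(dates, default_day = "Monday")
  mondays <- as.POSIXlt(dates)$wday == 1
  expect_true(all(W2[mondays, ] == 0))
  expect_error(build_week_design(dates, "Funday"), "unknown")
})

test_that("growth curve is zero pre-window and follows the logistic after", {
  xi <- c(-0.588, 0.010, 0.747, 203.36)
  g <- growth_curve(xi, "2003-03-08", "2003-06-23")
  expect_equal(growth_curve_value(as.Date("2003-03-08"), g), 0)
  expect_equal(growth_curve_value(as.Date("2001-01-01"), g), 0)
  # midpoint and asymptote arithmetic
  expect_equal(growth_curve_shift(xi[4], xi), xi[1] + xi[3] / 2)
  expect_equal(growth_curve_shift(1e9, xi), xi[1] + xi[3], tolerance = 1e-12)
  expect_equal(growth_curve_value(as.Date("2003-06-23") + round(xi[4]), g),
               growth_curve_shift(round(xi[4]), xi))
  expect_error(growth_curve_value(as.Date("2003-05-01"), g), "inside")
})

test_that("lagged blocks drop rows with incomplete or contaminated history", {
  ds <- tiny_dataset(n = 10)
  lb <- build_lagged_blocks(ds, 3)
  expect_equal(lb$n_used, 7)
  expect_equal(unname(lb$blocks[[1]][1, ]),
               unname(ds$covariates[4:1, 1]))
  # L = 0 block equals the covariate column
  lb0 <- build_lagged_blocks(ds, 0)
  expect_equal(drop(lb0$blocks[[1]]), ds$covariates[, 1])
  # a constant covariate gives a constant index for any feasible weights
  dsc <- casim_dataset(ds$dates, ds$outcome,
                       matrix(5, 10, 1, dimnames = list(NULL, "c")))
  lbc <- build_lagged_blocks(dsc, 2)
  th <- index_weights(c(0.5, 0.3, 0.2))
  expect_equal(drop(lbc$blocks[[1]] %*% as.numeric(th)), rep(5, lbc$n_used))
  expect_error(build_lagged_blocks(ds, 20), "history")
})

test_that("lag windows never straddle the excluded intervention window", {
  n <- 40
  dates <- as.Date("2003-01-01") + 0:(n - 1)
  iv <- dates[c(15, 25)]
  ds <- casim_dataset(dates, rep(100, n),
                      matrix(runif(n, 1, 2), n, 1,
                             dimnames = list(NULL, "x")), intervention = iv)
  lb <- build_lagged_blocks(ds, 3)
  # kept rows: before the window with full history, or far enough after it
  # (days 16..24 are excluded; the first post row whose 3-day window is
  # clean is day 28)
  expect_equal(lb$rows, c(4:15, 28:40))
  expect_false(any(ds$excluded[lb$rows]))
})

test_that("parametric fit recovers constant, weekly and growth parameters", {
  n <- 600
  dates <- as.Date("2002-06-01") + 0:(n - 1)
  iv <- dates[c(200, 280)]
  W <- build_week_design(dates)
  alpha <- c(0.1, 0.05, 0.2, 0.15, 0.12, 0.18)
  xi <- c(-0.5, 0.02, 0.6, 120)
  post <- dates >= iv[2]
  tau <- as.numeric(dates - iv[2])
  keep <- dates <= iv[1] | post
  lam <- numeric(n); lam[post] <- growth_curve_shift(tau[post], xi)
  y <- (4.5 + drop(W %*% alpha) + lam)[keep]
  pf <- fit_parametric_part(y, W[keep, ], post[keep], tau[keep])
  expect_lt(abs(pf$mu - 4.5), 1e-4)
  expect_lt(max(abs(pf$alpha - alpha)), 1e-4)
  expect_lt(max(abs(pf$xi - xi) / abs(xi)), 0.01)
  expect_true(pf$growth_active)
})

test_that("parametric fit degenerates gracefully without post-window rows", {
  n <- 140
  dates <- as.Date("2002-06-01") + 0:(n - 1)
  W <- build_week_design(dates)
  set.seed(51)
  y <- 4 + drop(W %*% rep(0.1, 6)) + rnorm(n, sd = 0.01)
  pf <- fit_parametric_part(y, W, post = NULL, tau = NULL)
  ref <- lm(y ~ W)
  expect_equal(pf$mu, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(unname(pf$alpha), unname(coef(ref)[-1]), tolerance = 1e-10)
  expect_false(pf$growth_active)
  # constant response: mu is the constant, everything else zero
  pc <- fit_parametric_part(rep(3.3, n), W, post = NULL, tau = NULL)
  expect_equal(pc$mu, 3.3, tolerance = 1e-10)
  expect_equal(unname(pc$alpha), rep(0, 6), tolerance = 1e-10)
})

test_that("degenerate one-covariate model collapses to a spline regression", {
  sim <- quick_sim(n = 300, p = 1, lags = 0, noise_sd = 0.02, seed = 6,
                   pollutant_like = TRUE,
                   alpha = rep(0, 6))
  fit <- casim_fit(sim$dataset, 0)
  lb <- build_lagged_blocks(sim$dataset, 0)
  a <- select_scale(lb$blocks[[1]])
  tr <- index_transform(0, a)
  u <- rescaled_beta_cdf(drop(lb$blocks[[1]]), tr)
  direct <- fit_monotone_spline(lb$y, u, place_knots(u, knot_count(lb$n_used)))
  # same spline space; the backfit adds weekly dummies that are pure noise
  # here, so its overall fit can only be at least as good
  expect_lte(sum(fit$residuals^2), direct$rss + 1e-6)
})

test_that("backfitting satisfies its exact identities and descent", {
  sim <- quick_sim(seed = 8)
  fit <- casim_fit(sim$dataset, c(2, 1))
  # fitted + residuals = observed log outcome on used rows
  expect_equal(fit$fitted + fit$residuals,
               sim$dataset$log_outcome[fit$rows], tolerance = 1e-12)
  expect_equal(fit$mse, mean(fit$residuals^2), tolerance = 1e-14)
  expect_true(all(diff(fit$rss_trace) <= 1e-8))
  # constraints hold for every block
  for (b in fit$blocks) {
    th <- as.numeric(b$weights)
    expect_equal(sum(th), 1, tolerance = 1e-10)
    expect_true(all(diff(th) <= 1e-10) && all(th >= 0))
  }
  # weekly effect is exactly zero on the default day by construction
  W <- build_week_design(fit$dates, "Friday")
  fri <- rowSums(W) == 0
  expect_true(any(fri))
  pr <- predict(fit)
  expect_equal(pr$log_fitted, fit$fitted, tolerance = 1e-10)
})

test_that("prediction reconstructs the outcome exactly and exponentiates", {
  sim <- quick_sim(seed = 9)
  fit <- casim_fit(sim$dataset, c(2, 1))
  pr <- predict(fit)
  expect_equal(pr$log_fitted + pr$log_residual,
               log(pr$observed), tolerance = 1e-12)
  expect_equal(pr$fitted, exp(pr$log_fitted), tolerance = 1e-12)
  expect_equal(pr$residual, pr$observed - pr$fitted, tolerance = 1e-10)
  # hold-out RMSE matches an independent recomputation
  rmse <- sqrt(mean(pr$log_residual^2))
  expect_equal(rmse, sqrt(fit$mse), tolerance = 1e-12)
})

test_that("zero counts are rejected at load time unless offset is requested", {
  dates <- as.Date("2002-01-01") + 0:9
  X <- matrix(1:10, 10, 1, dimnames = list(NULL, "x"))
  expect_error(casim_dataset(dates, c(3, 0, rep(5, 8)), X), "log transform")
  ds <- casim_dataset(dates, c(3, 0, rep(5, 8)), X, zero_offset = TRUE)
  expect_equal(ds$outcome[2], 0.5)
})
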