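# Small programmatic fixtures shared across tests.

# a tiny gap-free dataset with hand-set covariates
tiny_dataset <- function(n = 60, seed = 1, intervention = NULL, p = 1) {
  set.seed(seed)
  dates <- as.Date("2001-03-01") + 0:(n - 1)
  X <- matrix(abs(stats::rnorm(n * p, 50, 10)), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  casim_dataset(dates, outcome = round(exp(4 + 0.002 * X[, 1])),
                covariates = X, intervention = intervention)
}

# a quick small synthetic study without intervention window
quick_sim <- function(n = 400, p = 2, lags = c(2, 1), noise_sd = 0.05,
                      seed = 1, pollutant_like = c(TRUE, FALSE), ...) {
  truth <- casim_truth(n = n, p = p, lags = lags,
                       pollutant_like = pollutant_like, window = NULL,
                       noise_sd = noise_sd, seed = seed, ...)
  simulate_casim(truth)
}

# stationary AR(1) lag block for single-index tests
ar1_block <- function(n, L, ar = 0.7, mean = 50, sd = 10, seed = 1) {
  set.seed(seed)
  x <- as.numeric(stats::arima.sim(list(ar = ar), n + L)) * sd /
    sqrt(1 / (1 - ar^2)) + mean
  vapply(0:L, function(tau) x[(L + 1 - tau):(L + n - tau)], numeric(n))
}
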