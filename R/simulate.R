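#' Ground truth for the synthetic-data generator
#'
#' Collects every generative parameter of a synthetic study: series length,
#' per-covariate lag lengths and ordered-simplex weights, effect-curve
#' families (monotone-saturating for pollutant-like covariates, U-shaped
#' for weather-like ones), the constant, weekly effects, growth-curve
#' parameters and intervention window, per-covariate AR(1) models for the
#' exposure series, and the log-scale noise SD.
#'
#' Defaults emulate a multi-year daily air-pollution/health study: three
#' covariates (two pollutant-like at PM10/ozone-like scales, one
#' humidity-like), geometric-decay lag weights, weekly effects of magnitude
#' 0.06--0.20, growth-curve parameters \eqn{\xi \approx (-0.6, 0.01, 0.75,
#' 200)} (an abrupt post-intervention drop relaxing back over roughly 200
#' days), an excluded 107-day window, and residual SD 0.15 on the log scale.
#'
#' @param n number of days.
#' @param p number of covariates.
#' @param lags true lag lengths (length p).
#' @param pollutant_like logical length p: monotone-saturating effect (TRUE)
#'   or U-shaped (FALSE).
#' @param theta optional list of weight vectors; default geometric decay
#'   with ratio 0.6, renormalised (always on the ordered simplex).
#' @param mu,alpha,xi constant, weekly 6-vector, growth-curve 4-vector.
#' @param window \code{"auto"} (a 107-day window starting at day
#'   \code{floor(0.4 n)} when \code{n >= 1000}, none otherwise), NULL for no
#'   window, or explicit length-2 day indices.
#' @param cov_model optional list per covariate: \code{mean}, \code{sd},
#'   \code{ar} (AR(1) coefficient in (-1,1)), and optional \code{bounds}.
#'   Unbounded series are lognormal-marginal transforms of a stationary
#'   Gaussian AR(1) (hence positive, right-skewed, like pollutant
#'   concentrations); with \code{bounds = c(lo, hi)} the marginal is a
#'   probit transform into \code{(lo, hi)} (moment-matched by the delta
#'   method), used by default for the weather-like covariate because
#'   relative humidity is physically confined to an interval.
#' @param g_specs optional list per covariate describing the effect curve:
#'   \code{list(type = "saturating", amp, half)} gives
#'   \eqn{g(v) = amp \cdot v / (v + half)};
#'   \code{list(type = "ushape", amp, center, scale)} gives
#'   \eqn{g(v) = amp ((v - center)/scale)^2}.
#' @param noise_sd log-scale residual SD.
#' @param seed integer seed.
#' @param start_date first calendar date.
#' @return object of class \code{"casim_truth"}.
#' @export
casim_truth <- function(n = 1500L, p = 3L, lags = c(6L, 4L, 3L),
                        pollutant_like = c(TRUE, TRUE, FALSE), theta = NULL,
                        mu = 4.6,
                        alpha = c(0.08, 0.06, 0.20, 0.15, 0.17, 0.19),
                        xi = c(-0.6, 0.01, 0.75, 200),
                        window = "auto", cov_model = NULL, g_specs = NULL,
                        noise_sd = 0.15, seed = 1L,
                        start_date = "2000-01-01") {
  lags <- as.integer(rep_len(lags, p))
  pollutant_like <- rep_len(pollutant_like, p)
  if (is.null(theta)) {
    theta <- lapply(lags, function(L) {
      w <- 0.6^(0:L); w / sum(w)
    })
  }
  theta <- lapply(theta, function(th) as.numeric(index_weights(th)))
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  base_models <- list(list(mean = 50, sd = 25, ar = 0.7),
                      list(mean = 35, sd = 15, ar = 0.6),
                      list(mean = 78, sd = 10, ar = 0.8,
                           bounds = c(40, 100)))
  if (is.null(cov_model))
    cov_model <- lapply(seq_len(p), function(j)
      base_models[[(j - 1L) %% 3L + 1L]])
  for (cm in cov_model)
    if (abs(cm$ar) >= 1) stop("AR coefficients must lie in (-1, 1)")
  if (is.null(g_specs)) {
    g_specs <- lapply(seq_len(p), function(j) {
      if (pollutant_like[j])
        list(type = "saturating", amp = 0.5, half = cov_model[[j]]$mean)
      else
        list(type = "ushape", amp = 0.25, center = 60, scale = 20)
    })
  }
  if (identical(window, "auto"))
    window <- if (n >= 1000L) c(floor(0.4 * n), floor(0.4 * n) + 107L) else NULL
  if (!is.null(window) && (window[2] <= window[1] || window[2] > n))
    stop("invalid intervention window")
  structure(list(n = as.integer(n), p = as.integer(p), lags = lags,
                 pollutant_like = pollutant_like, theta = theta,
                 mu = mu, alpha = as.numeric(alpha), xi = as.numeric(xi),
                 window = window, cov_model = cov_model, g_specs = g_specs,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 start_date = as.Date(start_date)),
            class = "casim_truth")
}

eval_g_spec <- function(spec, v) {
  switch(spec$type,
         saturating = spec$amp * v / (v + spec$half),
         ushape = spec$amp * ((v - spec$center) / spec$scale)^2,
         stop("unknown effect-curve type: ", spec$type))
}

#' Generate the synthetic exposure series
#'
#' Draws \code{p} positive, stationary, autocorrelated daily series: each is
#' a lognormal-marginal transform (moment-matched to the requested mean and
#' SD) of a standardised Gaussian AR(1) with the requested lag-1
#' autocorrelation.  Deterministic given \code{truth$seed}.
#'
#' @param truth a [casim_truth()].
#' @return list with \code{covariates} (n x p matrix) and \code{dates}.
#' @export
generate_covariates <- function(truth) {
  stopifnot(inherits(truth, "casim_truth"))
  set.seed(truth$seed)
  n <- truth$n
  X <- matrix(0, n, truth$p,
              dimnames = list(NULL, paste0(ifelse(truth$pollutant_like,
                                                  "poll", "weather"),
                                           seq_len(truth$p))))
  for (j in seq_len(truth$p)) {
    cm <- truth$cov_model[[j]]
    z <- numeric(n)
    z[1] <- stats::rnorm(1)
    innov <- stats::rnorm(n - 1L, sd = sqrt(1 - cm$ar^2))
    for (t in 2:n) z[t] <- cm$ar * z[t - 1L] + innov[t - 1L]
    if (cm$sd == 0) {
      X[, j] <- cm$mean
    } else if (!is.null(cm$bounds)) {
      lo <- cm$bounds[1]; hi <- cm$bounds[2]
      muz <- stats::qnorm((cm$mean - lo) / (hi - lo))
      sigz <- cm$sd / ((hi - lo) * stats::dnorm(muz))
      X[, j] <- lo + (hi - lo) * stats::pnorm(muz + sigz * z)
    } else {
      s2 <- log(1 + (cm$sd / cm$mean)^2)
      X[, j] <- exp(log(cm$mean) - s2 / 2 + sqrt(s2) * z)
    }
  }
  list(covariates = X, dates = truth$start_date + 0:(n - 1L))
}

#' Assemble the synthetic outcome series from its components
#'
#' Builds the log-scale signal \eqn{\mu + \lambda(t) + S(t) + \sum_j
#' g_j(\theta_j^T X_{j,t}) + \epsilon_t}, with each \eqn{g_j} centred over
#' the rows a model fit would use (full lag history, outside the excluded
#' window) exactly as the estimator centres its effect terms.  Days inside
#' the intervention window are generated (the growth term is linearly
#' interpolated across the window so counts exist) but flagged excluded.
#' The outcome is the rounded exponential of the log signal; rounding can
#' be disabled for exact-recovery experiments.
#'
#' @param covariates output of [generate_covariates()].
#' @param truth a [casim_truth()].
#' @param round_counts round \eqn{e^{y_t}} to whole counts (default TRUE).
#' @return list with \code{dataset} (a [casim_dataset()]), \code{components}
#'   (data frame of every log-scale component per day),
#'   \code{g_centered} (list of centred truth effect functions), and
#'   \code{truth}.
#' @export
generate_response <- function(covariates, truth, round_counts = TRUE) {
  stopifnot(inherits(truth, "casim_truth"))
  X <- covariates$covariates
  dates <- covariates$dates
  n <- truth$n
  if (nrow(X) < max(truth$lags) + 1L) stop("series shorter than the max lag")
  set.seed(truth$seed + 1L)

  weekly <- drop(build_week_design(dates, "Friday") %*% truth$alpha)

  lambda <- numeric(n)
  excluded <- rep(FALSE, n)
  intervention <- NULL
  if (!is.null(truth$window)) {
    i1 <- truth$window[1]; i2 <- truth$window[2]
    intervention <- dates[c(i1, i2)]
    post <- seq_len(n) >= i2
    lambda[post] <- growth_curve_shift(as.numeric(dates[post] - dates[i2]),
                                       truth$xi)
    inside <- seq_len(n) > i1 & seq_len(n) < i2
    # interpolate across the window so generated counts exist there
    lam_end <- growth_curve_shift(0, truth$xi)
    lambda[inside] <- lam_end * (seq_len(n)[inside] - i1) / (i2 - i1)
    excluded <- inside
  }

  maxlag <- max(truth$lags)
  usable <- seq_len(n) > maxlag & !excluded
  if (!is.null(truth$window))
    usable <- usable & !vapply(seq_len(n), function(t)
      any(excluded[max(1L, t - maxlag):t]), logical(1))

  graw <- matrix(0, n, truth$p)
  gcent <- matrix(0, n, truth$p)
  offsets <- numeric(truth$p)
  vindex <- matrix(0, n, truth$p)
  for (j in seq_len(truth$p)) {
    x <- X[, j]
    xpad <- c(rep(x[1], truth$lags[j]), x)
    th <- truth$theta[[j]]
    v <- drop(stats::filter(xpad, th, method = "convolution",
                            sides = 1))[(truth$lags[j] + 1L):(truth$lags[j] + n)]
    vindex[, j] <- v
    graw[, j] <- eval_g_spec(truth$g_specs[[j]], v)
    offsets[j] <- mean(graw[usable, j])
    gcent[, j] <- graw[, j] - offsets[j]
  }

  signal <- truth$mu + lambda + weekly + rowSums(gcent)
  if (any(abs(signal) > 500)) stop("log signal too large: exp would overflow")
  noise <- stats::rnorm(n, 0, truth$noise_sd)
  y <- signal + noise
  outcome <- if (round_counts) round(exp(y)) else exp(y)

  dataset <- casim_dataset(dates, outcome, X,
                           pollutant_like = truth$pollutant_like,
                           intervention = intervention,
                           default_day = "Friday")
  g_centered <- lapply(seq_len(truth$p), function(j) {
    spec <- truth$g_specs[[j]]; off <- offsets[j]
    function(v) eval_g_spec(spec, v) - off
  })
  comps <- data.frame(date = dates, mu = truth$mu, lambda = lambda,
                      weekly = weekly, noise = noise, log_signal = signal,
                      log_outcome = y)
  for (j in seq_len(truth$p)) {
    comps[[paste0("g", j)]] <- gcent[, j]
    comps[[paste0("index", j)]] <- vindex[, j]
  }
  list(dataset = dataset, components = comps, g_centered = g_centered,
       g_offsets = offsets, truth = truth)
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper: [generate_covariates()] then [generate_response()].
#'
#' @inheritParams generate_response
#' @param truth a [casim_truth()].
#' @return see [generate_response()]; class \code{"casim_sim"}.
#' @export
simulate_casim <- function(truth = casim_truth(), round_counts = TRUE) {
  cov <- generate_covariates(truth)
  out <- generate_response(cov, truth, round_counts = round_counts)
  class(out) <- "casim_sim"
  out
}
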