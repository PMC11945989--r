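#' Residual bootstrap of a fitted model
#'
#' Quantifies estimator variability by the residual bootstrap on the log
#' scale: for each replicate, residuals of the point fit are resampled
#' i.i.d. with replacement (or in moving blocks, for autocorrelated
#' residuals, with \code{method = "block"}), added to the fitted log series,
#' and the whole model is re-fitted with the lags held fixed at the point
#' estimate.  Replicate fits are warm-started from the point fit.  Draws of
#' every parameter, every lag-weight vector, and every effect curve on a
#' fixed index grid are stored.
#'
#' @param dataset the training [casim_dataset()].
#' @param fit the converged point \code{"casim_fit"}.
#' @param B number of bootstrap replicates (default 500).
#' @param seed integer seed; draws are deterministic given the seed.
#' @param method \code{"iid"} (default) or \code{"block"} (moving-block with
#'   length \code{block_length}, default \code{ceiling(n^(1/3))}).
#' @param block_length block length for \code{method = "block"}.
#' @param grid_size points per effect-curve grid (default 100).
#' @param control a [casim_control()]; replicate fits use lightened limits.
#' @return object of class \code{"casim_boot"}: \code{params} (B x 11 matrix
#'   of mu, alpha, xi draws), \code{theta} (per-covariate draw matrices),
#'   \code{curves} (per-covariate list with \code{grid} and B x grid value
#'   matrix), \code{dropped} (non-converged replicates), \code{seed},
#'   \code{B}, and the point \code{fit}.
#' @export
bootstrap_casim <- function(dataset, fit, B = 500L, seed = 1L,
                            method = c("iid", "block"), block_length = NULL,
                            grid_size = 100L, control = casim_control()) {
  stopifnot(inherits(fit, "casim_fit"))
  method <- match.arg(method)
  if (B < 2L) stop("'B' must be at least 2")
  n <- fit$n_used
  res <- fit$residuals
  ctl <- fast_control(control)
  p <- length(fit$blocks)

  lb <- build_lagged_blocks(dataset, fit$lags, fit$trim_to)
  grids <- lapply(seq_len(p), function(j) {
    v <- drop(lb$blocks[[j]] %*% as.numeric(fit$blocks[[j]]$weights))
    seq(min(v), max(v), length.out = grid_size)
  })
  names(grids) <- names(fit$blocks)

  if (is.null(block_length)) block_length <- max(1L, ceiling(n^(1 / 3)))
  draw_res <- function() {
    if (method == "iid") return(sample(res, n, replace = TRUE))
    starts <- sample.int(n - block_length + 1L,
                         ceiling(n / block_length), replace = TRUE)
    idx <- as.vector(outer(0:(block_length - 1L), starts, `+`))[seq_len(n)]
    res[idx]
  }

  params <- matrix(NA_real_, B, 11,
                   dimnames = list(NULL, c("mu", names(fit$weekly$alpha),
                                           paste0("xi", 1:4))))
  theta <- lapply(fit$lags, function(L) matrix(NA_real_, B, L + 1L))
  names(theta) <- names(fit$blocks)
  curves <- lapply(grids, function(g) matrix(NA_real_, B, length(g)))
  dropped <- 0L

  set.seed(seed)
  for (b in seq_len(B)) {
    ystar <- fit$fitted + draw_res()
    ds <- dataset
    ds$outcome[fit$rows] <- exp(ystar)
    ds$log_outcome[fit$rows] <- ystar
    rf <- tryCatch(
      suppressWarnings(casim_fit(ds, fit$lags, control = ctl, init = fit,
                                 trim_to = fit$trim_to)),
      error = function(e) NULL)
    if (is.null(rf) || !rf$converged) { dropped <- dropped + 1L; next }
    params[b, ] <- c(rf$mu, rf$weekly$alpha, rf$growth$xi)
    for (j in seq_len(p)) {
      theta[[j]][b, ] <- as.numeric(rf$blocks[[j]]$weights)
      curves[[j]][b, ] <- eval_effect(rf$blocks[[j]]$effect, grids[[j]])
    }
  }
  if (dropped > 0.2 * B)
    stop("more than 20% of bootstrap replicates failed to converge")
  keep <- !is.na(params[, 1])
  structure(list(params = params[keep, , drop = FALSE],
                 theta = lapply(theta, function(m) m[keep, , drop = FALSE]),
                 curves = Map(function(g, m) list(grid = g,
                                                  draws = m[keep, , drop = FALSE]),
                              grids, curves),
                 dropped = dropped, B = B, seed = seed, method = method,
                 fit = fit),
            class = "casim_boot")
}

#' Percentile confidence bounds from bootstrap draws
#'
#' Applies the percentile method: lower and upper bounds are the
#' \eqn{(1-\mathrm{level})/2} and \eqn{1-(1-\mathrm{level})/2} nearest-rank
#' empirical quantiles of the draws, reported together with the bootstrap
#' standard deviation.  Effect-curve bands are pointwise on the stored
#' grid.  The percentile method does not force the point estimate inside
#' the interval; such violations are flagged, not corrected.
#'
#' @param boot a [bootstrap_casim()] result.
#' @param level nominal coverage (default 0.95); requires
#'   \code{B >= ceiling(2 / (1 - level))}.
#' @return list with \code{parameters} (data frame: estimate, sd, lower,
#'   upper, outside flag), \code{theta} (per-covariate data frames per lag)
#'   and \code{curves} (per-covariate data frames: grid, estimate, sd,
#'   lower, upper).
#' @export
confidence_bounds <- function(boot, level = 0.95) {
  stopifnot(inherits(boot, "casim_boot"))
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  if (nrow(boot$params) < ceiling(2 / (1 - level) - 1e-8))
    stop("too few bootstrap draws for the requested level")
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qb <- function(x) casim_quantile(x, pr)
  fit <- boot$fit
  est <- c(fit$mu, fit$weekly$alpha, fit$growth$xi)
  qs <- apply(boot$params, 2L, qb)
  parameters <- data.frame(
    parameter = colnames(boot$params), estimate = unname(est),
    sd = unname(apply(boot$params, 2L, stats::sd)),
    lower = qs[1, ], upper = qs[2, ], row.names = NULL)
  eps <- 1e-8 * pmax(1, abs(parameters$estimate))
  parameters$outside <- parameters$estimate < parameters$lower - eps |
    parameters$estimate > parameters$upper + eps
  if (any(parameters$outside))
    warning("point estimate outside its percentile interval for: ",
            paste(parameters$parameter[parameters$outside], collapse = ", "))

  theta <- Map(function(nm, m) {
    q <- apply(m, 2L, qb)
    data.frame(lag = seq_len(ncol(m)) - 1L,
               estimate = as.numeric(fit$blocks[[nm]]$weights),
               sd = apply(m, 2L, stats::sd), lower = q[1, ], upper = q[2, ])
  }, names(boot$theta), boot$theta)

  curves <- Map(function(nm, cv) {
    q <- apply(cv$draws, 2L, qb)
    data.frame(index = cv$grid,
               estimate = eval_effect(fit$blocks[[nm]]$effect, cv$grid),
               sd = apply(cv$draws, 2L, stats::sd),
               lower = q[1, ], upper = q[2, ])
  }, names(boot$curves), boot$curves)

  list(parameters = parameters, theta = theta, curves = curves,
       level = level)
}
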