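#' Fit the constrained additive single-index model by backfitting
#'
#' Estimates the full model
#' \deqn{\log Y_t = \mu + \lambda(t) + S(t) + \sum_j g_j(\theta_j^T X_{j,t})
#'   + \epsilon_t}
#' for given per-covariate lag lengths.  Estimation is two-phase: an
#' initialisation pass (parametric least squares for \eqn{\mu}, the weekly
#' effect and the growth curve; then sequential single-index fits of each
#' covariate block on the running partial residual), followed by
#' backfitting cycles that re-fit the parametric part on the outcome minus
#' all cumulative-effect terms, recompute residuals, and re-estimate each
#' block on its partial residual.  Each fitted \eqn{g_j} is centred to mean
#' zero over the used sample, the offset being absorbed into \eqn{\mu}, so
#' the decomposition is identified.  All refits are warm-started, which
#' makes the overall residual sum of squares non-increasing across cycles;
#' a block update that fails to improve is rolled back.
#'
#' Convergence is declared when the relative RSS change over a full cycle
#' drops below \code{control$tol}.
#'
#' @param dataset a [casim_dataset()].
#' @param lags integer vector of lag lengths, one per covariate.
#' @param control a [casim_control()].
#' @param init optional \code{"casim_fit"} used as a warm start (parametric
#'   part and lag weights; lags must match).
#' @param trim_to optional common trimming bound passed to
#'   [build_lagged_blocks()] (used by lag selection to keep \code{n} fixed).
#' @param update \code{"partial"} (default): each block is re-fitted on the
#'   residual net of the current estimates of all other blocks (classic
#'   backfitting, guarantees RSS descent).  \code{"sequential"}: each sweep
#'   subtracts only the blocks already updated in that sweep, re-deriving
#'   the whole decomposition from the parametric residual each time; descent
#'   is not guaranteed in this variant.
#' @return object of class \code{"casim_fit"}: parameters, per-covariate
#'   weights and effect functions, residuals, MSE, AIC, RSS trace and
#'   convergence information.
#' @export
casim_fit <- function(dataset, lags, control = casim_control(), init = NULL,
                      trim_to = NULL, update = c("partial", "sequential")) {
  stopifnot(inherits(dataset, "casim_dataset"))
  update <- match.arg(update)
  lb <- build_lagged_blocks(dataset, lags, trim_to)
  y <- lb$y
  n <- lb$n_used
  p <- length(lb$blocks)
  mono <- dataset$pollutant_like
  W <- build_week_design(lb$dates, dataset$default_day)
  if (!is.null(dataset$intervention)) {
    post <- lb$dates >= dataset$intervention[2]
    tau <- as.numeric(lb$dates - dataset$intervention[2])
  } else {
    post <- NULL; tau <- NULL
  }

  init_theta <- vector("list", p)
  prev_growth <- NULL
  if (!is.null(init)) {
    stopifnot(inherits(init, "casim_fit"))
    if (!identical(as.integer(init$lags), as.integer(lags)))
      stop("warm-start fit has different lags")
    init_theta <- lapply(init$blocks, function(b) as.numeric(b$weights))
    if (init$growth_active) prev_growth <- init$growth
  }

  comp <- matrix(0, n, p)
  # -- initialisation: parametric part, then sequential block fits --------
  par <- fit_parametric_part(y, W, post, tau, control, prev_growth)
  e <- y - par$fitted
  blocks_fit <- vector("list", p)
  for (j in seq_len(p)) {
    Z <- e - if (j > 1L) rowSums(comp[, seq_len(j - 1L), drop = FALSE]) else 0
    sf <- fit_single_index(Z, lb$blocks[[j]], mono[j], init = init_theta[[j]],
                           control = control)
    off <- mean(sf$fitted)
    sf$effect$centering_offset <- off
    comp[, j] <- sf$fitted - off
    par$mu <- par$mu + off
    par$fitted <- par$fitted + off
    e <- e - off
    blocks_fit[[j]] <- sf
  }
  rss <- sum((e - rowSums(comp))^2)
  rss_trace <- rss

  converged <- FALSE
  cycles <- 0L
  for (m in seq_len(control$max_cycles)) {
    cycles <- m
    rss_enter <- rss
    # Step 4: parametric part on outcome net of cumulative effects
    par_new <- fit_parametric_part(y - rowSums(comp), W, post, tau, control,
                                   prev_growth = if (par$growth_active)
                                     growth_curve(par$xi,
                                                  dataset$intervention[1],
                                                  dataset$intervention[2]))
    if (par_new$rss <= rss + control$tol) {
      par <- par_new
      rss <- par_new$rss
    }
    # Step 5: residuals net of the parametric part
    e <- y - par$fitted
    # Step 6: re-estimate every block on its partial residual
    for (j in seq_len(p)) {
      Z <- if (update == "partial") {
        e - rowSums(comp[, -j, drop = FALSE])
      } else {
        e - if (j > 1L) rowSums(comp[, seq_len(j - 1L), drop = FALSE]) else 0
      }
      cur_rss <- sum((Z - comp[, j])^2)
      sf <- fit_single_index(Z, lb$blocks[[j]], mono[j],
                             init = as.numeric(blocks_fit[[j]]$weights),
                             control = control)
      if (update == "sequential" || sf$rss <= cur_rss + control$tol) {
        off <- mean(sf$fitted)
        sf$effect$centering_offset <- off
        comp[, j] <- sf$fitted - off
        par$mu <- par$mu + off
        par$fitted <- par$fitted + off
        e <- e - off
        blocks_fit[[j]] <- sf
      }
    }
    rss <- sum((e - rowSums(comp))^2)
    rss_trace <- c(rss_trace, rss)
    if (abs(rss_enter - rss) <= control$tol * max(rss_enter, 1)) {
      converged <- TRUE
      break
    }
  }

  fitted_log <- par$fitted + rowSums(comp)
  residuals <- y - fitted_log
  mse <- mean(residuals^2)
  blocks <- lapply(seq_len(p), function(j)
    list(weights = blocks_fit[[j]]$weights, effect = blocks_fit[[j]]$effect))
  names(blocks) <- names(lb$blocks)

  fit <- structure(list(
    mu = par$mu,
    weekly = list(alpha = par$alpha, default_day = dataset$default_day),
    growth = growth_curve(par$xi, dataset$intervention[1],
                          dataset$intervention[2]),
    growth_active = par$growth_active,
    lags = as.integer(lags), blocks = blocks,
    fitted = fitted_log, residuals = residuals, mse = mse,
    rows = lb$rows, dates = lb$dates, n_used = n,
    converged = converged, iterations = cycles, rss_trace = rss_trace,
    pollutant_like = mono, trim_to = trim_to, dataset = dataset),
    class = "casim_fit")
  fit$aic <- compute_aic(fit)
  if (!converged)
    warning("backfitting did not converge in ", control$max_cycles, " cycles")
  fit
}

#' Akaike information criterion of a fitted model
#'
#' At fixed sample size the AIC \eqn{2k + n \log(SSR/n)} reduces (up to a
#' constant) to \eqn{\log(\mathrm{MSE}) + 2m/n}, where \eqn{m} counts the
#' free model parameters: the constant, the six weekly effects, the four
#' growth-curve parameters (when the model has an intervention window) and
#' the \eqn{L_j} free lag weights per covariate (one weight per block is
#' fixed by the sum-to-one constraint).  Spline coefficients are excluded:
#' their number does not vary across lag candidates, so they do not affect
#' AIC comparisons.
#'
#' @param fit a \code{"casim_fit"}.
#' @return the AIC value (natural log scale).
#' @export
compute_aic <- function(fit) {
  stopifnot(inherits(fit, "casim_fit"))
  if (!is.finite(fit$mse) || fit$mse <= 0) stop("MSE must be positive")
  m <- 1 + 6 + (if (fit$growth_active) 4 else 0) + sum(fit$lags)
  log(fit$mse) + 2 * m / fit$n_used
}

#' Fitted values and residuals on the log and original scales
#'
#' Recomputes the model's fitted series on any dataset with sufficient
#' covariate history for the fit's lags.  Original-scale fits are the
#' exponential of the log-scale fits; original-scale residuals are the
#' observed counts minus the exponentiated fit.
#'
#' @param object a \code{"casim_fit"}.
#' @param dataset a [casim_dataset()] (defaults to the training data).
#' @param ... unused.
#' @return data frame with date, observed count, log/original fitted values
#'   and residuals.
#' @export
predict.casim_fit <- function(object, dataset = object$dataset, ...) {
  lb <- build_lagged_blocks(dataset, object$lags)
  W <- build_week_design(lb$dates, object$weekly$default_day)
  lam <- if (object$growth_active) growth_curve_value(lb$dates, object$growth)
         else 0
  f <- object$mu + drop(W %*% object$weekly$alpha) + lam
  for (j in seq_along(object$blocks)) {
    b <- object$blocks[[j]]
    f <- f + eval_effect(b$effect,
                         drop(lb$blocks[[j]] %*% as.numeric(b$weights)))
  }
  data.frame(date = lb$dates,
             observed = dataset$outcome[lb$rows],
             log_fitted = f, fitted = exp(f),
             log_residual = lb$y - f,
             residual = dataset$outcome[lb$rows] - exp(f))
}

#' @export
print.casim_fit <- function(x, ...) {
  cat("Constrained additive single-index model fit\n")
  cat(sprintf("  n used: %d   cycles: %d   converged: %s\n",
              x$n_used, x$iterations, x$converged))
  cat(sprintf("  mu = %.4f   MSE = %.5g   AIC = %.4f\n", x$mu, x$mse, x$aic))
  cat("  weekly effects:\n")
  print(round(x$weekly$alpha, 4))
  if (x$growth_active)
    cat(sprintf("  growth curve xi = (%.3f, %.4f, %.3f, %.2f)\n",
                x$growth$xi[1], x$growth$xi[2], x$growth$xi[3], x$growth$xi[4]))
  cat("  lags:", paste(sprintf("%s=%d", names(x$blocks), x$lags),
                       collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.casim_fit <- function(object, ...) {
  theta <- lapply(object$blocks, function(b) as.numeric(b$weights))
  structure(list(fit = object, theta = theta,
                 rmse_log = sqrt(object$mse)), class = "summary.casim_fit")
}

#' @export
print.summary.casim_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  RMSE (log scale): %.4f\n", x$rmse_log))
  for (nm in names(x$theta))
    cat(sprintf("  theta[%s]: %s\n", nm,
                paste(sprintf("%.3f", x$theta[[nm]]), collapse = " ")))
  invisible(x)
}
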