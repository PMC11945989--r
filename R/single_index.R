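#' Control parameters for model fitting
#'
#' @param tol relative RSS change declaring convergence (single-index inner
#'   problem and backfitting cycles alike).
#' @param max_cycles maximum backfitting cycles.
#' @param si_outer maximum alternations between spline refit and weight
#'   update inside one single-index fit.
#' @param si_inner maximum gradient-projection steps on the weights per
#'   alternation.
#' @param armijo_max maximum step halvings in the backtracking line search.
#' @param xi2_grid,xi4_frac multi-start grids for the growth-curve rate and
#'   midpoint (the midpoint grid is expressed as fractions of the observed
#'   post-intervention span).
#' @param polish polish the growth-curve profile optimum with a local
#'   optimiser (default TRUE).
#' @return list of class \code{"casim_control"}.
#' @export
casim_control <- function(tol = 1e-6, max_cycles = 100L, si_outer = 25L,
                          si_inner = 50L, armijo_max = 30L,
                          xi2_grid = c(0.002, 0.005, 0.01, 0.02, 0.05, 0.1),
                          xi4_frac = c(0.1, 0.25, 0.4, 0.55, 0.7, 0.85),
                          polish = TRUE) {
  structure(list(tol = tol, max_cycles = as.integer(max_cycles),
                 si_outer = as.integer(si_outer),
                 si_inner = as.integer(si_inner),
                 armijo_max = as.integer(armijo_max),
                 xi2_grid = xi2_grid, xi4_frac = xi4_frac,
                 polish = isTRUE(polish)),
            class = "casim_control")
}

# lighter settings for the many throw-away fits of lag search and bootstrap
fast_control <- function(control = casim_control()) {
  control$tol <- max(control$tol, 1e-5)
  control$max_cycles <- min(control$max_cycles, 25L)
  control$si_outer <- min(control$si_outer, 10L)
  control$si_inner <- min(control$si_inner, 15L)
  control
}

#' Fit one constrained single-index block
#'
#' Estimates one covariate's cumulative-effect term
#' \eqn{g(\theta^T X_t)} from a partial-residual response: alternates
#' (i) given \eqn{\theta}, rebuild the index transform and quantile knots and
#' fit the (monotone or unconstrained) spline; (ii) given the spline,
#' gradient-projection steps on \eqn{\theta} — analytic gradient of the RSS
#' through the fixed spline, Armijo backtracking, Euclidean projection onto
#' the ordered unit simplex after each step.  Stops when the relative RSS
#' change falls below \code{control$tol}.  The returned RSS never exceeds the
#' starting RSS (descent is enforced; a knot refresh that would increase the
#' objective is rolled back).
#'
#' @param Z numeric partial-residual response.
#' @param lagged_block numeric matrix, n x (L+1), row t = \eqn{(X_t, X_{t-1},
#'   \dots, X_{t-L})}.
#' @param monotone_g logical: restrict the effect curve to be non-decreasing
#'   (pollutant-like covariates)?
#' @param init optional starting weights (defaults to equal weights, which
#'   are always feasible).
#' @param control a [casim_control()] list.
#' @return list with elements \code{weights} ([index_weights()]),
#'   \code{effect} (\code{"casim_effect"}), \code{rss}, \code{fitted},
#'   \code{iterations}, \code{converged}, and \code{step_failed} (TRUE when
#'   backtracking could not find a descent step before the RSS stabilised).
#' @export
fit_single_index <- function(Z, lagged_block, monotone_g = TRUE, init = NULL,
                             control = casim_control()) {
  X <- as.matrix(lagged_block)
  n <- nrow(X); q <- ncol(X)
  if (length(Z) != n) stop("'Z' and 'lagged_block' are misaligned")
  theta <- if (is.null(init)) rep(1 / q, q) else as.numeric(init)
  theta <- as.numeric(project_ordered_simplex(theta))
  a <- select_scale(X)
  tr <- index_transform(q - 1L, a)
  N <- knot_count(n)
  fitter <- if (monotone_g) fit_monotone_spline else fit_unconstrained_spline

  refit <- function(theta) {
    u <- rescaled_beta_cdf(drop(X %*% theta), tr)
    eff <- fitter(Z, u, place_knots(u, N), transform = tr)
    list(eff = eff, u = u)
  }

  cur <- refit(theta)
  rss <- cur$eff$rss
  step_failed <- FALSE
  converged <- FALSE
  it <- 0L

  if (q == 1L) {                      # simplex is the single point theta = 1
    converged <- TRUE
  } else {
    for (it in seq_len(control$si_outer)) {
      rss_enter <- rss
      # -- weight updates through the frozen spline ----------------------
      obj <- function(th) {
        u <- rescaled_beta_cdf(drop(X %*% th), tr)
        sum((Z - eval_effect(cur$eff, u, scale = "u", centered = FALSE))^2)
      }
      f0 <- rss
      for (k in seq_len(control$si_inner)) {
        v <- drop(X %*% theta)
        u <- rescaled_beta_cdf(v, tr)
        r <- Z - eval_effect(cur$eff, u, scale = "u", centered = FALSE)
        slope <- eval_effect(cur$eff, u, scale = "u", deriv = 1L) *
          rescaled_beta_pdf(v, tr)
        grad <- -2 * drop(crossprod(X, r * slope))
        if (!all(is.finite(grad))) stop("non-finite gradient in single-index fit")
        step <- 1
        improved <- FALSE
        for (h in seq_len(control$armijo_max)) {
          cand <- as.numeric(project_ordered_simplex(theta - step * grad))
          fc <- obj(cand)
          if (fc < f0 - 1e-4 * sum((cand - theta)^2) / step) {
            theta <- cand; f0 <- fc; improved <- TRUE
            break
          }
          step <- step / 2
        }
        if (!improved) break
      }
      rss <- f0
      # keep the frozen spline consistent with the updated weights
      u <- rescaled_beta_cdf(drop(X %*% theta), tr)
      cur$eff$fitted <- eval_effect(cur$eff, u, scale = "u", centered = FALSE)
      cur$eff$rss <- rss
      # -- refresh knots for the new index distribution and refit --------
      nxt <- refit(theta)
      if (nxt$eff$rss <= rss + control$tol) {
        cur <- nxt
        rss <- nxt$eff$rss
      } else {
        # knot refresh increased the objective: keep the frozen-spline fit
        step_failed <- TRUE
      }
      if (abs(rss_enter - rss) <= control$tol * max(rss_enter, 1)) {
        converged <- TRUE
        break
      }
    }
  }

  list(weights = index_weights(theta), effect = cur$eff, rss = rss,
       fitted = cur$eff$fitted, iterations = it, converged = converged,
       step_failed = step_failed)
}
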