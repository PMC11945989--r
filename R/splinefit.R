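#' @keywords internal
new_effect <- function(transform, knots, coef, monotone, fitted, rss,
                       centering_offset = 0) {
  structure(list(transform = transform, knots = knots,
                 coef = as.numeric(coef), monotone = isTRUE(monotone),
                 fitted = fitted, rss = rss,
                 centering_offset = centering_offset),
            class = "casim_effect")
}

#' Monotone B-spline regression
#'
#' Least-squares cubic B-spline fit of \code{Z} on transformed index values
#' \code{u}, restricted to non-decreasing spline coefficients — a sufficient
#' condition for a non-decreasing fitted curve.  The restriction is imposed
#' by reparametrising coefficient differences as non-negative and solving a
#' non-negativity-constrained least-squares problem (Lawson--Hanson NNLS);
#' the free level is profiled out through the partition of unity, so the
#' constant fit is always attainable and the constrained RSS never exceeds
#' the best constant's RSS.
#'
#' @param Z numeric response vector.
#' @param u numeric vector in \eqn{[0,1]}, same length as \code{Z}.
#' @param knots a [place_knots()] object.
#' @param transform optional [index_transform()] carried along for later
#'   evaluation on the covariate scale.
#' @return object of class \code{"casim_effect"} with non-decreasing
#'   \code{coef}, fitted values and RSS.
#' @export
fit_monotone_spline <- function(Z, u, knots, transform = NULL) {
  B <- bspline_design(u, knots)
  m <- ncol(B)
  if (length(Z) < m) stop("need at least as many observations as basis functions")
  A <- matrix(0, m, m); A[lower.tri(A, diag = TRUE)] <- 1
  G <- B %*% A                      # G[,1] == 1 by partition of unity
  G2 <- G[, -1L, drop = FALSE]
  Zc <- Z - mean(Z)
  G2c <- sweep(G2, 2L, colMeans(G2))
  delta <- pracma::lsqnonneg(G2c, Zc)$x
  c1 <- mean(Z - G2 %*% delta)
  beta <- cumsum(c(c1, delta))
  fitted <- drop(B %*% beta)
  new_effect(transform, knots, beta, TRUE, fitted, sum((Z - fitted)^2))
}

#' Unconstrained B-spline regression
#'
#' Ordinary least squares on the cubic B-spline design; used for covariates
#' whose effect curve is not shape-restricted (weather variables, whose
#' effect is typically U-shaped).  A rank-deficient design (possible when
#' clamping piles index values onto a boundary) falls back to a tiny ridge
#' (1e-8) on the normal equations with a warning.
#'
#' @inheritParams fit_monotone_spline
#' @return object of class \code{"casim_effect"}.
#' @export
fit_unconstrained_spline <- function(Z, u, knots, transform = NULL) {
  B <- bspline_design(u, knots)
  m <- ncol(B)
  if (length(Z) < m) stop("need at least as many observations as basis functions")
  fit <- stats::lm.fit(B, Z)
  if (fit$rank < m) {
    warning("rank-deficient spline design; using ridge fallback")
    beta <- solve(crossprod(B) + 1e-8 * diag(m), crossprod(B, Z))
  } else {
    beta <- fit$coefficients
  }
  beta <- as.numeric(beta)
  fitted <- drop(B %*% beta)
  new_effect(transform, knots, beta, FALSE, fitted, sum((Z - fitted)^2))
}

#' Evaluate a fitted effect function
#'
#' @param effect a \code{"casim_effect"} object.
#' @param v index values on the covariate scale (uses the stored transform),
#'   or values already in \eqn{[0,1]} when \code{scale = "u"}.
#' @param scale \code{"index"} (default) or \code{"u"}.
#' @param centered subtract the stored centring offset (default TRUE).
#' @param deriv derivative order with respect to \code{u} (0 or 1); the
#'   centring offset is ignored for derivatives.
#' @return numeric vector of effect values.
#' @export
eval_effect <- function(effect, v, scale = c("index", "u"), centered = TRUE,
                        deriv = 0L) {
  stopifnot(inherits(effect, "casim_effect"))
  scale <- match.arg(scale)
  u <- if (scale == "index") {
    if (is.null(effect$transform)) stop("effect has no stored index transform")
    rescaled_beta_cdf(v, effect$transform)
  } else v
  val <- drop(bspline_design(u, effect$knots, derivs = deriv) %*% effect$coef)
  if (deriv == 0L && centered) val <- val - effect$centering_offset
  val
}

#' @export
print.casim_effect <- function(x, ...) {
  cat(sprintf("B-spline effect function: %s, %d basis functions%s\n",
              if (x$monotone) "monotone non-decreasing" else "unconstrained",
              length(x$coef),
              if (!is.null(x$transform))
                sprintf(", index scale a = %.4g (lag order %d)",
                        x$transform$a, x$transform$d) else ""))
  invisible(x)
}
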