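#' Index transform for a single-index lag block
#'
#' The scalar index \eqn{v = \theta^T X} formed from a covariate's lag window
#' lives on roughly \eqn{[-a, a]}, where \code{a} is a high percentile of the
#' per-day sup norm of the lag window.  Before spline fitting the index is
#' carried to \eqn{[0, 1]} by the CDF of a symmetric Beta-type law with shape
#' \eqn{(d+1)/2} rescaled and centred on \eqn{[-a, a]}, \code{d} being the lag
#' order.  This object bundles the two numbers that define that map.
#'
#' @param d integer lag order (number of lags beyond the contemporaneous
#'   value); \code{d >= 0}.
#' @param a positive scale, in the units of the covariate.
#' @return An object of class \code{"casim_transform"} with fields \code{d}
#'   and \code{a}.
#' @seealso [rescaled_beta_cdf()], [select_scale()]
#' @export
index_transform <- function(d, a) {
  if (length(d) != 1L || is.na(d) || d < 0 || d != floor(d))
    stop("'d' must be a single non-negative integer")
  if (length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive number")
  structure(list(d = as.integer(d), a = as.numeric(a)),
            class = "casim_transform")
}

#' Rescaled centred Beta CDF
#'
#' Evaluates the monotone map \eqn{F_d} carrying an index value
#' \eqn{v \in [-a, a]} to \eqn{[0, 1]}: the CDF of the symmetric
#' Beta\eqn{\{(d+1)/2, (d+1)/2\}} law on \eqn{[-1, 1]} evaluated at
#' \eqn{v/a}.  Values of \code{v} outside \eqn{[-a, a]} (possible because
#' \code{a} is a percentile, not a maximum) are clamped to the boundary.
#'
#' Computed through the regularized incomplete beta function
#' (\code{\link[stats]{pbeta}}), not quadrature.
#'
#' @param v numeric vector of index values.
#' @param transform a [index_transform()] object.
#' @return numeric vector in \eqn{[0, 1]}, same length as \code{v}.
#' @export
rescaled_beta_cdf <- function(v, transform) {
  stopifnot(inherits(transform, "casim_transform"))
  s <- d2shape(transform$d)
  z <- pmin(pmax(v / transform$a, -1), 1)
  # antisymmetric form: F(-v) = 1 - F(v) holds exactly, F(0) is exactly 1/2
  0.5 + 0.5 * (stats::pbeta((z + 1) / 2, s, s) -
                 stats::pbeta((1 - z) / 2, s, s))
}

#' Density of the rescaled centred Beta law
#'
#' Derivative of [rescaled_beta_cdf()] with respect to \code{v}; zero outside
#' \eqn{(-a, a)}, where the CDF is flat because of clamping.  Used for the
#' analytic gradient of the single-index objective.
#'
#' @inheritParams rescaled_beta_cdf
#' @return numeric vector of density values.
#' @export
rescaled_beta_pdf <- function(v, transform) {
  stopifnot(inherits(transform, "casim_transform"))
  s <- d2shape(transform$d)
  z <- v / transform$a
  out <- numeric(length(v))
  inside <- is.finite(z) & abs(z) < 1
  out[inside] <- stats::dbeta((z[inside] + 1) / 2, s, s) / (2 * transform$a)
  out
}

d2shape <- function(d) (d + 1) / 2

#' Scale of the index transform from a lagged block
#'
#' Returns the empirical 95th percentile (nearest-rank rule) of the per-row
#' sup norms \eqn{\max(|X_t|, |X_{t-1}|, \dots, |X_{t-L}|)} of a lagged
#' covariate block.  This is the half-width \code{a} of the interval on which
#' the index transform lives.
#'
#' @param lagged_block numeric matrix, rows = days, columns = lags 0..L.
#' @param prob percentile level, default 0.95.
#' @return positive scalar.
#' @export
select_scale <- function(lagged_block, prob = 0.95) {
  lagged_block <- as.matrix(lagged_block)
  if (nrow(lagged_block) < 2L) stop("lagged block needs at least 2 rows")
  if (anyNA(lagged_block)) stop("lagged block contains missing values")
  sup <- apply(abs(lagged_block), 1L, max)
  a <- casim_quantile(sup, prob)
  if (a <= 0) stop("index scale is zero (all-zero lag window)")
  a
}

# nearest-rank (type-1) empirical quantile, the one percentile rule used
# throughout the package
casim_quantile <- function(x, prob) {
  unname(stats::quantile(x, probs = prob, type = 1, names = FALSE))
}

#' Number of interior knots from the sample size
#'
#' The spline flexibility is fixed by the deterministic rule
#' \eqn{N = \max(\lfloor n^{1/5.5} \rfloor, 5)}.
#'
#' @param n sample size (\code{n >= 2}).
#' @return integer number of interior knots, at least 5.
#' @export
knot_count <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 2) stop("'n' must be at least 2")
  max(floor(n^(1 / 5.5)), 5L)
}

#' Quantile-based knot sequence on [0, 1]
#'
#' Places \code{N} interior knots at the \eqn{j/(N+1)} empirical quantiles
#' (nearest-rank rule) of the transformed index values, so each inter-knot
#' segment holds roughly the same number of observations, and augments them
#' with boundary knots 0 and 1 each repeated \code{order} times.  Duplicate
#' interior knots (heavy ties in \code{u}) are collapsed with a warning and
#' \code{N} reduced accordingly.
#'
#' @param u numeric vector of transformed index values in \eqn{[0, 1]}.
#' @param N requested number of interior knots.
#' @param order spline order (4 = cubic).
#' @return An object of class \code{"casim_knots"}: list with \code{interior},
#'   \code{order}, and the \code{augmented} knot vector.  Basis dimension is
#'   \code{length(interior) + order}.
#' @export
place_knots <- function(u, N, order = 4L) {
  if (any(u < 0 | u > 1, na.rm = TRUE)) stop("'u' must lie in [0, 1]")
  if (N < 1L) stop("'N' must be at least 1")
  interior <- casim_quantile(u, seq_len(N) / (N + 1))
  # knots at the very boundary add no flexibility beyond the clamped copies
  interior <- interior[interior > 0 & interior < 1]
  if (anyDuplicated(interior)) {
    interior <- unique(interior)
    warning("duplicate interior knots collapsed; N reduced to ",
            length(interior))
  }
  if (length(interior) < 1L)
    stop("too few distinct index values to place interior knots")
  structure(list(interior = interior, order = as.integer(order),
                 augmented = c(rep(0, order), interior, rep(1, order))),
            class = "casim_knots")
}

#' B-spline design matrix on [0, 1]
#'
#' Cubic (order-\code{k}) B-spline basis evaluated at the transformed index
#' values, built on the augmented knot sequence of [place_knots()].  Rows sum
#' to one (partition of unity) and all entries are non-negative.
#'
#' @param u numeric vector in \eqn{[0, 1]}.
#' @param knots a \code{"casim_knots"} object.
#' @param derivs derivative order (0 = values, 1 = first derivative).
#' @return numeric matrix, \code{length(u)} rows and
#'   \code{length(knots$interior) + knots$order} columns.
#' @export
bspline_design <- function(u, knots, derivs = 0L) {
  stopifnot(inherits(knots, "casim_knots"))
  if (any(u < 0 | u > 1, na.rm = TRUE)) stop("'u' must lie in [0, 1]")
  splines::splineDesign(knots$augmented, u, ord = knots$order,
                        derivs = rep(derivs, length(u)))
}
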