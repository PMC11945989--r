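#' Lag-weight vector on the ordered unit simplex
#'
#' Constructor and validator for a covariate's lag weights
#' \eqn{\theta = (\theta_0, \dots, \theta_L)}: non-negative, non-increasing
#' in the lag, and summing to one.  The non-increasing shape encodes the
#' epidemiological assumption that more recent exposure never matters less
#' than older exposure; the unit sum identifies the scale of the index.
#'
#' @param theta numeric vector of weights.
#' @param check validate the constraints (default TRUE).
#' @return object of class \code{"casim_weights"} (a numeric vector with a
#'   \code{lag} attribute equal to \code{length(theta) - 1}).
#' @export
index_weights <- function(theta, check = TRUE) {
  theta <- as.numeric(theta)
  if (length(theta) < 1L || anyNA(theta)) stop("invalid weight vector")
  if (check) {
    if (abs(sum(theta) - 1) > 1e-10) stop("weights must sum to 1")
    if (any(diff(theta) > 1e-10)) stop("weights must be non-increasing")
    if (any(theta < -1e-10)) stop("weights must be non-negative")
  }
  structure(theta, lag = length(theta) - 1L, class = "casim_weights")
}

#' Euclidean projection onto the ordered unit simplex
#'
#' Projects an arbitrary vector onto
#' \eqn{\{\theta : \theta_0 \ge \theta_1 \ge \dots \ge \theta_L \ge 0,\ \sum
#' \theta = 1\}}.  The projection is computed in two exact steps: isotonic
#' regression onto the non-increasing cone (pool-adjacent-violators via
#' \code{\link[stats]{isoreg}}), then the water-filling shift-and-clip that
#' solves the scalar dual of the sum constraint in closed form.  The
#' composition is the exact Euclidean projection because projection onto the
#' monotone cone commutes with adding a constant and clipping at zero.
#'
#' @param raw numeric vector, finite.
#' @return a [index_weights()] object of the same length.
#' @export
project_ordered_simplex <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) < 1L) stop("empty vector")
  if (anyNA(raw) || any(!is.finite(raw))) stop("non-finite input")
  if (length(raw) == 1L) return(index_weights(1))
  # the projection is the identity on the feasible set; returning feasible
  # input unchanged also makes repeated projection exactly idempotent
  if (all(diff(raw) <= 0) && raw[length(raw)] >= 0 &&
      abs(sum(raw) - 1) <= 1e-12)
    return(index_weights(raw, check = FALSE))
  # projection onto the non-increasing cone
  m <- -stats::isoreg(-raw)$yf
  # m is sorted non-increasing: water-filling solves sum(pmax(m - lam, 0)) = 1
  cs <- cumsum(m)
  k <- max(which(m - (cs - 1) / seq_along(m) > 0))
  lam <- (cs[k] - 1) / k
  index_weights(pmax(m - lam, 0))
}
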