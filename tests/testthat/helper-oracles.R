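# Independent oracles used across the suite.  Each re-derives a quantity by
# a route disjoint from the package implementation: adaptive quadrature for
# the index-transform CDF, KKT active-set enumeration for the constrained
# least-squares problems, and a direct Cox-de Boor recursion for the
# B-spline basis.

# CDF of the rescaled centred Beta law by adaptive quadrature of its density
# (substitution t = sin(s) removes the endpoint singularity at d = 0 while
# leaving the integrand exactly the printed one)
oracle_beta_cdf <- function(v, d, a) {
  integrand <- function(s) {
    t <- sin(s)
    gamma(d + 1) / gamma((d + 1) / 2)^2 / 2^d *
      (1 - t^2)^((d - 1) / 2) * cos(s)
  }
  upper <- min(max(v / a, -1), 1)
  if (upper <= -1) return(0)
  stats::integrate(integrand, -pi / 2, asin(upper), rel.tol = 1e-12,
                   abs.tol = 1e-12)$value
}

# Euclidean projection onto {theta: ordered non-increasing, >= 0, sum 1}
# by enumerating every active set of the inequality constraints and taking
# the best primal-feasible equality-constrained solution (the projection is
# always among the candidates).
oracle_ordered_simplex <- function(y) {
  q <- length(y)
  # inequality rows: theta_i - theta_{i+1} >= 0 (i < q), theta_q >= 0
  G <- matrix(0, q, q)
  for (i in seq_len(q - 1)) { G[i, i] <- 1; G[i, i + 1] <- -1 }
  G[q, q] <- 1
  best <- NULL; best_val <- Inf
  for (mask in 0:(2^q - 1)) {
    act <- which(bitwAnd(mask, 2^(seq_len(q) - 1)) > 0)
    C <- rbind(rep(1, q), G[act, , drop = FALSE])
    b <- c(1, rep(0, length(act)))
    th <- tryCatch({
      nu <- solve(tcrossprod(C), C %*% y - b)
      drop(y - crossprod(C, nu))
    }, error = function(e) NULL)
    if (is.null(th)) next
    if (all(G %*% th >= -1e-9)) {
      val <- sum((th - y)^2)
      if (val < best_val) { best_val <- val; best <- th }
    }
  }
  best
}

# Constrained least squares min ||B beta - Z||^2 s.t. diff(beta) >= 0 by
# active-set enumeration: ties between adjacent coefficients are imposed as
# equalities through a grouping map, and the best feasible candidate wins.
oracle_monotone_ls <- function(Z, B) {
  m <- ncol(B)
  best_val <- Inf; best <- NULL
  for (mask in 0:(2^(m - 1) - 1)) {
    tied <- bitwAnd(mask, 2^(seq_len(m - 1) - 1)) > 0
    group <- cumsum(c(1, !tied))
    M <- outer(group, seq_len(max(group)), `==`) + 0
    phi <- tryCatch(qr.solve(B %*% M, Z), error = function(e) NULL)
    if (is.null(phi)) next
    beta <- drop(M %*% phi)
    if (all(diff(beta) >= -1e-9)) {
      val <- sum((B %*% beta - Z)^2)
      if (val < best_val) { best_val <- val; best <- beta }
    }
  }
  list(beta = best, rss = best_val)
}

# Cox-de Boor recursion evaluated directly from the augmented knot vector
oracle_bspline_row <- function(x, knots, ord) {
  nb <- length(knots) - ord
  b <- numeric(length(knots) - 1)
  for (j in seq_along(b)) {
    b[j] <- as.numeric(x >= knots[j] & x < knots[j + 1])
  }
  # right-continuity fix: x at the right boundary belongs to the last
  # non-empty interval
  if (x >= knots[length(knots)]) {
    last <- max(which(knots < knots[length(knots)]))
    b[last] <- 1
  }
  for (k in 2:ord) {
    bk <- numeric(length(knots) - k)
    for (j in seq_along(bk)) {
      t1 <- knots[j + k - 1] - knots[j]
      t2 <- knots[j + k] - knots[j + 1]
      a1 <- if (t1 > 0) (x - knots[j]) / t1 * b[j] else 0
      a2 <- if (t2 > 0) (knots[j + k] - x) / t2 * b[j + 1] else 0
      bk[j] <- a1 + a2
    }
    b <- bk
  }
  b[seq_len(nb)]
}
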