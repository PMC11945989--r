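#' Day-of-week indicator design
#'
#' Builds the n x 6 indicator matrix of the weekly admission-pattern term
#' \eqn{S(t) = \sum_{k=1}^{6} \alpha_k D_{k,t}}: the default day carries no
#' indicator (its effect is pinned to 0 for identifiability) and the six
#' columns are the remaining weekdays in calendar order starting the day
#' after the default day (Friday default puts k = 1..6 at Saturday, Sunday,
#' Monday, Tuesday, Wednesday, Thursday).  Weekday extraction uses the ISO
#' day number, independent of locale.
#'
#' @param dates \code{Date} vector.
#' @param default_day weekday name, default \code{"Friday"}.
#' @return integer matrix with one row per date and 6 named columns; rows on
#'   the default day are all zero, other rows have exactly one 1.
#' @export
build_week_design <- function(dates, default_day = "Friday") {
  daynames <- c("Sunday", "Monday", "Tuesday", "Wednesday", "Thursday",
                "Friday", "Saturday")
  d0 <- match(default_day, daynames) - 1L       # 0 = Sunday, ..., 6 = Saturday
  if (is.na(d0)) stop("unknown default_day: ", default_day)
  wd <- as.POSIXlt(as.Date(dates))$wday
  order_wd <- (d0 + 1:6) %% 7L
  D <- matrix(0L, length(dates), 6L,
              dimnames = list(NULL, daynames[order_wd + 1L]))
  for (k in 1:6) D[wd == order_wd[k], k] <- 1L
  D
}

#' Logistic growth-curve intervention term
#'
#' The four-parameter sigmoid capturing a sustained post-intervention level
#' shift in the log outcome: zero up to the window start, and
#' \deqn{\lambda(\tau) = \xi_1 + \xi_3 / (1 + e^{-\xi_2 (\tau - \xi_4)})}
#' from the window end onward, where \eqn{\tau} counts days since the window
#' end.  \eqn{\xi_1} is the immediate post-window shift relative to the
#' pre-window level, \eqn{\xi_1 + \xi_3} the long-run shift, \eqn{\xi_2 > 0}
#' the relaxation rate (1/days) and \eqn{\xi_4} the midpoint (days).
#'
#' @param xi numeric length-4 parameter vector.
#' @param t_start,t_end window boundary dates (may be NULL for a pure-shape
#'   object used with [growth_curve_shift()]).
#' @return object of class \code{"casim_growth"}.
#' @export
growth_curve <- function(xi, t_start = NULL, t_end = NULL) {
  xi <- as.numeric(xi)
  if (length(xi) != 4L || anyNA(xi)) stop("'xi' must be 4 finite numbers")
  structure(list(xi = xi,
                 t_start = if (!is.null(t_start)) as.Date(t_start),
                 t_end = if (!is.null(t_end)) as.Date(t_end)),
            class = "casim_growth")
}

#' @rdname growth_curve
#' @param tau days since the window end (numeric vector).
#' @export
growth_curve_shift <- function(tau, xi) {
  xi[1] + xi[3] / (1 + exp(-xi[2] * (tau - xi[4])))
}

#' Evaluate the growth-curve term at dates
#'
#' Zero at or before the window start, the logistic shift at or after the
#' window end.  Dates strictly inside the window are an error: those rows
#' are excluded from fitting and the curve is not defined there.
#'
#' @param t \code{Date} vector.
#' @param growth a [growth_curve()] with window dates set.
#' @return numeric vector of \eqn{\lambda(t)} values.
#' @export
growth_curve_value <- function(t, growth) {
  stopifnot(inherits(growth, "casim_growth"))
  t <- as.Date(t)
  if (is.null(growth$t_start) || is.null(growth$t_end))
    stop("growth curve has no window dates")
  if (any(t > growth$t_start & t < growth$t_end))
    stop("growth curve undefined strictly inside the intervention window")
  out <- numeric(length(t))
  post <- t >= growth$t_end
  out[post] <- growth_curve_shift(as.numeric(t[post] - growth$t_end),
                                  growth$xi)
  out
}

#' Least-squares fit of the parametric model part
#'
#' Fits \eqn{y_t = \mu + S(t) + \lambda(t) + \epsilon_t} on the used rows:
#' given the growth curve's nonlinear pair \eqn{(\xi_2, \xi_4)} the model is
#' linear in \eqn{(\mu, \alpha, \xi_1, \xi_3)}, so the fit profiles the
#' linear part out and minimises the profiled RSS over \eqn{(\xi_2, \xi_4)}
#' by a multi-start grid (optionally including the previous iterate, which
#' makes the objective non-increasing across backfitting sweeps) followed by
#' a Nelder--Mead polish.  With no post-window rows (or no window at all)
#' the growth term is fixed at zero and the fit is a single linear
#' regression.
#'
#' @param y response vector on the used rows (a partial residual during
#'   backfitting).
#' @param W week design matrix for the used rows ([build_week_design()]).
#' @param post logical: is the row at or after the window end?
#' @param tau days since window end (only used where \code{post}).
#' @param control a [casim_control()].
#' @param prev_growth optional \code{"casim_growth"} warm start.
#' @return list with \code{mu}, \code{alpha} (named 6-vector), \code{xi},
#'   \code{growth_active}, \code{fitted}, \code{rss}.
#' @export
fit_parametric_part <- function(y, W, post = NULL, tau = NULL,
                                control = casim_control(),
                                prev_growth = NULL) {
  n <- length(y)
  if (is.null(post) || !any(post) || all(post)) {
    if (!is.null(post) && all(post))
      warning("no pre-intervention rows: growth term unidentifiable, fixed at 0")
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, W), y)
    cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    fitted <- y - fit$residuals
    return(list(mu = unname(cf[1]), alpha = cf[-1], xi = rep(0, 4),
                growth_active = FALSE, fitted = fitted,
                rss = sum(fit$residuals^2)))
  }

  tpost <- tau[post]
  lin_rss <- function(par) {            # par = (log xi2, xi4)
    s <- numeric(n)
    s[post] <- 1 / (1 + exp(-exp(par[1]) * (tpost - par[2])))
    D <- cbind(1, W, as.numeric(post), s)
    f <- stats::lm.fit(D, y)
    sum(f$residuals^2)
  }

  cand <- expand.grid(xi2 = control$xi2_grid,
                      xi4 = casim_quantile(tpost, control$xi4_frac))
  if (!is.null(prev_growth) && prev_growth$xi[2] > 0)
    cand <- rbind(cand, data.frame(xi2 = prev_growth$xi[2],
                                   xi4 = prev_growth$xi[4]))
  vals <- apply(cand, 1L, function(z) lin_rss(c(log(z[1]), z[2])))
  best <- as.numeric(cand[which.min(vals), ])
  par <- c(log(best[1]), best[2])
  if (control$polish) {
    op <- stats::optim(par, lin_rss, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 400))
    if (op$value <= min(vals)) par <- op$par
  }

  s <- numeric(n)
  s[post] <- 1 / (1 + exp(-exp(par[1]) * (tpost - par[2])))
  D <- cbind(1, W, as.numeric(post), s)
  f <- stats::lm.fit(D, y)
  cf <- ifelse(is.na(f$coefficients), 0, f$coefficients)
  m <- ncol(W)
  list(mu = unname(cf[1]), alpha = stats::setNames(cf[2:(m + 1)], colnames(W)),
       xi = c(unname(cf[m + 2]), exp(par[1]), unname(cf[m + 3]), par[2]),
       growth_active = TRUE, fitted = y - f$residuals,
       rss = sum(f$residuals^2))
}
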