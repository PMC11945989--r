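#' Daily outcome/covariate time-series dataset
#'
#' Validating constructor for the modelling dataset: a gap-free daily series
#' of positive outcome counts (e.g. respiratory hospital admissions), a
#' matrix of covariate series (pollutant concentrations, temperature,
#' relative humidity), and an optional intervention window whose interior
#' days are excluded from fitting (the model's growth-curve term describes
#' the level shift across that window, not the transition inside it).
#'
#' @param dates \code{Date} vector, strictly increasing, daily.  Calendar
#'   gaps are rejected unless \code{allow_gaps = TRUE}, in which case each
#'   gap starts a new contiguous segment and lag windows never straddle
#'   segments.
#' @param outcome positive daily counts \eqn{Y_t}.  Zeros are rejected
#'   because the model works on \eqn{\log Y_t}; set \code{zero_offset =
#'   TRUE} to add 0.5 to every count instead.
#' @param covariates numeric matrix or data frame, one named column per
#'   covariate, all finite.
#' @param pollutant_like named logical (or logical of \code{ncol}): does the
#'   covariate's effect curve have to be monotone non-decreasing (pollutants)
#'   or is it unrestricted (weather)?  Default: all TRUE.
#' @param intervention optional length-2 \code{Date} vector (start, end) of
#'   the excluded window; rows with \code{start < date < end} are flagged
#'   excluded.
#' @param default_day weekday whose day-of-week effect is pinned to zero.
#' @param allow_gaps,zero_offset see above.
#' @return object of class \code{"casim_dataset"}.
#' @export
casim_dataset <- function(dates, outcome, covariates,
                          pollutant_like = NULL, intervention = NULL,
                          default_day = "Friday", allow_gaps = FALSE,
                          zero_offset = FALSE) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable dates present")
  if (anyDuplicated(dates)) {
    stop("duplicated date(s): ",
         paste(format(dates[duplicated(dates)][1]), collapse = ", "))
  }
  if (is.unsorted(dates, strictly = TRUE)) stop("dates must be strictly increasing")
  n <- length(dates)
  step <- as.integer(diff(dates))
  if (any(step != 1L)) {
    if (!allow_gaps) {
      stop("calendar gap after ", format(dates[which(step != 1L)[1]]),
           " (use allow_gaps = TRUE to treat gaps as segment breaks)")
    }
  }
  segment <- cumsum(c(1L, as.integer(step != 1L)))

  outcome <- as.numeric(outcome)
  if (length(outcome) != n) stop("'outcome' length does not match dates")
  if (anyNA(outcome) || any(!is.finite(outcome))) stop("non-finite outcome values")
  if (zero_offset) outcome <- outcome + 0.5
  if (any(outcome <= 0)) {
    stop("non-positive outcome on ", format(dates[which(outcome <= 0)[1]]),
         ": the log transform requires positive counts",
         " (zero_offset = TRUE adds 0.5)")
  }

  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n) stop("'covariates' rows do not match dates")
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("X", seq_len(ncol(covariates)))
  if (!is.numeric(covariates) || anyNA(covariates) || any(!is.finite(covariates)))
    stop("covariates must be finite numeric")

  p <- ncol(covariates)
  if (is.null(pollutant_like)) pollutant_like <- rep(TRUE, p)
  if (!is.null(names(pollutant_like)))
    pollutant_like <- pollutant_like[colnames(covariates)]
  if (length(pollutant_like) != p || anyNA(pollutant_like))
    stop("'pollutant_like' must designate every covariate")
  pollutant_like <- as.logical(pollutant_like)
  names(pollutant_like) <- colnames(covariates)

  excluded <- rep(FALSE, n)
  if (!is.null(intervention)) {
    intervention <- as.Date(intervention)
    if (length(intervention) != 2L || anyNA(intervention) ||
        intervention[1] >= intervention[2])
      stop("'intervention' must be two increasing dates (start, end)")
    excluded <- dates > intervention[1] & dates < intervention[2]
  }

  structure(list(dates = dates, outcome = outcome,
                 log_outcome = log(outcome), covariates = covariates,
                 pollutant_like = pollutant_like,
                 intervention = intervention, excluded = excluded,
                 segment = segment, default_day = default_day),
            class = "casim_dataset")
}

#' @export
print.casim_dataset <- function(x, ...) {
  cat(sprintf("casim dataset: %d days (%s to %s), %d covariates [%s]\n",
              length(x$dates), format(x$dates[1]),
              format(x$dates[length(x$dates)]), ncol(x$covariates),
              paste(colnames(x$covariates), collapse = ", ")))
  if (!is.null(x$intervention))
    cat(sprintf("  excluded intervention window: %s to %s (%d days inside)\n",
                format(x$intervention[1]), format(x$intervention[2]),
                sum(x$excluded)))
  invisible(x)
}

#' Lagged covariate blocks aligned on a common row index
#'
#' For each covariate \code{j}, builds the matrix whose row \code{t} is
#' \eqn{(X_{j,t}, X_{j,t-1}, \dots, X_{j,t-L_j})}.  Rows whose lag window
#' would cross a segment boundary, precede the series start, or overlap the
#' excluded intervention window are dropped, and all blocks share one common
#' row index (determined by the largest lag so every block is complete on
#' every kept row).
#'
#' @param dataset a [casim_dataset()].
#' @param lags integer vector \eqn{(L_1, \dots, L_p)} of lag lengths.
#' @param trim_to optional integer: trim as if every lag were this long, so
#'   the usable sample is identical across lag candidates (required for
#'   comparable AICs during lag selection).
#' @return list with \code{rows} (kept row indices into the dataset),
#'   \code{dates}, \code{y} (log outcome on kept rows), \code{blocks}
#'   (per-covariate matrices), \code{lags} and \code{n_used}.
#' @export
build_lagged_blocks <- function(dataset, lags, trim_to = NULL) {
  stopifnot(inherits(dataset, "casim_dataset"))
  p <- ncol(dataset$covariates)
  lags <- as.integer(lags)
  if (length(lags) != p || any(lags < 0)) stop("'lags' must give one L >= 0 per covariate")
  n <- length(dataset$dates)
  M <- if (is.null(trim_to)) max(lags) else max(as.integer(trim_to), max(lags))
  t_idx <- seq_len(n)
  ok <- t_idx > M
  if (!any(ok)) stop("lags exceed the available history")
  excl_cum0 <- c(0, cumsum(dataset$excluded))
  keep <- which(ok)
  same_seg <- dataset$segment[keep - M] == dataset$segment[keep]
  # window [t-M, t] must be one contiguous segment with no excluded day
  win_excl <- excl_cum0[keep + 1L] - excl_cum0[keep - M]
  rows <- keep[same_seg & win_excl == 0L]
  if (length(rows) == 0L) stop("no usable rows for the requested lags")
  blocks <- lapply(seq_len(p), function(j) {
    x <- dataset$covariates[, j]
    b <- vapply(0:lags[j], function(tau) x[rows - tau], numeric(length(rows)))
    b <- matrix(b, nrow = length(rows))
    colnames(b) <- paste0("lag", 0:lags[j])
    b
  })
  names(blocks) <- colnames(dataset$covariates)
  list(rows = rows, dates = dataset$dates[rows],
       y = dataset$log_outcome[rows], blocks = blocks, lags = lags,
       n_used = length(rows))
}
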