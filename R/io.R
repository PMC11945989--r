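#' Read a modelling dataset from delimited text
#'
#' Reads a CSV with one row per day: an ISO-8601 date column, a positive
#' outcome-count column, and one numeric column per covariate.  All
#' validation (duplicate dates, calendar gaps, non-positive counts,
#' non-numeric covariates) is delegated to [casim_dataset()], which reports
#' the offending rows.
#'
#' @param path file path.
#' @param date_col,outcome_col column names (defaults "date", "outcome").
#' @param covariate_cols covariate column names; default: every other
#'   column.
#' @param pollutant_like,intervention,default_day,allow_gaps,zero_offset
#'   passed to [casim_dataset()].
#' @param sep field separator (default comma).
#' @return a [casim_dataset()].
#' @export
read_casim_dataset <- function(path, date_col = "date",
                               outcome_col = "outcome",
                               covariate_cols = NULL, pollutant_like = NULL,
                               intervention = NULL, default_day = "Friday",
                               allow_gaps = FALSE, zero_offset = FALSE,
                               sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(date_col, outcome_col))
    if (!col %in% names(df)) stop("missing mapped column: ", col)
  if (is.null(covariate_cols))
    covariate_cols <- setdiff(names(df), c(date_col, outcome_col))
  missing_cov <- setdiff(covariate_cols, names(df))
  if (length(missing_cov))
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "))
  cov <- df[covariate_cols]
  bad <- !vapply(cov, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric covariate column(s): ",
         paste(covariate_cols[bad], collapse = ", "))
  casim_dataset(dates = as.Date(df[[date_col]], format = "%Y-%m-%d"),
                outcome = df[[outcome_col]], covariates = as.matrix(cov),
                pollutant_like = pollutant_like, intervention = intervention,
                default_day = default_day, allow_gaps = allow_gaps,
                zero_offset = zero_offset)
}

#' Write a synthetic dataset and its truth to disk
#'
#' @param sim a [simulate_casim()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  df <- data.frame(date = format(ds$dates), outcome = ds$outcome,
                   ds$covariates, check.names = FALSE)
  dataset_path <- file.path(outdir, "dataset.csv")
  utils::write.csv(df, dataset_path, row.names = FALSE)
  truth_path <- file.path(outdir, "truth.txt")
  tr <- sim$truth
  con <- file(truth_path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("n: %d", tr$n), sprintf("p: %d", tr$p),
    sprintf("lags: %s", paste(tr$lags, collapse = " ")),
    sprintf("mu: %.10g", tr$mu),
    sprintf("alpha: %s", paste(sprintf("%.10g", tr$alpha), collapse = " ")),
    sprintf("xi: %s", paste(sprintf("%.10g", tr$xi), collapse = " ")),
    sprintf("noise_sd: %.10g", tr$noise_sd),
    sprintf("seed: %d", tr$seed),
    unlist(lapply(seq_len(tr$p), function(j)
      sprintf("theta%d: %s", j,
              paste(sprintf("%.10g", tr$theta[[j]]), collapse = " "))))),
    con)
  comp_path <- file.path(outdir, "components.csv")
  utils::write.csv(sim$components, comp_path, row.names = FALSE)
  invisible(c(dataset_path, truth_path, comp_path))
}

#' Write the full model report
#'
#' Serialises a fit (and optional bootstrap bounds) as delimited text:
#' parameter table (estimate, and SD/bounds when available), lag table,
#' per-lag weight table with bands, effect curves on a grid with bands,
#' the fitted/residual series on both scales, the RSS trace, and a run
#' log.  Optionally writes diagnostic plots (weights per lag, effect
#' curves, fitted series) as PNG files.
#'
#' @param fit a \code{"casim_fit"}.
#' @param bounds optional [confidence_bounds()] result.
#' @param outdir output directory.
#' @param plots write PNG diagnostics (default FALSE).
#' @return invisibly, the directory.
#' @export
write_report <- function(fit, bounds = NULL, outdir, plots = FALSE) {
  stopifnot(inherits(fit, "casim_fit"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(outdir, f),
                                         row.names = FALSE)

  if (is.null(bounds)) {
    params <- data.frame(
      parameter = c("mu", names(fit$weekly$alpha), paste0("xi", 1:4)),
      estimate = c(fit$mu, fit$weekly$alpha, fit$growth$xi))
  } else {
    params <- bounds$parameters
  }
  wr(params, "parameters.csv")

  wr(data.frame(covariate = names(fit$blocks), lag = fit$lags),
     "lags.csv")

  weights <- do.call(rbind, lapply(names(fit$blocks), function(nm) {
    if (!is.null(bounds)) {
      cbind(covariate = nm, bounds$theta[[nm]])
    } else {
      th <- as.numeric(fit$blocks[[nm]]$weights)
      data.frame(covariate = nm, lag = seq_along(th) - 1L, estimate = th)
    }
  }))
  wr(weights, "weights.csv")

  lb <- build_lagged_blocks(fit$dataset, fit$lags, fit$trim_to)
  effects <- do.call(rbind, lapply(names(fit$blocks), function(nm) {
    if (!is.null(bounds)) return(cbind(covariate = nm, bounds$curves[[nm]]))
    b <- fit$blocks[[nm]]
    v <- drop(lb$blocks[[nm]] %*% as.numeric(b$weights))
    grid <- seq(min(v), max(v), length.out = 100)
    data.frame(covariate = nm, index = grid,
               estimate = eval_effect(b$effect, grid))
  }))
  wr(effects, "effects.csv")

  wr(predict(fit), "series.csv")
  wr(data.frame(cycle = seq_along(fit$rss_trace) - 1L, rss = fit$rss_trace),
     "rss_trace.csv")

  writeLines(c(
    sprintf("n_used: %d", fit$n_used),
    sprintf("converged: %s after %d cycles", fit$converged, fit$iterations),
    sprintf("mse: %.10g", fit$mse),
    sprintf("rmse_log: %.10g", sqrt(fit$mse)),
    sprintf("aic: %.10g", fit$aic),
    sprintf("lags: %s", paste(fit$lags, collapse = " "))),
    file.path(outdir, "run_log.txt"))

  if (plots) {
    grDevices::png(file.path(outdir, "weights.png"), 900, 300 *
                     ceiling(length(fit$blocks) / 3))
    graphics::par(mfrow = c(ceiling(length(fit$blocks) / 3),
                            min(3, length(fit$blocks))))
    for (nm in names(fit$blocks)) {
      th <- as.numeric(fit$blocks[[nm]]$weights)
      graphics::plot(seq_along(th) - 1L, th, type = "b", xlab = "lag (days)",
                     ylab = "weight", main = nm)
    }
    grDevices::dev.off()
    grDevices::png(file.path(outdir, "effects.png"), 900, 300 *
                     ceiling(length(fit$blocks) / 3))
    graphics::par(mfrow = c(ceiling(length(fit$blocks) / 3),
                            min(3, length(fit$blocks))))
    for (nm in names(fit$blocks)) {
      sub <- effects[effects$covariate == nm, ]
      graphics::plot(sub$index, sub$estimate, type = "l",
                     xlab = "weighted average", ylab = "effect", main = nm)
    }
    grDevices::dev.off()
    grDevices::png(file.path(outdir, "series.png"), 1000, 500)
    pr <- predict(fit)
    graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
    graphics::plot(pr$date, lb$y, col = "steelblue", pch = 20, cex = 0.4,
                   xlab = "", ylab = "log outcome")
    graphics::lines(pr$date, pr$log_fitted)
    graphics::plot(pr$date, pr$log_residual, pch = 20, cex = 0.4,
                   xlab = "", ylab = "log residual")
    graphics::abline(h = 0, lty = 2)
    grDevices::dev.off()
  }
  invisible(outdir)
}
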