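#' Internal validation generic
#'
#' @param object a fitted model.
#' @param ... method arguments.
#' @export
validate <- function(object, ...) UseMethod("validate")

#' Bootstrap optimism-corrected internal validation
#'
#' Harrell-style internal validation of an \code{\link{sts_riskmodel}}. For
#' each of \code{B} with-replacement resamples of the training rows the
#' entire modelling pipeline (including re-estimation of the
#' standardization) is refitted; the resample AUC (\code{auc_boot}) and the
#' refitted model's AUC on the original data (\code{auc_orig}) give the
#' per-resample optimism \code{auc_boot - auc_orig}. The corrected AUC is
#' the apparent AUC minus the mean optimism; its CI is the percentile
#' interval of the per-resample corrected values, and the bootstrap AUC
#' mean/CI summarize \code{auc_boot}. Calibration slope and intercept are
#' reported both apparent (full-data fit on its own predictions) and
#' optimism-corrected by the same resample scheme; sensitivity and
#' specificity are taken at the Youden-optimal threshold of the apparent
#' predictions. Resamples with a single outcome class are redrawn (count
#' logged) so B stays fixed.
#'
#' @param object an \code{\link{sts_riskmodel}}.
#' @param B number of bootstrap resamples (default 500).
#' @param seed integer seed; results are reproducible bit-for-bit given the
#'   seed.
#' @param ... reserved.
#' @return object of class \code{sts_validation} with the performance fields
#'   described above.
#' @export
validate.sts_riskmodel <- function(object, B = 500, seed = 1, ...) {
  if (B < 1) stop_invalid("B must be >= 1")
  data <- object$data
  n <- length(object$y)
  apparent_auc <- auc_mann_whitney(object$fitted_link, object$y)
  cal_app <- tryCatch(calibration_slope_intercept(object$fitted, object$y),
                      error = function(e) list(slope = NA_real_,
                                               intercept = NA_real_))
  op <- youden_operating_point(object$fitted, object$y)
  set.seed(seed)
  auc_boot <- auc_orig <- slope_opt <- int_opt <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      # a resample needs at least two observations of each class to refit
      if (min(tabulate(object$y[idx] + 1L, 2L)) >= 2L) break
      redraws <- redraws + 1L
    }
    fit_b <- sts_riskmodel(object$formula, data[idx, , drop = FALSE],
                           mixing = object$mixing,
                           strength = object$strength)
    eta_orig <- predict(fit_b, data, type = "link")
    auc_boot[b] <- auc_mann_whitney(fit_b$fitted_link, fit_b$y)
    auc_orig[b] <- auc_mann_whitney(eta_orig, object$y)
    cal_b <- tryCatch(
      calibration_slope_intercept(fit_b$fitted, fit_b$y),
      error = function(e) list(slope = NA_real_, intercept = NA_real_))
    cal_ob <- tryCatch(
      calibration_slope_intercept(stats::plogis(eta_orig), object$y),
      error = function(e) list(slope = NA_real_, intercept = NA_real_))
    slope_opt[b] <- cal_b$slope - cal_ob$slope
    int_opt[b] <- cal_b$intercept - cal_ob$intercept
  }
  optimism <- auc_boot - auc_orig
  corrected_b <- apparent_auc - optimism
  qs <- function(v) unname(stats::quantile(v, c(0.025, 0.975), na.rm = TRUE))
  structure(list(
    apparent_auc = apparent_auc,
    boot_auc_mean = mean(auc_boot),
    boot_auc_ci = qs(auc_boot),
    optimism = mean(optimism),
    corrected_auc = apparent_auc - mean(optimism),
    corrected_auc_ci = qs(corrected_b),
    calibration_slope = cal_app$slope,
    calibration_intercept = cal_app$intercept,
    corrected_calibration_slope = cal_app$slope - mean(slope_opt, na.rm = TRUE),
    corrected_calibration_intercept = cal_app$intercept -
      mean(int_opt, na.rm = TRUE),
    sensitivity = op$sensitivity,
    specificity = op$specificity,
    threshold = op$threshold,
    B = B, n = n, seed = seed, redraws = redraws,
    formula = object$formula
  ), class = "sts_validation")
}

#' @export
print.sts_validation <- function(x, ...) {
  cat("Bootstrap internal validation (", x$B, " resamples, n = ", x$n, ")\n",
      sep = "")
  cat("  model:", deparse(x$formula), "\n")
  cat(sprintf("  apparent AUC           %.3f\n", x$apparent_auc))
  cat(sprintf("  bootstrap AUC mean     %.3f (95%% CI %.3f-%.3f)\n",
              x$boot_auc_mean, x$boot_auc_ci[1], x$boot_auc_ci[2]))
  cat(sprintf("  optimism-corrected AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$corrected_auc, x$corrected_auc_ci[1], x$corrected_auc_ci[2]))
  cat(sprintf("  calibration slope %.2f, intercept %.2f (apparent)\n",
              x$calibration_slope, x$calibration_intercept))
  cat(sprintf("  sensitivity %.3f, specificity %.3f (Youden threshold %.3f)\n",
              x$sensitivity, x$specificity, x$threshold))
  if (x$redraws > 0)
    cat(sprintf("  (%d degenerate resamples redrawn)\n", x$redraws))
  invisible(x)
}

#' Benchmark model specifications
#'
#' The five prediction models compared for each outcome: demographics only,
#' the two established clinical screens, and the smartphone models with and
#' without the temporal measures.
#'
#' @return named list mapping model name to predictor fields.
#' @export
model_specs <- function() {
  list(age_sex = c("age", "sex"),
       walking_speed = "walking_speed",
       grip_strength = "grip",
       smartphone = c("age", "sex", "peak_force", "T1", "T2"),
       smartphone_reduced = c("age", "sex", "peak_force"))
}

#' Fit and internally validate the benchmark model suite
#'
#' Fits the five \code{\link{model_specs}} models for one outcome and runs
#' \code{\link{validate}} on each, returning one performance row per model
#' in the conventional reporting order.
#'
#' @param cohort data frame containing the outcome column and all predictor
#'   fields (\code{age}, \code{sex}, \code{walking_speed}, \code{grip},
#'   \code{peak_force}, \code{T1}, \code{T2}).
#' @param outcome \code{"sarcopenia"} or \code{"frailty"} (column
#'   \code{frail}); any logical column name is accepted.
#' @param B bootstrap resamples per model.
#' @param seed integer seed; each model gets a deterministic child seed.
#' @param mixing,strength passed to \code{\link{sts_riskmodel}}.
#' @return data frame of class \code{sts_suite}, one row per model with the
#'   full performance report.
#' @export
run_model_suite <- function(cohort, outcome = c("sarcopenia", "frailty"),
                            B = 500, seed = 1, mixing = 0.5, strength = 1) {
  if (length(outcome) > 1) outcome <- match.arg(outcome)
  ycol <- if (outcome == "frailty" && !"frailty" %in% names(cohort)) "frail"
          else outcome
  if (!ycol %in% names(cohort))
    stop_invalid("cohort has no outcome column '%s'", ycol)
  specs <- model_specs()
  rows <- lapply(seq_along(specs), function(i) {
    preds <- specs[[i]]
    miss <- setdiff(preds, names(cohort))
    if (length(miss) > 0)
      stop_invalid("cohort missing predictor column(s): %s",
                   paste(miss, collapse = ", "))
    fml <- stats::reformulate(preds, response = ycol)
    fit <- sts_riskmodel(fml, cohort, mixing = mixing, strength = strength)
    v <- validate(fit, B = B, seed = child_seed(seed, i))
    data.frame(model = names(specs)[i],
               predictors = paste(preds, collapse = "+"),
               boot_auc_mean = v$boot_auc_mean,
               boot_auc_lo = v$boot_auc_ci[1], boot_auc_hi = v$boot_auc_ci[2],
               apparent_auc = v$apparent_auc,
               corrected_auc = v$corrected_auc,
               corrected_auc_lo = v$corrected_auc_ci[1],
               corrected_auc_hi = v$corrected_auc_ci[2],
               calibration_slope = v$calibration_slope,
               calibration_intercept = v$calibration_intercept,
               sensitivity = v$sensitivity,
               specificity = v$specificity)
  })
  out <- do.call(rbind, rows)
  attr(out, "outcome") <- outcome
  attr(out, "settings") <- list(B = B, seed = seed, mixing = mixing,
                                strength = strength)
  class(out) <- c("sts_suite", "data.frame")
  out
}

#' @export
print.sts_suite <- function(x, digits = 3, ...) {
  s <- attr(x, "settings")
  cat(sprintf("Model performance for %s (B = %d, seed = %d)\n",
              attr(x, "outcome"), s$B, s$seed))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a performance table as CSV and JSON
#'
#' @param suite an \code{sts_suite}.
#' @param path output path without extension; \code{.csv} and \code{.json}
#'   files are written.
#' @return invisibly, the two file paths.
#' @export
write_performance_table <- function(suite, path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  utils::write.csv(as.data.frame(suite), csv, row.names = FALSE)
  jsonlite::write_json(list(outcome = attr(suite, "outcome"),
                            settings = attr(suite, "settings"),
                            performance = as.data.frame(suite)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
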