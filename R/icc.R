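#' Intraclass correlation ICC(2,1)
#'
#' Single-measurement, absolute-agreement intraclass correlation from the
#' two-way (subjects x raters) mean-squares decomposition:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater, and
#' residual mean squares. This is the form used for trial-pair
#' reproducibility (two consecutive sit-to-stand trials as raters) and for
#' device-agreement waveform comparison. Negative estimates are returned as
#' computed, not truncated at zero.
#'
#' @param ratings numeric n x k matrix (n subjects >= 3, k raters >= 2), no
#'   missing cells.
#' @return an object of class \code{icc_result}: \code{icc}, the mean squares
#'   \code{ms_rows}, \code{ms_cols}, \code{ms_error}, and \code{n_subjects},
#'   \code{k_raters}.
#' @export
icc_2_1 <- function(ratings) {
  x <- as.matrix(ratings)
  if (!is.numeric(x)) stop_invalid("ratings must be numeric")
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop_invalid("need at least 3 subjects (got %d)", n)
  if (k < 2L) stop_invalid("need at least 2 raters (got %d)", k)
  if (anyNA(x)) stop_invalid("missing cells are not supported")
  m <- mean(x)
  if (all(abs(x - m) < .Machine$double.eps * 100 * max(1, abs(m))))
    stop_invalid("ICC undefined for a constant ratings matrix (zero total variance)")
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - m)^2)
  ssc <- n * sum((col_m - m)^2)
  sst <- sum((x - m)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  structure(list(icc = icc, ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n_subjects = n, k_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f  (n = %d subjects, k = %d raters)\n",
              x$icc, x$n_subjects, x$k_raters))
  cat(sprintf("  mean squares: rows %.5g, cols %.5g, error %.5g\n",
              x$ms_rows, x$ms_cols, x$ms_error))
  invisible(x)
}

#' Device-agreement waveform ICC
#'
#' Compares two recordings of the same sit-to-stand movement (e.g. smartphone
#' vs a high-rate reference accelerometer). The signals are brought to a
#' common sampling rate, temporally aligned by normalized cross-correlation,
#' restricted to the movement phase (onset through stabilization), and the
#' time samples are then treated as "subjects" with the two devices as raters
#' in \code{\link{icc_2_1}}.
#'
#' @param a \code{\link{scalar_trace}} for the index device; the comparison is
#'   done at this signal's sampling rate.
#' @param b \code{\link{scalar_trace}} for the other device; resampled to
#'   \code{a}'s rate if needed.
#' @param features \code{\link{sts_features}} giving the movement phase on
#'   \code{a}'s time base.
#' @param max_lag alignment search half-window in seconds.
#' @return an \code{icc_result} with the alignment lag attached as attribute
#'   \code{"lag"}.
#' @export
waveform_agreement <- function(a, b, features, max_lag = 2) {
  stopifnot(inherits(a, "scalar_trace"), inherits(b, "scalar_trace"))
  if (abs(b$sampling_rate - a$sampling_rate) > 1e-9)
    b <- resample_linear(b, a$sampling_rate)
  al <- align_by_crosscorrelation(a, b, max_lag = max_lag)
  k <- al$lag_samples
  i0 <- features$onset_index
  i1 <- features$stabilization_index
  seg_a <- extract_movement_phase(a, features)$values
  j0 <- i0 + k; j1 <- i1 + k
  if (j0 < 1 || j1 > length(b$values))
    stop_invalid("aligned movement phase [%d, %d] falls outside the second signal (length %d)",
                 j0, j1, length(b$values))
  seg_b <- b$values[j0:j1]
  if (length(seg_a) != length(seg_b))
    stop_invalid("movement-phase segments have unequal length after alignment")
  res <- icc_2_1(cbind(seg_a, seg_b))
  attr(res, "lag") <- al$lag
  res
}
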