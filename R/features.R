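#' Sit-to-stand event features
#'
#' Constructor for the feature set of a single sit-to-stand trial: event
#' indices (1-based samples), rising time T1 (onset to peak, s), stability
#' time T2 (peak to stabilization, s), peak dynamic acceleration (m/s^2) and
#' peak force (N, peak acceleration times body mass). Invalid trials (e.g.
#' never-stabilized) carry \code{valid = FALSE} and a reason, and are excluded
#' from downstream analysis.
#'
#' @param onset_index,peak_index,stabilization_index 1-based sample indices.
#' @param sampling_rate Hz.
#' @param peak_accel peak dynamic acceleration in m/s^2.
#' @param weight_kg body mass in kg.
#' @param stabilized logical; \code{FALSE} when the stabilization criterion
#'   was never met.
#' @param valid logical; \code{FALSE} flags an excluded trial.
#' @param reason character reason when invalid.
#' @return an object of class \code{sts_features}.
#' @export
sts_features <- function(onset_index, peak_index, stabilization_index,
                         sampling_rate, peak_accel, weight_kg,
                         stabilized = TRUE, valid = TRUE, reason = NA_character_) {
  if (valid) {
    if (!(onset_index <= peak_index && peak_index <= stabilization_index))
      stop_invalid("event ordering violated: onset %d, peak %d, stabilization %d",
                   onset_index, peak_index, stabilization_index)
  }
  structure(list(
    onset_index = as.integer(onset_index),
    peak_index = as.integer(peak_index),
    stabilization_index = as.integer(stabilization_index),
    sampling_rate = sampling_rate,
    T1 = (peak_index - onset_index) / sampling_rate,
    T2 = (stabilization_index - peak_index) / sampling_rate,
    peak_accel = peak_accel,
    peak_force = peak_accel * weight_kg,
    weight_kg = weight_kg,
    stabilized = stabilized, valid = valid, reason = reason
  ), class = "sts_features")
}

#' @export
print.sts_features <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("<sts_features> INVALID trial (%s)\n", x$reason))
  } else {
    cat(sprintf(
      "<sts_features> onset %d, peak %d, stab %d | T1 %.3f s, T2 %.3f s, peak %.3f m/s^2, force %.2f N%s\n",
      x$onset_index, x$peak_index, x$stabilization_index,
      x$T1, x$T2, x$peak_accel, x$peak_force,
      if (x$stabilized) "" else " [never stabilized]"))
  }
  invisible(x)
}

#' Detect the onset of standing
#'
#' The onset is the sample of lowest acceleration between the start of the
#' recording and the global maximum (the unweighting dip that precedes the
#' rise). The search is restricted to before the global maximum so post-peak
#' oscillation troughs cannot be selected; ties break to the earliest sample.
#'
#' @param signal filtered dynamic \code{\link{scalar_trace}}.
#' @return 1-based onset index.
#' @export
detect_onset <- function(signal) {
  stopifnot(inherits(signal, "scalar_trace"))
  v <- signal$values
  gmax <- which.max(v)
  if (gmax == 1L)
    stop_invalid("invalid trial: signal has no rise after its start (maximum at first sample)")
  which.min(v[seq_len(gmax)])
}

#' Detect the acceleration peak
#'
#' The peak is the highest acceleration strictly after the onset; ties break
#' to the earliest sample.
#'
#' @param signal filtered dynamic \code{\link{scalar_trace}}.
#' @param onset_index 1-based onset sample.
#' @return list with \code{peak_index} (1-based) and \code{peak_accel}.
#' @export
detect_peak <- function(signal, onset_index) {
  stopifnot(inherits(signal, "scalar_trace"))
  v <- signal$values
  n <- length(v)
  if (onset_index < 1 || onset_index >= n)
    stop_invalid("invalid trial: onset at final sample leaves no room for a peak")
  rel <- which.max(v[(onset_index + 1L):n])
  idx <- onset_index + rel
  list(peak_index = as.integer(idx), peak_accel = v[idx])
}

#' Detect postural stabilization
#'
#' Stable stance is reached when the acceleration variation after the peak
#' falls to 1% or less of standard gravity. Variation is operationalized as
#' the peak-to-peak range of the signal over a trailing window (default
#' 0.2 s) lying entirely after the peak; the first sample whose trailing
#' window satisfies range <= 0.01 g is returned. If no sample qualifies the
#' trace end is returned with \code{stabilized = FALSE}.
#'
#' @param signal filtered dynamic \code{\link{scalar_trace}}.
#' @param peak_index 1-based peak sample.
#' @param window trailing-window length in seconds (>= 2 samples).
#' @param threshold variation threshold in m/s^2 (default 0.01 g).
#' @return list with \code{stabilization_index} and logical \code{stabilized}.
#' @export
detect_stabilization <- function(signal, peak_index, window = 0.2,
                                 threshold = 0.01 * G_ACCEL) {
  stopifnot(inherits(signal, "scalar_trace"))
  v <- signal$values
  n <- length(v)
  w <- as.integer(round(window * signal$sampling_rate))
  if (w < 2L) stop_invalid("stabilization window must span at least 2 samples")
  if (peak_index < 1 || peak_index > n) stop_invalid("peak_index out of range")
  if (n - peak_index < w)
    stop_invalid("invalid trial: post-peak segment (%d samples) shorter than the %d-sample window",
                 n - peak_index, w)
  candidates <- seq.int(peak_index + w, n)
  for (i in candidates) {
    seg <- v[(i - w + 1L):i]
    if (max(seg) - min(seg) <= threshold)
      return(list(stabilization_index = as.integer(i), stabilized = TRUE))
  }
  list(stabilization_index = as.integer(n), stabilized = FALSE)
}

#' Extract sit-to-stand features from a raw trace
#'
#' Runs the full measurement chain: triaxial norm, inverse-FFT low-pass
#' filter, gravity handling, then onset/peak/stabilization detection; the
#' peak force is the peak dynamic acceleration multiplied by body mass.
#' Detector failures (no rise, never-stabilized within the criterion) yield a
#' flagged invalid \code{sts_features} rather than an error, mirroring
#' excluded trials in a cohort workflow.
#'
#' @param trace an \code{\link{accel_trace}}.
#' @param weight_kg body mass in kg (> 0).
#' @param cutoff low-pass cutoff in Hz.
#' @param stab_window stabilization trailing window in seconds.
#' @param taper optional filter taper width in Hz.
#' @param require_stabilized treat a never-stabilized trial as invalid
#'   (default TRUE).
#' @return an \code{\link{sts_features}} object.
#' @export
extract_sts_features <- function(trace, weight_kg, cutoff = 7.5,
                                 stab_window = 0.2, taper = 0,
                                 require_stabilized = TRUE) {
  stopifnot(inherits(trace, "accel_trace"))
  if (!is.finite(weight_kg) || weight_kg <= 0)
    stop_invalid("weight_kg must be positive")
  dyn <- dynamic_component(lowpass_fft(triaxial_norm(trace), cutoff = cutoff,
                                       taper = taper))
  out <- tryCatch({
    onset <- detect_onset(dyn)
    pk <- detect_peak(dyn, onset)
    st <- detect_stabilization(dyn, pk$peak_index, window = stab_window)
    f <- sts_features(onset, pk$peak_index, st$stabilization_index,
                      trace$sampling_rate, pk$peak_accel, weight_kg,
                      stabilized = st$stabilized)
    if (require_stabilized && !st$stabilized) {
      f$valid <- FALSE
      f$reason <- "never stabilized (variation criterion unmet)"
    }
    f
  }, error = function(e) {
    structure(list(onset_index = NA_integer_, peak_index = NA_integer_,
                   stabilization_index = NA_integer_,
                   sampling_rate = trace$sampling_rate,
                   T1 = NA_real_, T2 = NA_real_, peak_accel = NA_real_,
                   peak_force = NA_real_, weight_kg = weight_kg,
                   stabilized = FALSE, valid = FALSE,
                   reason = conditionMessage(e)),
              class = "sts_features")
  })
  out
}

#' Average two sit-to-stand trials
#'
#' Participant-level features are the arithmetic mean of the two trials'
#' peak force, peak acceleration, T1 and T2 (event indices are trial-specific
#' and dropped). If exactly one trial is valid its values are returned with
#' \code{degraded = TRUE}; if neither is valid the result is flagged invalid.
#'
#' @param f1,f2 \code{\link{sts_features}} objects for the two trials.
#' @return a list with \code{peak_force}, \code{peak_accel}, \code{T1},
#'   \code{T2}, \code{n_trials}, \code{degraded}, \code{valid}.
#' @export
average_trials <- function(f1, f2) {
  stopifnot(inherits(f1, "sts_features"), inherits(f2, "sts_features"))
  ok <- c(f1$valid, f2$valid)
  if (!any(ok)) {
    return(list(peak_force = NA_real_, peak_accel = NA_real_,
                T1 = NA_real_, T2 = NA_real_,
                n_trials = 0L, degraded = TRUE, valid = FALSE))
  }
  use <- list(f1, f2)[ok]
  avg <- function(field) mean(vapply(use, `[[`, numeric(1), field))
  list(peak_force = avg("peak_force"), peak_accel = avg("peak_accel"),
       T1 = avg("T1"), T2 = avg("T2"),
       n_trials = length(use), degraded = !all(ok), valid = TRUE)
}
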