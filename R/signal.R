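#' FFT brick-wall low-pass filter
#'
#' Filters a scalar trace by taking the discrete Fourier transform, zeroing
#' every bin whose frequency lies strictly above \code{cutoff} (conjugate
#' pairs are zeroed together, so the inverse transform is real), and inverse
#' transforming. The default 7.5 Hz cutoff removes sensor noise outside the
#' band of voluntary sit-to-stand movement. An optional raised-cosine taper of
#' width \code{taper} Hz below the cutoff softens the brick wall to reduce
#' ringing on short traces; the default is the literal brick wall, which is
#' idempotent.
#'
#' @param signal a \code{\link{scalar_trace}}.
#' @param cutoff pass-band edge in Hz; must be below the Nyquist frequency.
#' @param taper taper width in Hz (>= 0); 0 gives the exact brick wall.
#' @return a \code{scalar_trace} with provenance \code{"filtered"}.
#' @export
lowpass_fft <- function(signal, cutoff = 7.5, taper = 0) {
  stopifnot(inherits(signal, "scalar_trace"))
  x <- signal$values
  n <- length(x)
  rate <- signal$sampling_rate
  if (n < 2L) stop_invalid("signal too short to filter")
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= rate / 2)
    stop_invalid("cutoff must lie in (0, Nyquist) = (0, %g)", rate / 2)
  if (taper < 0 || taper >= cutoff) stop_invalid("taper must lie in [0, cutoff)")
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)          # folded (two-sided) bin frequencies
  w <- numeric(n)
  w[f <= cutoff - taper] <- 1
  if (taper > 0) {
    ramp <- f > cutoff - taper & f <= cutoff
    w[ramp] <- 0.5 * (1 + cos(pi * (f[ramp] - (cutoff - taper)) / taper))
  }
  y <- Re(stats::fft(stats::fft(x) * w, inverse = TRUE)) / n
  out <- scalar_trace(y, rate, "filtered")
  attr(out, "dialect") <- attr(signal, "dialect")
  out
}

#' Euclidean norm of a triaxial trace
#'
#' Per-sample norm \eqn{\sqrt{a_x^2+a_y^2+a_z^2}}. Because a smartphone's
#' device frame rotates with the body, the norm is used as an
#' orientation-invariant summary: it is unchanged by any rigid rotation of the
#' axes.
#'
#' @param trace an \code{\link{accel_trace}}.
#' @return a \code{scalar_trace} with provenance \code{"raw-norm"}; the
#'   trace's gravity dialect is carried along as attribute \code{"dialect"}.
#' @export
triaxial_norm <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  s <- scalar_trace(sqrt(trace$ax^2 + trace$ay^2 + trace$az^2),
                    trace$sampling_rate, "raw-norm")
  attr(s, "dialect") <- trace$dialect
  s
}

#' Dynamic (gravity-free) component of the filtered norm
#'
#' Bridges the non-negative norm to the signed signal on which event detection
#' operates. For a gravity-included recording with near-vertical movement the
#' norm is approximately \eqn{g + d(t)}, so subtracting standard gravity
#' (9.80665 m/s^2) recovers the signed dynamic acceleration \eqn{d(t)}
#' (negative during the unweighting dip). For a gravity-excluded recording the
#' norm is already the dynamic magnitude and is passed through unchanged.
#'
#' @param norm_signal filtered norm, a \code{scalar_trace} with provenance
#'   \code{"filtered"}.
#' @param dialect \code{"gravity-included"} or \code{"gravity-excluded"}; if
#'   missing, taken from the signal's \code{"dialect"} attribute.
#' @return a \code{scalar_trace} with provenance \code{"dynamic"}.
#' @export
dynamic_component <- function(norm_signal, dialect = NULL) {
  stopifnot(inherits(norm_signal, "scalar_trace"))
  if (norm_signal$provenance != "filtered")
    stop_invalid("dynamic_component expects a filtered norm (got provenance '%s')",
                 norm_signal$provenance)
  if (is.null(dialect)) dialect <- attr(norm_signal, "dialect")
  if (is.null(dialect) ||
      !dialect %in% c("gravity-included", "gravity-excluded"))
    stop_invalid("unknown gravity dialect: %s",
                 if (is.null(dialect)) "<missing>" else dialect)
  v <- if (dialect == "gravity-included") norm_signal$values - G_ACCEL
       else norm_signal$values
  scalar_trace(v, norm_signal$sampling_rate, "dynamic")
}

#' Linear resampling onto a new uniform grid
#'
#' Linearly interpolates the signal onto a uniform grid at \code{target_rate}
#' spanning the same duration. Used to bring a high-rate reference recording
#' (e.g. 1000 Hz) and a 60 Hz smartphone recording to a common rate before
#' alignment and waveform comparison.
#'
#' @param signal a \code{\link{scalar_trace}} with at least 2 samples.
#' @param target_rate new sampling rate in Hz (> 0).
#' @return a \code{scalar_trace} at \code{target_rate}, same provenance.
#' @export
resample_linear <- function(signal, target_rate) {
  stopifnot(inherits(signal, "scalar_trace"))
  if (length(signal$values) < 2L) stop_invalid("need >= 2 samples to resample")
  if (!is.finite(target_rate) || target_rate <= 0)
    stop_invalid("target_rate must be positive")
  n <- length(signal$values)
  dur <- (n - 1) / signal$sampling_rate
  t_old <- (seq_len(n) - 1) / signal$sampling_rate
  m <- floor(dur * target_rate + 1e-9) + 1
  t_new <- (seq_len(m) - 1) / target_rate
  y <- stats::approx(t_old, signal$values, xout = pmin(t_new, dur))$y
  out <- scalar_trace(y, target_rate, signal$provenance)
  attr(out, "dialect") <- attr(signal, "dialect")
  out
}

#' Temporal alignment by normalized cross-correlation
#'
#' Finds the time lag of signal \code{b} relative to \code{a} that maximizes
#' the Pearson correlation over the overlapping segment, searching integer
#' sample lags within \code{max_lag} seconds and requiring at least 50%
#' overlap. A positive lag means \code{b} is delayed with respect to \code{a}
#' (i.e. \code{b[t] = a[t - lag]}). Ties are broken toward the smallest
#' absolute lag, then the smaller signed lag.
#'
#' @param a,b \code{\link{scalar_trace}}s at a common sampling rate (resample
#'   first if necessary).
#' @param max_lag half-width of the lag search window in seconds.
#' @return a list with elements \code{lag} (seconds), \code{lag_samples},
#'   and \code{correlation}.
#' @export
align_by_crosscorrelation <- function(a, b, max_lag = 2) {
  stopifnot(inherits(a, "scalar_trace"), inherits(b, "scalar_trace"))
  if (abs(a$sampling_rate - b$sampling_rate) > 1e-9)
    stop_invalid("signals must share a sampling rate (resample first): %g vs %g",
                 a$sampling_rate, b$sampling_rate)
  xa <- a$values; xb <- b$values
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0)
    stop_invalid("cannot align a zero-variance signal")
  rate <- a$sampling_rate
  n <- min(length(xa), length(xb))
  kmax <- min(round(max_lag * rate), floor(n / 2))  # >= 50% overlap
  lags <- seq.int(-kmax, kmax)
  cors <- vapply(lags, function(k) {
    if (k >= 0) {
      ia <- seq_len(n - k); ib <- ia + k
    } else {
      ib <- seq_len(n + k); ia <- ib - k
    }
    u <- xa[ia]; v <- xb[ib]
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(-Inf)
    stats::cor(u, v)
  }, numeric(1))
  best <- max(cors)
  cand <- lags[cors >= best - 1e-12]
  k <- cand[order(abs(cand), cand)][1]
  list(lag = k / rate, lag_samples = as.integer(k), correlation = best)
}

#' Extract the movement phase of a signal
#'
#' Returns the sub-signal from the standing onset through stabilization
#' (inclusive), the segment used for device-agreement waveform comparison.
#'
#' @param signal a \code{\link{scalar_trace}}.
#' @param features an \code{\link{sts_features}} object (or any list with
#'   \code{onset_index} and \code{stabilization_index}, 1-based).
#' @return a \code{scalar_trace} containing the movement-phase segment.
#' @export
extract_movement_phase <- function(signal, features) {
  stopifnot(inherits(signal, "scalar_trace"))
  i0 <- features$onset_index
  i1 <- features$stabilization_index
  n <- length(signal$values)
  if (is.null(i0) || is.null(i1) || !is.finite(i0) || !is.finite(i1) ||
      i0 < 1 || i1 > n || i0 > i1)
    stop_invalid("movement-phase indices [%s, %s] out of range for signal of length %d",
                 format(i0), format(i1), n)
  scalar_trace(signal$values[i0:i1], signal$sampling_rate, signal$provenance)
}
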