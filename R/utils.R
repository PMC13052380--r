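# Standard gravitational acceleration (m/s^2); the stabilization criterion is
# expressed as a fraction of this value.
G_ACCEL <- 9.80665

#' Round half away from zero
#'
#' Cohort tables conventionally report percentages rounded half-up to one
#' decimal; base \code{round()} rounds half-to-even, which disagrees at e.g.
#' 0.25. Only used for non-negative summary quantities.
#'
#' @param x numeric vector, non-negative.
#' @param digits decimal places to keep.
#' @return \code{x} rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Percentage of a count, rounded as in cohort tables
#'
#' @param num numerator count.
#' @param den denominator count (> 0).
#' @param digits decimal places (default 1).
#' @return percentage on the 0--100 scale.
#' @export
percent_of <- function(num, den, digits = 1) {
  stopifnot(all(den > 0))
  round_half_up(100 * num / den, digits)
}

# Deterministic child seed derived from a parent seed and an index, kept below
# 2^31 so it is a valid R integer seed.
child_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647)
  as.integer(((s * 48271) %% 2147483647 + as.numeric(k) * 9973) %% 2147483647)
}

# 3x3 rotation matrix from ZYX Euler angles (radians).
rotation_matrix <- function(yaw = 0, pitch = 0, roll = 0) {
  cz <- cos(yaw); sz <- sin(yaw)
  cy <- cos(pitch); sy <- sin(pitch)
  cx <- cos(roll); sx <- sin(roll)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

stop_invalid <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
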