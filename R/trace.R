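#' Triaxial acceleration trace
#'
#' Container for a uniformly sampled triaxial acceleration recording, the raw
#' input of the sit-to-stand pipeline. The \code{dialect} records whether the
#' sensor reports specific force including gravity (\code{"gravity-included"},
#' the usual accelerometer output) or linear acceleration with gravity removed
#' (\code{"gravity-excluded"}); downstream gravity handling differs between the
#' two (see \code{\link{dynamic_component}}).
#'
#' @param ax,ay,az numeric vectors of equal length (>= 2), accelerations in
#'   m/s^2 along the three device axes.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param dialect \code{"gravity-included"} or \code{"gravity-excluded"}.
#' @return an object of class \code{accel_trace}.
#' @export
accel_trace <- function(ax, ay, az,
                        sampling_rate = 60,
                        dialect = c("gravity-included", "gravity-excluded")) {
  dialect <- match.arg(dialect)
  ax <- as.numeric(ax); ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(ax)
  if (n < 2L || length(ay) != n || length(az) != n)
    stop_invalid("axis vectors must have equal length >= 2 (got %d, %d, %d)",
                 n, length(ay), length(az))
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az)))
    stop_invalid("acceleration values must all be finite")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop_invalid("sampling_rate must be a positive number")
  structure(list(ax = ax, ay = ay, az = az,
                 sampling_rate = as.numeric(sampling_rate),
                 dialect = dialect),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.2f s), %s\n",
              length(x$ax), x$sampling_rate,
              (length(x$ax) - 1) / x$sampling_rate, x$dialect))
  invisible(x)
}

#' @export
length.accel_trace <- function(x) length(x$ax)

#' Scalar-valued trace
#'
#' A single uniformly sampled scalar signal (e.g. the triaxial norm), with a
#' \code{provenance} tag tracking which pipeline stage produced it so that
#' stage preconditions can be enforced.
#'
#' @param values numeric vector of finite values.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param provenance one of \code{"raw-norm"}, \code{"filtered"},
#'   \code{"dynamic"}.
#' @return an object of class \code{scalar_trace}.
#' @export
scalar_trace <- function(values, sampling_rate,
                         provenance = c("raw-norm", "filtered", "dynamic")) {
  provenance <- match.arg(provenance)
  values <- as.numeric(values)
  if (length(values) < 1L) stop_invalid("empty signal")
  if (!all(is.finite(values))) stop_invalid("signal values must be finite")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop_invalid("sampling_rate must be a positive number")
  structure(list(values = values, sampling_rate = as.numeric(sampling_rate),
                 provenance = provenance),
            class = "scalar_trace")
}

#' @export
print.scalar_trace <- function(x, ...) {
  cat(sprintf("<scalar_trace:%s> %d samples @ %g Hz, range [%.3f, %.3f]\n",
              x$provenance, length(x$values), x$sampling_rate,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.scalar_trace <- function(x) length(x$values)

#' Write / read a trace as CSV plus JSON sidecar
#'
#' The CSV holds columns \code{sample_index, ax, ay, az}; the sidecar (same
#' path with extension \code{.json}) holds the sampling rate, dialect and,
#' optionally, generator ground-truth event metadata.
#'
#' @param trace an \code{\link{accel_trace}}.
#' @param file CSV path; the sidecar path is derived from it.
#' @param truth optional list of ground-truth metadata to store in the sidecar.
#' @return \code{write_trace} returns \code{file} invisibly; \code{read_trace}
#'   returns the \code{accel_trace} with any sidecar \code{truth} attached as
#'   an attribute.
#' @export
write_trace <- function(trace, file, truth = NULL) {
  stopifnot(inherits(trace, "accel_trace"))
  df <- data.frame(sample_index = seq_along(trace$ax) - 1L,
                   ax = trace$ax, ay = trace$ay, az = trace$az)
  utils::write.csv(df, file, row.names = FALSE)
  side <- list(sampling_rate = trace$sampling_rate, dialect = trace$dialect)
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, sidecar_path(file), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

sidecar_path <- function(file) {
  paste0(tools::file_path_sans_ext(file), ".json")
}

#' @rdname write_trace
#' @export
read_trace <- function(file) {
  df <- utils::read.csv(file)
  required <- c("sample_index", "ax", "ay", "az")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop_invalid("trace file %s is missing column(s): %s", file,
                 paste(missing_cols, collapse = ", "))
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad) > 0)
    stop_invalid("trace file %s has non-numeric or missing values at data row(s) %s",
                 file, paste(utils::head(bad, 5), collapse = ", "))
  side <- sidecar_path(file)
  if (!file.exists(side))
    stop_invalid("trace sidecar %s not found", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  tr <- accel_trace(df$ax, df$ay, df$az,
                    sampling_rate = meta$sampling_rate,
                    dialect = meta$dialect)
  if (!is.null(meta$truth)) attr(tr, "truth") <- meta$truth
  tr
}
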