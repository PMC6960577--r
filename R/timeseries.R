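#' Uniformly sampled time series
#'
#' Lightweight container for one modality trace: a numeric value vector
#' sampled uniformly at `fs` Hz starting at `t0` seconds. Values carry the
#' modality's native units (bpm for heart rate, microsiemens for skin
#' conductance, microvolts for EEG, unitless intensities for face traces).
#'
#' @param values numeric vector of samples; must be finite.
#' @param fs sampling rate in Hz; must be positive.
#' @param modality tag such as "hr", "gsr", "eeg" or "face".
#' @param t0 time of the first sample in seconds.
#' @return An object of class `time_series` with elements `values`, `fs`,
#'   `modality` and `t0`.
#' @export
time_series <- function(values, fs, modality = "signal", t0 = 0) {
  values <- as.numeric(values)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (length(values) == 0L)
    stop("`values` must be non-empty")
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  structure(
    list(values = values, fs = fs, modality = as.character(modality)[1L],
         t0 = as.numeric(t0)[1L]),
    class = "time_series"
  )
}

#' Sample timestamps of a time series
#'
#' @param ts a [time_series()].
#' @return numeric vector of timestamps in seconds, strictly increasing and
#'   uniform at `1/fs`.
#' @export
time_points <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  ts$t0 + (seq_along(ts$values) - 1L) / ts$fs
}

#' Duration spanned by a time series
#'
#' @param ts a [time_series()].
#' @return duration in seconds (`n / fs`).
#' @export
ts_duration <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  length(ts$values) / ts$fs
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s: %d samples @ %g Hz (%.1f s)\n",
              x$modality, length(x$values), x$fs, ts_duration(x)))
  invisible(x)
}

# replace the value vector, keeping sampling metadata
ts_replace <- function(ts, values) {
  ts$values <- as.numeric(values)
  ts
}
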