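#' Preprocessing configuration
#'
#' Controls the cleaning pipeline applied to every physiological trace
#' before feature extraction: detrend, abrupt-change (outlier) correction,
#' normalization, beta-band filtering of EEG, and windowing into
#' synchronized samples.
#'
#' @param window_length analysis window in seconds (default 10).
#' @param overlap window overlap fraction in `[0, 1)`.
#' @param detrend_method `"linear"` (least-squares line removed) or
#'   `"constant"` (mean removed).
#' @param abrupt_threshold robust z-score beyond which a sample counts as
#'   an abrupt change (default 5).
#' @param abrupt_window rolling-statistics window in seconds (default 1).
#' @param normalization `"minmax"` (to `[0, 1]`) or `"none"`.
#' @param eeg_band numeric length-2, EEG band edges in Hz (default 12--30,
#'   the beta rhythm).
#' @return A `preproc_config` list.
#' @export
preproc_config <- function(window_length = 10, overlap = 0,
                           detrend_method = "linear",
                           abrupt_threshold = 5, abrupt_window = 1,
                           normalization = "minmax",
                           eeg_band = c(12, 30)) {
  if (window_length <= 0) stop("`window_length` must be positive")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  if (abrupt_threshold <= 0) stop("`abrupt_threshold` must be positive")
  if (eeg_band[1] >= eeg_band[2]) stop("EEG band low edge must be < high edge")
  structure(list(window_length = window_length, overlap = overlap,
                 detrend_method = match.arg(detrend_method,
                                            c("linear", "constant")),
                 abrupt_threshold = abrupt_threshold,
                 abrupt_window = abrupt_window,
                 normalization = match.arg(normalization,
                                           c("minmax", "none")),
                 eeg_band = eeg_band),
            class = "preproc_config")
}

#' Remove a trend from a time series
#'
#' Least-squares linear detrending by default: the fitted line is
#' subtracted, so an exactly linear input maps to zero residual and the
#' output of any input has (numerically) zero mean.
#'
#' @param ts a [time_series()].
#' @param method `"linear"` or `"constant"` (mean removal).
#' @return a [time_series()] of the same length.
#' @export
detrend_series <- function(ts, method = "linear") {
  stopifnot(inherits(ts, "time_series"))
  method <- match.arg(method, c("linear", "constant"))
  v <- ts$values
  if (length(v) < 2L) stop("detrending needs at least 2 samples")
  if (method == "constant") return(ts_replace(ts, v - mean(v)))
  i <- seq_along(v)
  fit <- stats::lm.fit(cbind(1, i), v)
  ts_replace(ts, as.numeric(fit$residuals))
}

# Rolling median with odd width k. endrule "keep" leaves the half-window
# edge samples untouched, so edge samples are never flagged as outliers
# (their deviation from the "median" is zero by construction) -- a
# conservative edge policy that keeps the correction idempotent.
.roll_median <- function(v, k) {
  k <- max(3L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(v)) return(rep(stats::median(v), length(v)))
  as.numeric(stats::runmed(v, k, endrule = "keep"))
}

#' Correct abrupt changes (outlier samples) in a time series
#'
#' Samples whose robust z-score against a rolling median/MAD exceeds
#' `threshold` are replaced by the rolling median; all other samples pass
#' through bit-identical. The rolling MAD is floored at a tenth of the
#' series' global MAD (with a small absolute epsilon below that), so
#' locally smooth or constant stretches -- where the local MAD collapses
#' to zero -- never flag curvature as abrupt change. Samples within half a
#' rolling window of either end keep their original values.
#'
#' @param ts a [time_series()].
#' @param threshold robust z-score threshold (> 0), default 5.
#' @param window rolling window length in seconds, default 1.
#' @return a corrected [time_series()].
#' @export
correct_abrupt <- function(ts, threshold = 5, window = 1) {
  stopifnot(inherits(ts, "time_series"))
  if (threshold <= 0) stop("`threshold` must be positive")
  v <- ts$values
  if (!all(is.finite(v))) stop("non-finite values in input")
  k <- round(window * ts$fs)
  med <- .roll_median(v, k)
  dev <- abs(v - med)
  mad <- 1.4826 * .roll_median(dev, k)
  # floor the rolling MAD at a tenth of the global robust scale: a locally
  # collapsed MAD (smooth or constant stretches) must not flag smooth
  # curvature as abrupt
  eps <- max(0.1 * stats::mad(v), 1e-9 * max(1, max(abs(v))))
  z <- dev / pmax(mad, eps)
  out <- v
  bad <- z > threshold
  out[bad] <- med[bad]
  ts_replace(ts, out)
}

#' Normalize a time series
#'
#' Min-max normalization to `[0, 1]` by default (a monotone transform, so
#' rank order is preserved). A constant series maps to 0.5 everywhere by
#' convention.
#'
#' @param ts a [time_series()].
#' @param method `"minmax"` or `"none"`.
#' @return a normalized [time_series()].
#' @export
normalize_series <- function(ts, method = "minmax") {
  stopifnot(inherits(ts, "time_series"))
  method <- match.arg(method, c("minmax", "none"))
  if (method == "none") return(ts)
  v <- ts$values
  r <- range(v)
  if (r[1] == r[2]) return(ts_replace(ts, rep(0.5, length(v))))
  ts_replace(ts, (v - r[1]) / (r[2] - r[1]))
}

#' Zero-phase band-pass filter (EEG beta band by default)
#'
#' 4th-order Butterworth applied forward and backward
#' (`signal::filtfilt`), so the pass band is attenuated by less than 3 dB
#' and the phase is zero. Tones at least one octave outside the band are
#' attenuated by 20 dB or more.
#'
#' @param ts a [time_series()]; `fs` must exceed twice the high edge.
#' @param low,high band edges in Hz (default 12 and 30).
#' @return the filtered [time_series()].
#' @export
bandpass_beta <- function(ts, low = 12, high = 30) {
  stopifnot(inherits(ts, "time_series"))
  if (low >= high) stop("`low` must be < `high`")
  if (ts$fs <= 2 * high)
    stop("sampling rate must exceed twice the high band edge (Nyquist)")
  bf <- signal::butter(4, c(low, high) / (ts$fs / 2), type = "pass")
  ts_replace(ts, signal::filtfilt(bf, ts$values))
}

#' Clean one session's traces
#'
#' Applies the pipeline stage order detrend -> abrupt correction ->
#' normalize to HR, GSR and all EEG channels, then band-passes the EEG to
#' the configured band. Each stage preserves sample count. A copy of the
#' heart-rate trace after abrupt correction only (`hr_clean`, still in bpm)
#' is kept alongside, because the Poincare descriptors are defined on RR
#' intervals in physiological units.
#'
#' @param session a `flight_session`.
#' @param cfg a [preproc_config()].
#' @return the session with cleaned traces and an added `hr_clean` element.
#' @export
preprocess_session <- function(session, cfg = preproc_config()) {
  stopifnot(inherits(session, "flight_session"))
  clean <- function(ts) {
    ts <- detrend_series(ts, cfg$detrend_method)
    ts <- correct_abrupt(ts, cfg$abrupt_threshold, cfg$abrupt_window)
    normalize_series(ts, cfg$normalization)
  }
  session$hr_clean <- correct_abrupt(session$hr, cfg$abrupt_threshold,
                                     cfg$abrupt_window)
  session$hr <- clean(session$hr)
  session$gsr <- clean(session$gsr)
  session$eeg <- lapply(session$eeg, function(ts)
    bandpass_beta(clean(ts), cfg$eeg_band[1], cfg$eeg_band[2]))
  session$preprocessed <- TRUE
  session
}

#' Cut a session into synchronized windowed samples
#'
#' Windows start every `window_length * (1 - overlap)` seconds. Each
#' sample carries all modality windows cropped to the identical time
#' interval at their native rates, plus the regression target: the mean
#' face intensity of each emotion over the window.
#'
#' @param session a `flight_session` (typically after
#'   [preprocess_session()]).
#' @param cfg a [preproc_config()].
#' @return list of `windowed_sample` objects with fields `session_id`,
#'   `window`, `t_start`, `t_end`, `hr`, `hr_clean`, `gsr`, `eeg` (named
#'   list of 8 vectors) and `target` (length-5, in `[0, 1]`).
#' @export
windowize <- function(session, cfg = preproc_config()) {
  stopifnot(inherits(session, "flight_session"))
  duration <- ts_duration(session$hr)
  wl <- cfg$window_length
  if (wl > duration) stop("window longer than session")
  stride <- wl * (1 - cfg$overlap)
  starts <- seq(0, duration - wl, by = stride)
  crop <- function(ts, t0, t1) {
    i0 <- floor(t0 * ts$fs) + 1L
    i1 <- min(length(ts$values), floor(t1 * ts$fs))
    ts$values[i0:i1]
  }
  fs_face <- attr(session$face, "fs")
  hr_clean <- if (is.null(session$hr_clean)) session$hr else session$hr_clean
  lapply(seq_along(starts), function(w) {
    t0 <- starts[w]; t1 <- t0 + wl
    f0 <- floor(t0 * fs_face) + 1L
    f1 <- min(nrow(session$face), floor(t1 * fs_face))
    target <- colMeans(session$face[f0:f1, , drop = FALSE])
    structure(
      list(session_id = session$session_id, window = w,
           t_start = t0, t_end = t1,
           hr = crop(session$hr, t0, t1),
           hr_clean = crop(hr_clean, t0, t1),
           gsr = crop(session$gsr, t0, t1),
           eeg = lapply(session$eeg, crop, t0 = t0, t1 = t1),
           target = target),
      class = "windowed_sample"
    )
  })
}
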