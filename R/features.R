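#' @name features
#' @title Windowed feature extraction
#'
#' @description
#' Computes the per-window feature set: 11 heart-rate features (summary
#' statistics, differential entropy, range, RMS and the four Poincare
#' descriptors), 7 electrodermal features (statistics plus phasic peak
#' rate) and 9 features per EEG channel (statistics plus sym7 wavelet
#' coefficient means) over 8 channels -- 90 features in all-features mode.
NULL

#' Summary statistics of a window
#'
#' @param values non-empty numeric vector.
#' @return named vector `MN` (mean), `MD` (median), `STD` (population
#'   standard deviation), `VAR` (population variance, exactly `STD^2`),
#'   `RMS` (root mean square).
#' @export
basic_stats <- function(values) {
  if (length(values) == 0L) stop("empty window")
  m <- mean(values)
  v <- mean((values - m)^2)    # population variance
  c(MN = m, MD = stats::median(values), STD = sqrt(v), VAR = v,
    RMS = sqrt(mean(values^2)))
}

#' Differential entropy of a window (histogram plug-in)
#'
#' Plug-in estimate of the continuous (differential) entropy
#' h(X) = -Integral f log f, in nats, from a histogram with
#' Freedman-Diaconis bin widths. Degenerate (constant) input has no
#' density on the continuum; it returns the configured floor.
#'
#' @param values numeric vector, at least 10 samples.
#' @param floor value returned for (near-)constant input; default -20 nats.
#' @return entropy estimate in nats.
#' @export
differential_entropy <- function(values, floor = -20) {
  n <- length(values)
  if (n < 10L) stop("entropy estimator needs at least 10 samples")
  iqr <- stats::IQR(values)
  rng <- diff(range(values))
  if (rng == 0) return(floor)
  width <- 2 * iqr / n^(1 / 3)
  if (width <= 0) width <- rng / ceiling(sqrt(n))
  nbins <- max(1L, ceiling(rng / width))
  breaks <- seq(min(values), max(values), length.out = nbins + 1L)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins)
  w <- diff(breaks)[1]
  p <- counts[counts > 0] / n
  h <- -sum(p * log(p / w))
  max(h, floor)
}

#' Range of a window
#'
#' @param values numeric vector, at least 2 samples.
#' @param mode `"extrema"` (default): `max - min`; `"endpoints"`: absolute
#'   difference between the last and first sample of the window.
#' @return non-negative scalar.
#' @export
sample_range <- function(values, mode = c("extrema", "endpoints")) {
  if (length(values) < 2L) stop("range needs at least 2 samples")
  mode <- match.arg(mode)
  if (mode == "extrema") diff(range(values))
  else abs(values[length(values)] - values[1L])
}

# local maxima (strictly above both neighbours) with topographic prominence
.find_peaks <- function(v, prominence) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  cand <- which(v[2:(n - 1L)] > v[1:(n - 2L)] &
                v[2:(n - 1L)] > v[3:n]) + 1L
  keep <- vapply(cand, function(i) {
    left_min <- v[i]; j <- i
    while (j > 1L && v[j] <= v[i]) { j <- j - 1L; left_min <- min(left_min, v[j]) }
    if (v[j] <= v[i]) left_min <- min(v[seq_len(i)])
    right_min <- v[i]; j <- i
    while (j < n && v[j] <= v[i]) { j <- j + 1L; right_min <- min(right_min, v[j]) }
    if (v[j] <= v[i]) right_min <- min(v[i:n])
    v[i] - max(left_min, right_min) >= prominence
  }, logical(1))
  cand[keep]
}

#' Peak rate of a window
#'
#' Counts local maxima with topographic prominence at least `prominence`
#' and divides by the window duration, giving peaks per second -- the
#' electrodermal phasic-event rate feature.
#'
#' @param values numeric window.
#' @param fs sampling rate in Hz (> 0).
#' @param prominence minimum peak prominence, in the window's units (> 0).
#' @return peaks per second.
#' @export
count_peaks <- function(values, fs, prominence = 0.05) {
  if (fs <= 0) stop("`fs` must be positive")
  if (prominence <= 0) stop("`prominence` must be positive")
  length(.find_peaks(values, prominence)) / (length(values) / fs)
}

#' RR intervals from a heart-rate trace
#'
#' One interbeat interval per pulse-rate sample: `RR = 60000 / HR` ms.
#'
#' @param hr a [time_series()] in bpm, strictly positive.
#' @return numeric vector of RR intervals in milliseconds.
#' @export
rr_from_hr <- function(hr) {
  v <- if (inherits(hr, "time_series")) hr$values else as.numeric(hr)
  if (any(v <= 0)) stop("heart rate must be strictly positive (bpm)")
  60000 / v
}

#' Poincare plot descriptors of an RR series
#'
#' The Poincare plot scatters each interval against the next:
#' x_i = RR_i, y_i = RR_(i+1). Descriptors of the cloud: its centroid
#' norm ||C|| = sqrt(xc^2 + yc^2); the distances of each point to the
#' diagonal and anti-diagonal through the centroid,
#' d1_i = |(x_i - xc) - (y_i - yc)| / sqrt(2) and
#' d2_i = |(x_i - xc) + (y_i - yc)| / sqrt(2); the short- and long-axis
#' dispersions SD1 = sqrt(mean d1^2), SD2 = sqrt(mean d2^2) (mean, not
#' n - 1); and the ellipse area SA = pi * SD1 * SD2.
#'
#' @param rr numeric vector of RR intervals in ms, at least 3 values.
#' @return list of class `poincare_descriptors` with `sd1`, `sd2`,
#'   `centroid_norm` (all ms) and `ellipse_area` (ms^2).
#' @export
poincare_descriptors <- function(rr) {
  rr <- as.numeric(rr)
  if (length(rr) < 3L) stop("need at least 3 RR intervals (2 lag pairs)")
  n <- length(rr) - 1L
  x <- rr[seq_len(n)]
  y <- rr[seq_len(n) + 1L]
  xc <- mean(x); yc <- mean(y)
  d1 <- abs((x - xc) - (y - yc)) / sqrt(2)
  d2 <- abs((x - xc) + (y - yc)) / sqrt(2)
  sd1 <- sqrt(mean(d1^2))
  sd2 <- sqrt(mean(d2^2))
  structure(list(sd1 = sd1, sd2 = sd2,
                 centroid_norm = sqrt(xc^2 + yc^2),
                 ellipse_area = pi * sd1 * sd2),
            class = "poincare_descriptors")
}

#' @export
print.poincare_descriptors <- function(x, ...) {
  cat(sprintf("<poincare> SD1 %.2f ms, SD2 %.2f ms, ||C|| %.2f ms, area %.2f ms^2\n",
              x$sd1, x$sd2, x$centroid_norm, x$ellipse_area))
  invisible(x)
}

#' Heart-rate feature block (11 features)
#'
#' `MN, MD, STD, VAR, ENT, RNG, RMS` on the processed window plus the four
#' Poincare descriptors `SD1, SD2, SCT, SAR` computed from RR intervals of
#' the cleaned (physiological-unit) window.
#'
#' @param window processed HR window (normalized values).
#' @param window_clean HR window in bpm for the RR-based block; defaults
#'   to `window`.
#' @param fs sampling rate in Hz.
#' @return named numeric vector of length 11, names prefixed `hr_`.
#' @export
extract_hr_features <- function(window, window_clean = window, fs = 1) {
  st <- basic_stats(window)
  pc <- poincare_descriptors(rr_from_hr(window_clean))
  out <- c(st["MN"], st["MD"], st["STD"], st["VAR"],
           ENT = differential_entropy(window),
           RNG = sample_range(window), RMS = st[["RMS"]],
           SD1 = pc$sd1, SD2 = pc$sd2, SCT = pc$centroid_norm,
           SAR = pc$ellipse_area)
  names(out) <- paste0("hr_", c("MN", "MD", "STD", "VAR", "ENT", "RNG",
                                "RMS", "SD1", "SD2", "SCT", "SAR"))
  out
}

#' Electrodermal feature block (7 features)
#'
#' `MN, MD, STD, VAR, ENT, RNG` plus the phasic peak rate `PEK`
#' (peaks per second). RMS is the dropped eighth candidate; the stated
#' seven-feature electrodermal block governs the pipeline.
#'
#' @param window processed GSR window.
#' @param fs sampling rate in Hz.
#' @param prominence peak prominence threshold in window units.
#' @return named numeric vector of length 7, names prefixed `gsr_`.
#' @export
extract_gsr_features <- function(window, fs, prominence = 0.05) {
  st <- basic_stats(window)
  out <- c(st["MN"], st["MD"], st["STD"], st["VAR"],
           ENT = differential_entropy(window),
           RNG = sample_range(window),
           PEK = count_peaks(window, fs, prominence))
  names(out) <- paste0("gsr_", c("MN", "MD", "STD", "VAR", "ENT", "RNG",
                                 "PEK"))
  out
}

#' EEG feature block (9 features per channel, 72 in total)
#'
#' Per channel: `MN, MD, STD, VAR, ENT, RNG, RMS` plus the sym7 wavelet
#' approximation/detail coefficient means `WAC, WDC`.
#'
#' @param eeg_windows named list of 8 channel windows.
#' @param wavelet a [wavelet_config()].
#' @return named numeric vector of length 72, names
#'   `eeg_<channel>_<feature>`.
#' @export
extract_eeg_features <- function(eeg_windows, wavelet = wavelet_config()) {
  if (length(eeg_windows) != 8L) stop("expected 8 EEG channel windows")
  blocks <- lapply(names(eeg_windows), function(ch) {
    w <- eeg_windows[[ch]]
    st <- basic_stats(w)
    wf <- wavelet_features(w, wavelet)
    out <- c(st["MN"], st["MD"], st["STD"], st["VAR"],
             ENT = differential_entropy(w),
             RNG = sample_range(w), RMS = st[["RMS"]],
             WAC = wf[["WAC"]], WDC = wf[["WDC"]])
    names(out) <- paste0("eeg_", ch, "_",
                         c("MN", "MD", "STD", "VAR", "ENT", "RNG", "RMS",
                           "WAC", "WDC"))
    out
  })
  unlist(blocks)
}

#' All-features vector of one windowed sample
#'
#' Concatenates the HR (11), GSR (7) and EEG (72) blocks into the
#' 90-feature vector used in all-features mode, respecting the modality
#' mask.
#'
#' @param sample a `windowed_sample` from [windowize()].
#' @param wavelet a [wavelet_config()].
#' @param gsr_fs GSR sampling rate (Hz) used for the peak-rate feature.
#' @param modalities named logical vector switching blocks on/off.
#' @return named numeric feature vector.
#' @export
extract_all <- function(sample, wavelet = wavelet_config(), gsr_fs = 16,
                        modalities = c(hr = TRUE, gsr = TRUE, eeg = TRUE)) {
  stopifnot(inherits(sample, "windowed_sample"))
  out <- numeric(0)
  if (isTRUE(modalities[["hr"]])) {
    if (is.null(sample$hr)) stop("sample is missing modality: hr")
    dur <- sample$t_end - sample$t_start
    out <- c(out, extract_hr_features(sample$hr, sample$hr_clean,
                                      fs = length(sample$hr) / dur))
  }
  if (isTRUE(modalities[["gsr"]])) {
    if (is.null(sample$gsr)) stop("sample is missing modality: gsr")
    dur <- sample$t_end - sample$t_start
    out <- c(out, extract_gsr_features(sample$gsr,
                                       fs = length(sample$gsr) / dur))
  }
  if (isTRUE(modalities[["eeg"]])) {
    if (is.null(sample$eeg)) stop("sample is missing modality: eeg")
    out <- c(out, extract_eeg_features(sample$eeg, wavelet))
  }
  if (length(out) == 0L) stop("at least one modality must be enabled")
  out
}

#' Build the feature matrix of a set of windowed samples
#'
#' @param samples list of `windowed_sample` objects (possibly from several
#'   sessions).
#' @param wavelet a [wavelet_config()].
#' @param modalities named logical vector switching modality blocks.
#' @return a `feature_matrix`: list with `x` (n x p numeric matrix, named
#'   columns), `targets` (n x 5, columns [EMOTIONS]), `session_id`,
#'   `window`, `blocks` (named list of column indices per block) and
#'   `mode = "all"`.
#' @export
build_feature_matrix <- function(samples, wavelet = wavelet_config(),
                                 modalities = c(hr = TRUE, gsr = TRUE,
                                                eeg = TRUE)) {
  if (length(samples) == 0L) stop("no samples")
  rows <- lapply(samples, extract_all, wavelet = wavelet,
                 modalities = modalities)
  x <- do.call(rbind, rows)
  if (anyNA(x)) stop("NaN/NA produced in feature extraction")
  targets <- do.call(rbind, lapply(samples, `[[`, "target"))
  colnames(targets) <- EMOTIONS
  blocks <- .feature_blocks(colnames(x))
  structure(
    list(x = x, targets = targets,
         session_id = vapply(samples, `[[`, character(1), "session_id"),
         window = vapply(samples, `[[`, integer(1), "window"),
         blocks = blocks, mode = "all"),
    class = "feature_matrix"
  )
}

# group feature-matrix columns into modality blocks (one per EEG channel)
.feature_blocks <- function(cn) {
  blocks <- list()
  if (any(grepl("^hr_", cn))) blocks$hr <- which(grepl("^hr_", cn))
  if (any(grepl("^gsr_", cn))) blocks$gsr <- which(grepl("^gsr_", cn))
  for (ch in EEG_CHANNELS) {
    pat <- paste0("^eeg_", ch, "_")
    if (any(grepl(pat, cn))) blocks[[paste0("eeg_", ch)]] <- which(grepl(pat, cn))
  }
  blocks
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (%s mode), %d session(s)\n",
              nrow(x$x), ncol(x$x), x$mode, length(unique(x$session_id))))
  invisible(x)
}

# subset rows of a feature matrix
fm_rows <- function(fm, idx) {
  fm$x <- fm$x[idx, , drop = FALSE]
  fm$targets <- fm$targets[idx, , drop = FALSE]
  fm$session_id <- fm$session_id[idx]
  fm$window <- fm$window[idx]
  fm
}
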