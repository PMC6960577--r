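# Multilevel discrete wavelet transform (Mallat pyramid) with symmetric
# boundary extension. Conventions (extension length, convolution alignment,
# output length floor((n + L - 1) / 2)) follow the common DWT definition, so
# coefficients agree with independent implementations to rounding error.

# Symlet-7 decomposition filters (orthonormal; published constants).
.sym7_dec_lo <- c(
   0.002681814568257878, -0.0010473848886829163, -0.01263630340325193,
   0.03051551316596357,   0.0678926935013727,    -0.049552834937127255,
   0.017441255086855827,  0.5361019170917628,     0.767764317003164,
   0.2886296317515146,   -0.14004724044296152,   -0.10780823770381774,
   0.004010244871533663,  0.010268176708511255)

# quadrature mirror high-pass counterpart
.sym7_dec_hi <- c(
  -0.010268176708511255,  0.004010244871533663,  0.10780823770381774,
  -0.14004724044296152,  -0.2886296317515146,    0.767764317003164,
  -0.5361019170917628,    0.017441255086855827,  0.049552834937127255,
   0.0678926935013727,   -0.03051551316596357,  -0.01263630340325193,
   0.0010473848886829163, 0.002681814568257878)

#' Wavelet feature configuration
#'
#' @param wavelet mother wavelet name; only the symlet `"sym7"` is built in.
#' @param level decomposition level (default 4). At 500 Hz the level-4
#'   detail band is roughly 16--31 Hz, matching the beta rhythm.
#' @return a `wavelet_config` list.
#' @export
wavelet_config <- function(wavelet = "sym7", level = 4L) {
  wavelet <- match.arg(wavelet, "sym7")
  level <- as.integer(level)
  if (level < 1L) stop("`level` must be >= 1")
  structure(list(wavelet = wavelet, level = level), class = "wavelet_config")
}

# one analysis step: symmetric extension, convolve, downsample
.dwt_step <- function(x, filt) {
  n <- length(x); L <- length(filt)
  ext <- c(rev(x[seq_len(L - 1L)]), x, rev(x[seq(n - L + 2L, n)]))
  # direct convolution (C loop); y[i] = sum_j filt[j] ext[i-j+1], valid i >= L
  y <- stats::filter(ext, filt, method = "convolution", sides = 1L)
  as.numeric(y[seq(L + 1L, by = 2L, length.out = (n + L - 1L) %/% 2L)])
}

#' Multilevel discrete wavelet decomposition
#'
#' @param x numeric signal.
#' @param cfg a [wavelet_config()].
#' @return list with `approximation` (level-L approximation coefficients)
#'   and `details` (list of detail coefficient vectors, level 1 first).
#' @export
wavedec <- function(x, cfg = wavelet_config()) {
  L <- length(.sym7_dec_lo)
  min_len <- (L - 1L) * 2L^cfg$level
  if (length(x) < min_len)
    stop(sprintf("signal too short for level %d: need at least %d samples",
                 cfg$level, min_len))
  details <- vector("list", cfg$level)
  a <- as.numeric(x)
  for (lev in seq_len(cfg$level)) {
    details[[lev]] <- .dwt_step(a, .sym7_dec_hi)
    a <- .dwt_step(a, .sym7_dec_lo)
  }
  list(approximation = a, details = details)
}

#' Wavelet features of a window
#'
#' Mean of the deepest-level approximation coefficients (`FEAT_WAC`) and
#' mean of the deepest-level detail coefficients (`FEAT_WDC`) of a sym7
#' multilevel decomposition.
#'
#' @param values numeric window.
#' @param cfg a [wavelet_config()].
#' @return named numeric vector `c(WAC = ..., WDC = ...)`.
#' @export
wavelet_features <- function(values, cfg = wavelet_config()) {
  dec <- wavedec(values, cfg)
  c(WAC = mean(dec$approximation),
    WDC = mean(dec$details[[cfg$level]]))
}
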