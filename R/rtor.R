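#' Realtime Outliers Removal configuration
#'
#' @param batch_length number of trailing output samples kept in the
#'   rolling batch (N >= 3, default 20).
#' @param k robust z-score threshold (> 0, default 4).
#' @param mad_floor lower bound on the batch MAD, in the stream's units
#'   (default 0.1, sized for intensity outputs in `[0, 1]`). The floor
#'   keeps the filter aimed at genuinely abrupt output glitches: inside a
#'   flat stretch the MAD collapses towards zero and, unprotected, any
#'   legitimate movement of the emotion trace would be flagged.
#' @return a `rtor_config` list.
#' @export
rtor_config <- function(batch_length = 20L, k = 4, mad_floor = 0.1) {
  batch_length <- as.integer(batch_length)
  if (batch_length < 3L) stop("`batch_length` must be >= 3")
  if (k <= 0) stop("`k` must be positive")
  if (mad_floor < 0) stop("`mad_floor` must be >= 0")
  structure(list(batch_length = batch_length, k = k, mad_floor = mad_floor),
            class = "rtor_config")
}

#' Realtime Outliers Removal (RTOR)
#'
#' Causal correction of abrupt network outputs. Each of the five output
#' channels is processed independently: the rolling batch holds the last N
#' raw output samples, and a sample whose absolute deviation from the
#' batch median exceeds `k * max(MAD, mad_floor)` is replaced by that
#' median; everything else passes through bit-identical. The first N
#' samples are a warm-up and always pass through. Output at index t
#' depends only on inputs at indices <= t. Keeping the batch on the raw
#' (uncorrected) history lets the filter re-adapt after a genuine level
#' change instead of locking onto the pre-change level.
#'
#' @param stream numeric vector, or n x c matrix of multi-channel outputs.
#' @param cfg a [rtor_config()].
#' @return corrected stream of the same shape; attribute `warmup_only` is
#'   TRUE (with a warning) when the stream is no longer than the batch.
#' @export
rtor_filter <- function(stream, cfg = rtor_config()) {
  stopifnot(inherits(cfg, "rtor_config"))
  vec_in <- is.null(dim(stream))
  Y <- if (vec_in) matrix(stream, ncol = 1L) else as.matrix(stream)
  if (nrow(Y) == 0L) stop("empty stream")
  N <- cfg$batch_length
  if (nrow(Y) <= N) {
    warning("stream no longer than the batch; passed through unchanged")
    out <- if (vec_in) as.numeric(Y) else Y
    attr(out, "warmup_only") <- TRUE
    return(out)
  }
  for (ch in seq_len(ncol(Y))) {
    raw <- Y[, ch]
    v <- raw
    for (t in (N + 1L):length(v)) {
      batch <- raw[(t - N):(t - 1L)]
      med <- stats::median(batch)
      mad <- 1.4826 * stats::median(abs(batch - med))
      if (abs(raw[t] - med) > cfg$k * max(mad, cfg$mad_floor)) v[t] <- med
    }
    Y[, ch] <- v
  }
  if (vec_in) as.numeric(Y) else Y
}
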