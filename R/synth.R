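#' @name synth
#' @title Synthetic flight-session generator
#'
#' @description
#' Generates cohorts of simulated flight sessions with the statistical
#' structure the recognition pipeline assumes: a smooth latent 5-emotion
#' intensity process driven by the seven flight tasks, and physiological
#' modalities coupled to it -- heart-rate variability growing with arousal,
#' electrodermal phasic peaks firing at an arousal-dependent Poisson rate,
#' and per-channel EEG beta-band (12--30 Hz) power that is an affine
#' function of the latent intensities. The observed face trace is the
#' latent trace plus truncated Gaussian noise, clipped to [0, 1].
NULL

#' Emotion channel names, in fixed order
#'
#' The five facial-emotion intensities used throughout the package. Neutral
#' and disgust are deliberately absent. The order is load-bearing: argmax
#' tie-breaks, target columns and network outputs all follow it.
#' @export
EMOTIONS <- c("happy", "sad", "angry", "surprised", "scared")

#' Flight task names, in flight order
#' @export
FLIGHT_TASKS <- c("takeoff", "climbing", "cruise", "descent",
                  "approach", "final_approach", "landing")

# fraction of the session spent in each task
.task_fractions <- c(takeoff = 0.10, climbing = 0.20, cruise = 0.20,
                     descent = 0.10, approach = 0.10,
                     final_approach = 0.20, landing = 0.10)

# Per-task mean intensity of each emotion (rows = emotions, cols = tasks).
# Each task has one clearly dominant emotion, and the task durations are
# chosen so that every emotion dominates about one fifth of the session.
.default_task_means <- function() {
  m <- rbind(
    happy     = c(0.25, 0.60, 0.25, 0.20, 0.05, 0.05, 0.30),
    sad       = c(0.05, 0.05, 0.55, 0.10, 0.20, 0.10, 0.10),
    angry     = c(0.05, 0.10, 0.15, 0.10, 0.60, 0.10, 0.55),
    surprised = c(0.65, 0.25, 0.05, 0.60, 0.15, 0.30, 0.20),
    scared    = c(0.30, 0.10, 0.05, 0.25, 0.25, 0.65, 0.05)
  )
  colnames(m) <- FLIGHT_TASKS
  m
}

# Fixed full-rank loading of each EEG channel's beta power on the five
# latent intensities (rows = channels in montage order).
.eeg_loadings <- function() {
  w <- rbind(
    Fp1 = c(0.9, 0.1, 0.2, 0.4, 0.3),
    F3  = c(0.2, 0.8, 0.1, 0.3, 0.2),
    C3  = c(0.1, 0.2, 0.9, 0.2, 0.3),
    T7  = c(0.3, 0.2, 0.2, 0.8, 0.1),
    Fp2 = c(0.2, 0.3, 0.3, 0.1, 0.9),
    F4  = c(0.7, 0.4, 0.1, 0.6, 0.2),
    C4  = c(0.1, 0.6, 0.5, 0.2, 0.6),
    T8  = c(0.4, 0.1, 0.6, 0.5, 0.4)
  )
  colnames(w) <- EMOTIONS
  w
}

#' EEG channel labels (10-20 system montage)
#' @export
EEG_CHANNELS <- c("Fp1", "F3", "C3", "T7", "Fp2", "F4", "C4", "T8")

#' Build the seven-task flight schedule
#'
#' Splits a session of `duration` seconds into the seven flight tasks
#' (takeoff, climbing, cruise, descent, approach, final approach, landing)
#' using the package's default duration fractions. Segments are contiguous,
#' non-overlapping and cover the whole session.
#'
#' @param duration session length in seconds.
#' @return data.frame with columns `task`, `t_start`, `t_end`.
#' @export
default_schedule <- function(duration) {
  if (!is.finite(duration) || duration <= 0)
    stop("`duration` must be positive (seconds)")
  edges <- duration * cumsum(c(0, .task_fractions))
  data.frame(task = FLIGHT_TASKS,
             t_start = edges[-length(edges)],
             t_end = edges[-1],
             stringsAsFactors = FALSE)
}

validate_schedule <- function(schedule) {
  if (is.null(schedule) || nrow(schedule) == 0L)
    stop("schedule has no tasks")
  stopifnot(all(c("task", "t_start", "t_end") %in% names(schedule)))
  if (nrow(schedule) != 7L || !identical(schedule$task, FLIGHT_TASKS))
    stop("schedule must contain exactly the 7 flight tasks in order")
  if (any(schedule$t_end <= schedule$t_start))
    stop("each task must have t_end > t_start")
  if (any(abs(schedule$t_start[-1] - schedule$t_end[-nrow(schedule)]) > 1e-9))
    stop("task segments must be contiguous and non-overlapping")
  invisible(schedule)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults define the simulated study conditions: 13 flights, 600 s
#' sessions, device-style sampling rates (HR 1 Hz, GSR 16 Hz, EEG 500 Hz,
#' face video 30 Hz), and coupling gains strong enough that the latent
#' intensities are recoverable from the biosignals.
#'
#' @param n_flights number of sessions in the cohort (>= 2, LOOCV needs two
#'   folds); 13 by default.
#' @param session_duration session length in seconds.
#' @param fs named list of per-modality sampling rates in Hz.
#' @param task_emotion_means 5 x 7 matrix of per-task latent means
#'   (rows = emotions, columns = tasks), each entry in [0, 1].
#' @param hr_baseline mean heart rate in bpm.
#' @param hr_variability_gain extra beat-to-beat HR dispersion (bpm sd) per
#'   unit arousal, where arousal = scared + surprised.
#' @param gsr_peak_rate_gain extra electrodermal phasic events per second
#'   per unit arousal.
#' @param eeg_beta_power_gain extra beta-band power (uV^2) per unit latent
#'   loading.
#' @param noise named list of observation noise scales: `hr` (bpm sd floor),
#'   `gsr` (uS sd), `eeg` (broadband uV sd).
#' @param face_noise_sd sd of the truncated Gaussian noise added to the
#'   latent trace to form the observed face intensities.
#' @param ou_theta mean-reversion rate (1/s) of the latent
#'   Ornstein-Uhlenbeck process.
#' @param ou_sigma diffusion scale of the latent process (intensity units).
#' @param gsr_kernel_tau decay time constant (s) of the phasic response
#'   kernel.
#' @param rng_seed master seed; per-session seeds are derived from it by
#'   stable hashing of the session id.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_flights = 13L,
                         session_duration = 600,
                         fs = list(hr = 1, gsr = 16, eeg = 500, face = 30),
                         task_emotion_means = .default_task_means(),
                         hr_baseline = 72,
                         hr_variability_gain = 6,
                         gsr_peak_rate_gain = 0.5,
                         eeg_beta_power_gain = 12,
                         noise = list(hr = 0.4, gsr = 0.01, eeg = 3),
                         face_noise_sd = 0.02,
                         ou_theta = 0.5,
                         ou_sigma = 0.06,
                         gsr_kernel_tau = 2,
                         rng_seed = 1L) {
  if (n_flights < 2L) stop("`n_flights` must be >= 2 (LOOCV needs >= 2 folds)")
  if (session_duration <= 0) stop("`session_duration` must be positive")
  fs_v <- unlist(fs)
  if (any(fs_v <= 0)) stop("all sampling rates must be positive")
  if (hr_variability_gain < 0 || gsr_peak_rate_gain < 0 ||
      eeg_beta_power_gain < 0)
    stop("coupling gains must be >= 0")
  stopifnot(is.matrix(task_emotion_means),
            nrow(task_emotion_means) == 5L,
            ncol(task_emotion_means) == 7L,
            all(task_emotion_means >= 0 & task_emotion_means <= 1))
  structure(
    list(n_flights = as.integer(n_flights),
         session_duration = session_duration,
         fs = fs, task_emotion_means = task_emotion_means,
         hr_baseline = hr_baseline,
         hr_variability_gain = hr_variability_gain,
         gsr_peak_rate_gain = gsr_peak_rate_gain,
         eeg_beta_power_gain = eeg_beta_power_gain,
         noise = noise, face_noise_sd = face_noise_sd,
         ou_theta = ou_theta, ou_sigma = ou_sigma,
         gsr_kernel_tau = gsr_kernel_tau,
         rng_seed = as.integer(rng_seed)),
    class = "synth_config"
  )
}

# Stable, platform-independent string hash folded with the master seed,
# kept inside the 32-bit integer range.
session_seed <- function(master_seed, session_id) {
  bytes <- utf8ToInt(as.character(session_id))
  h <- as.numeric(master_seed) %% 2147483647
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# run code under a local RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Latent emotion-intensity process
#'
#' Simulates the hidden 5-channel emotion trace that drives a session: for
#' each emotion an Ornstein-Uhlenbeck process reverting towards the current
#' task's mean intensity, clipped to [0, 1]. The trace is sampled at the
#' face-video rate and is deterministic given `seed`.
#'
#' @param schedule a valid seven-task schedule, see [default_schedule()].
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @return matrix (time x 5) with columns named after [EMOTIONS]; attribute
#'   `fs` carries the sampling rate.
#' @export
latent_emotion_process <- function(schedule, cfg, seed) {
  validate_schedule(schedule)
  fs <- cfg$fs$face
  duration <- max(schedule$t_end)
  n <- max(2L, round(duration * fs))
  t <- (seq_len(n) - 1L) / fs
  task_idx <- findInterval(t, schedule$t_start)
  task_idx[task_idx < 1L] <- 1L
  means <- cfg$task_emotion_means[, task_idx, drop = FALSE] # 5 x n
  dt <- 1 / fs
  decay <- exp(-cfg$ou_theta * dt)
  # stationary per-step innovation sd of the discretised OU process
  innov_sd <- cfg$ou_sigma * sqrt((1 - decay^2) / (2 * cfg$ou_theta))
  lat <- with_seed(seed, {
    eps <- matrix(stats::rnorm(5L * n, sd = innov_sd), nrow = 5L)
    out <- matrix(0, nrow = 5L, ncol = n)
    out[, 1L] <- means[, 1L]
    for (i in seq_len(n - 1L)) {
      out[, i + 1L] <- means[, i + 1L] +
        (out[, i] - means[, i + 1L]) * decay + eps[, i + 1L]
    }
    out
  })
  lat <- pmin(pmax(lat, 0), 1)
  lat <- t(lat)
  colnames(lat) <- EMOTIONS
  attr(lat, "fs") <- fs
  lat
}

# hold-sample a latent matrix (at face fs) onto another modality's time grid
.latent_at <- function(latent, fs_from, n_to, fs_to) {
  idx <- pmin(nrow(latent), floor((seq_len(n_to) - 1L) / fs_to * fs_from) + 1L)
  latent[idx, , drop = FALSE]
}

#' Generate one synthetic flight session
#'
#' Draws the latent emotion trace for the session's schedule, then couples
#' each physiological modality to it: heart rate is a baseline plus slow
#' wander plus beat-to-beat jitter whose sd grows with arousal
#' (scared + surprised); skin conductance is a slow tonic drift plus
#' exponential-decay phasic peaks firing at an arousal-dependent Poisson
#' rate; each EEG channel is broadband Gaussian noise plus a 12--30 Hz
#' band-limited component whose power is an affine function of the latent
#' intensities; the observed face trace is the latent trace plus truncated
#' Gaussian noise, clipped to [0, 1].
#'
#' @param cfg a [synth_config()].
#' @param session_id session label, e.g. "RC1".
#' @param seed integer seed; defaults to a stable hash of
#'   `cfg$rng_seed` and `session_id`.
#' @return A `flight_session`: list with elements `session_id`, `hr`, `gsr`,
#'   `eeg` (named list of 8 [time_series()]), `face` (time x 5 intensity
#'   matrix with attribute `fs`), `schedule`, and `latent` (the hidden
#'   ground-truth trace).
#' @export
generate_session <- function(cfg, session_id,
                             seed = session_seed(cfg$rng_seed, session_id)) {
  if (cfg$session_duration <= 0) stop("non-positive session duration")
  schedule <- default_schedule(cfg$session_duration)
  latent <- latent_emotion_process(schedule, cfg, seed)
  arousal <- latent[, "scared"] + latent[, "surprised"]

  with_seed(seed + 1L, {
    ## heart rate (bpm) at fs$hr
    n_hr <- round(cfg$session_duration * cfg$fs$hr)
    lat_hr <- .latent_at(latent, cfg$fs$face, n_hr, cfg$fs$hr)
    arousal_hr <- lat_hr[, "scared"] + lat_hr[, "surprised"]
    wander <- stats::filter(stats::rnorm(n_hr, sd = 0.3), 0.98,
                            method = "recursive")
    jitter_sd <- cfg$noise$hr + cfg$hr_variability_gain * arousal_hr
    hr_vals <- cfg$hr_baseline + as.numeric(wander) +
      stats::rnorm(n_hr) * jitter_sd
    hr_vals <- pmax(hr_vals, 30)   # physiological floor, keeps RR finite
    hr <- time_series(hr_vals, cfg$fs$hr, "hr")

    ## skin conductance (uS) at fs$gsr
    n_gsr <- round(cfg$session_duration * cfg$fs$gsr)
    lat_gsr <- .latent_at(latent, cfg$fs$face, n_gsr, cfg$fs$gsr)
    arousal_gsr <- lat_gsr[, "scared"] + lat_gsr[, "surprised"]
    tonic <- 4 + as.numeric(stats::filter(stats::rnorm(n_gsr, sd = 0.01),
                                          0.999, method = "recursive"))
    rate <- (0.04 + cfg$gsr_peak_rate_gain * arousal_gsr) / cfg$fs$gsr
    events <- stats::rpois(n_gsr, lambda = rate)
    amps <- events * stats::rlnorm(n_gsr, meanlog = log(0.35), sdlog = 0.3)
    kern_len <- ceiling(cfg$gsr_kernel_tau * 5 * cfg$fs$gsr)
    kern <- exp(-(seq_len(kern_len) - 1L) / (cfg$gsr_kernel_tau * cfg$fs$gsr))
    phasic <- stats::convolve(amps, rev(kern), type = "open")[seq_len(n_gsr)]
    gsr_vals <- tonic + phasic + stats::rnorm(n_gsr, sd = cfg$noise$gsr)
    gsr <- time_series(pmax(gsr_vals, 0.05), cfg$fs$gsr, "gsr")

    ## EEG (uV), 8 channels at fs$eeg
    n_eeg <- round(cfg$session_duration * cfg$fs$eeg)
    lat_eeg <- .latent_at(latent, cfg$fs$face, n_eeg, cfg$fs$eeg)
    loadings <- .eeg_loadings()
    eeg <- vector("list", length(EEG_CHANNELS))
    names(eeg) <- EEG_CHANNELS
    for (ch in seq_along(EEG_CHANNELS)) {
      power <- 2 + cfg$eeg_beta_power_gain *
        as.numeric(lat_eeg %*% loadings[ch, ])      # uV^2, always > 0
      beta <- .band_limited_noise(n_eeg, cfg$fs$eeg, 12, 30)
      x <- sqrt(power) * beta + stats::rnorm(n_eeg, sd = cfg$noise$eeg)
      eeg[[ch]] <- time_series(x, cfg$fs$eeg, paste0("eeg:", EEG_CHANNELS[ch]))
    }

    ## observed face intensities at fs$face
    face <- latent + matrix(stats::rnorm(length(latent), sd = cfg$face_noise_sd),
                            nrow = nrow(latent))
    face <- pmin(pmax(face, 0), 1)
    colnames(face) <- EMOTIONS
    attr(face, "fs") <- cfg$fs$face

    structure(
      list(session_id = as.character(session_id), hr = hr, gsr = gsr,
           eeg = eeg, face = face, schedule = schedule, latent = latent),
      class = "flight_session"
    )
  })
}

# unit-variance noise band-limited to [low, high] Hz
.band_limited_noise <- function(n, fs, low, high) {
  w <- stats::rnorm(n)
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, w)
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

#' @export
print.flight_session <- function(x, ...) {
  cat(sprintf("<flight_session> %s: %.0f s | HR %g Hz, GSR %g Hz, EEG 8 ch @ %g Hz, face %g Hz\n",
              x$session_id, ts_duration(x$hr), x$hr$fs, x$gsr$fs,
              x$eeg[[1]]$fs, attr(x$face, "fs")))
  invisible(x)
}

#' Generate a synthetic flight cohort
#'
#' @param cfg a [synth_config()].
#' @param session_ids optional character vector of distinct session labels;
#'   defaults to the study-style labels `S01`, `S02`, ...
#' @return list of `flight_session` objects, one per flight, reproducible
#'   from `cfg$rng_seed`.
#' @export
generate_cohort <- function(cfg, session_ids = NULL) {
  if (cfg$n_flights < 2L) stop("need at least 2 flights")
  if (is.null(session_ids))
    session_ids <- sprintf("S%02d", seq_len(cfg$n_flights))
  if (anyDuplicated(session_ids))
    stop("duplicate session ids")
  if (length(session_ids) != cfg$n_flights)
    stop("`session_ids` must have length `n_flights`")
  cohort <- lapply(session_ids, function(id) generate_session(cfg, id))
  names(cohort) <- session_ids
  cohort
}
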