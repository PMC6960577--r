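# Small, fast generator settings for module tests: short sessions, EEG at
# 80 Hz (still well above the 2 x 30 Hz Nyquist bound of the beta band).
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_flights = 2L, session_duration = 60,
         fs = list(hr = 1, gsr = 16, eeg = 80, face = 30),
         rng_seed = 7L),
    list(...))
  do.call(synth_config, args)
}

# Shared fixtures for the heavier study-scale checks, built lazily once
# per test run and reused across test files.
.fixture_env <- new.env(parent = emptyenv())

study_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort(synth_config(rng_seed = 1L))
  .fixture_env$cohort
}

study_report <- function() {
  if (is.null(.fixture_env$report))
    .fixture_env$report <- run_test(test_spec_for(21), study_cohort(),
                                    seed = 1L)
  .fixture_env$report
}
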