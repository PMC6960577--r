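test_that("summary statistics match hand computations", {
  s <- basic_stats(c(3, 3, 3))
  expect_equal(unname(s[c("MN", "MD", "STD", "VAR", "RMS")]),
               c(3, 3, 0, 0, 3))
  s2 <- basic_stats(c(-1, 1))
  expect_equal(unname(s2[c("MN", "MD", "RMS")]), c(0, 0, 1))
  s3 <- basic_stats(c(1, 2, 3, 4))
  expect_equal(unname(s3[c("MN", "MD", "VAR")]), c(2.5, 2.5, 1.25))
  expect_equal(s3[["VAR"]], s3[["STD"]]^2, tolerance = 1e-12)
  expect_error(basic_stats(numeric(0)), "empty")
})

test_that("differential entropy matches closed forms and the scaling law", {
  set.seed(11)
  u <- runif(10000)
  expect_lt(abs(differential_entropy(u)), 0.05)          # h(U[0,1]) = 0
  g <- rnorm(10000)
  expect_equal(differential_entropy(g), 0.5 * log(2 * pi * exp(1)),
               tolerance = 0.05)                          # 1.4189 nats
  c_scale <- 3.7
  expect_equal(differential_entropy(c_scale * g) - differential_entropy(g),
               log(c_scale), tolerance = 0.05)
  expect_equal(differential_entropy(rep(1, 100)), -20)    # sentinel floor
  expect_error(differential_entropy(1:5), "at least 10")
})

test_that("sample range supports extrema and endpoint modes", {
  expect_equal(sample_range(c(1, 5, 2)), 4)
  expect_equal(sample_range(c(1, 5, 2), mode = "endpoints"), 1)
  expect_equal(sample_range(rep(2, 5)), 0)
  expect_equal(sample_range(rep(2, 5), mode = "endpoints"), 0)
  expect_error(sample_range(1), "at least 2")
})

test_that("peak counting is prominence-gated and rate-normalized", {
  expect_equal(count_peaks(seq(0, 1, length.out = 100), fs = 10), 0)
  # 5 phasic-style peaks in a 10 s window at 16 Hz
  v <- rep(0, 160)
  for (p in seq(10, 150, length.out = 5)) {
    i <- round(p)
    v[i:(i + 3)] <- v[i:(i + 3)] + c(1, 0.7, 0.4, 0.2)
  }
  expect_equal(count_peaks(v, fs = 16, prominence = 0.5), 0.5)
  # doubling the window at the same density leaves the rate unchanged
  expect_equal(count_peaks(c(v, v), fs = 16, prominence = 0.5), 0.5,
               tolerance = 0.1)
  expect_error(count_peaks(v, fs = 0), "positive")
  expect_error(count_peaks(v, fs = 16, prominence = 0), "positive")
})

test_that("sym7 decomposition reproduces an independent DWT implementation", {
  x <- sin(2 * pi * (0:63) / 16) + 0.5 * cos(2 * pi * (0:63) / 5)
  d1 <- wavedec(x, wavelet_config(level = 1))
  # frozen values from an independent discrete wavelet implementation
  expect_equal(d1$approximation[1:5],
               c(1.5170169771090183, 1.4756712356093953, 0.38395516637304467,
                 0.773775672649858, 0.672484786393116), tolerance = 1e-8)
  expect_equal(d1$details[[1]][1:5],
               c(-0.2533626849179085, 0.22555527872426692,
                 -0.028348350501669884, -0.15087234746578895,
                 0.12018913407739164), tolerance = 1e-8)
  expect_equal(length(d1$approximation), 38L)

  d2 <- wavedec(x, wavelet_config(level = 2))
  expect_equal(mean(d2$approximation), 0.0718016503249202, tolerance = 1e-8)
  expect_equal(mean(d2$details[[2]]), 0.036693449246024495, tolerance = 1e-8)

  y <- sin(2 * pi * (0:511) / 32) + 0.1 * cos(2 * pi * (0:511) / 7)
  wf <- wavelet_features(y, wavelet_config(level = 4))
  expect_equal(wf[["WAC"]], 0.032333903241469626, tolerance = 1e-8)
  expect_equal(wf[["WDC"]], 0.0019083777328990914, tolerance = 1e-8)
})

test_that("wavelet features handle degenerate inputs and short windows", {
  z <- wavelet_features(rep(0, 512))
  expect_equal(unname(z), c(0, 0))
  const <- wavelet_features(rep(2.5, 512))
  expect_lt(abs(const[["WDC"]]), 1e-8)
  expect_error(wavelet_features(rnorm(100), wavelet_config(level = 4)),
               "at least 208")
})

test_that("RR conversion inverts pulse rate", {
  expect_equal(rr_from_hr(time_series(60, fs = 1, "hr")), 1000)
  expect_equal(rr_from_hr(time_series(75, fs = 1, "hr")), 800)
  expect_equal(rr_from_hr(time_series(c(60, 120), fs = 1, "hr")),
               c(1000, 500))
  expect_error(rr_from_hr(c(60, -5)), "positive")
})

test_that("Poincare descriptors match hand-computed clouds", {
  p <- poincare_descriptors(c(800, 800, 800))
  expect_equal(p$sd1, 0)
  expect_equal(p$sd2, 0)
  expect_equal(p$ellipse_area, 0)
  expect_equal(p$centroid_norm, 800 * sqrt(2))

  # pairs (600,800) and (800,600); centroid (700,700)
  q <- poincare_descriptors(c(600, 800, 600))
  expect_equal(q$sd1, 200 / sqrt(2), tolerance = 1e-9)
  expect_equal(q$sd2, 0, tolerance = 1e-9)
  expect_equal(q$ellipse_area, 0, tolerance = 1e-9)

  expect_error(poincare_descriptors(c(800, 810)), "at least 3")
})

test_that("Poincare implementation agrees with a brute-force loop", {
  brute <- function(rr) {
    n <- length(rr) - 1
    xc <- 0; yc <- 0
    for (i in 1:n) { xc <- xc + rr[i] / n; yc <- yc + rr[i + 1] / n }
    s1 <- 0; s2 <- 0
    for (i in 1:n) {
      d1 <- abs((rr[i] - xc) - (rr[i + 1] - yc)) / sqrt(2)
      d2 <- abs((rr[i] - xc) + (rr[i + 1] - yc)) / sqrt(2)
      s1 <- s1 + d1^2 / n; s2 <- s2 + d2^2 / n
    }
    c(sqrt(s1), sqrt(s2), sqrt(xc^2 + yc^2), pi * sqrt(s1) * sqrt(s2))
  }
  set.seed(99)
  for (i in 1:100) {
    rr <- runif(sample(3:40, 1), 500, 1200)
    p <- poincare_descriptors(rr)
    expect_equal(c(p$sd1, p$sd2, p$centroid_norm, p$ellipse_area),
                 brute(rr), tolerance = 1e-9)
  }
  # identity: area == pi * SD1 * SD2
  rr <- runif(50, 600, 1100)
  p <- poincare_descriptors(rr)
  expect_equal(p$ellipse_area, pi * p$sd1 * p$sd2, tolerance = 1e-12)
})

test_that("feature blocks have the stated widths and stable names", {
  cfg <- small_cfg()
  s <- preprocess_session(generate_session(cfg, "F1"))
  w <- windowize(s)[[2]]
  hr <- extract_hr_features(w$hr, w$hr_clean, fs = 1)
  expect_length(hr, 11L)
  gsr <- extract_gsr_features(w$gsr, fs = 16)
  expect_length(gsr, 7L)
  eeg <- extract_eeg_features(w$eeg)
  expect_length(eeg, 72L)
  all_f <- extract_all(w)
  expect_length(all_f, 90L)
  expect_identical(names(all_f), c(names(hr), names(gsr), names(eeg)))
  # bit-identical re-extraction
  expect_identical(all_f, extract_all(w))
  expect_error(extract_all(structure(w[setdiff(names(w), "gsr")],
                                     class = "windowed_sample")),
               "gsr")
})

test_that("shift invariance holds where expected", {
  set.seed(5)
  v <- rnorm(64) + 10
  shifted <- v + 100
  s0 <- basic_stats(v); s1 <- basic_stats(shifted)
  expect_equal(s1[["STD"]], s0[["STD"]], tolerance = 1e-9)
  expect_equal(s1[["VAR"]], s0[["VAR"]], tolerance = 1e-9)
  expect_equal(sample_range(shifted), sample_range(v), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(s1[["MN"]], s0[["MN"]])))
  expect_false(isTRUE(all.equal(s1[["RMS"]], s0[["RMS"]])))
  rr <- runif(30, 600, 1000)
  p0 <- poincare_descriptors(rr); p1 <- poincare_descriptors(rr + 50)
  expect_equal(p1$sd1, p0$sd1, tolerance = 1e-9)
  expect_equal(p1$sd2, p0$sd2, tolerance = 1e-9)
})
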