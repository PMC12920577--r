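test_that("R-peak detection recovers generator truth on clean recordings", {
  hits <- total <- dets <- truepos <- 0
  for (seed in 1:20) {
    cfg <- sim_config(fs = 125, duration = 30, n_leads = 1, mean_hr = 70,
                      hr_jitter_sd = 0.02,
                      class_probs = c(N = 0.7, S = 0.1, V = 0.1, E = 0.1),
                      noise = list(baseline_amp = 0, baseline_freq = 0.3,
                                   white_sd = 0, powerline_amp = 0,
                                   powerline_freq = 50),
                      seed = seed)
    sim <- synth_recording(cfg)
    rec <- bandpass_filter(sim$recording, filter_spec(fs = 125))
    pk <- detect_r_peaks(rec$signal[, 1], 125)
    tol <- round(0.05 * 125)
    truth <- sim$annotations$sample
    hits <- hits + sum(vapply(truth, function(s) any(abs(pk - s) <= tol), TRUE))
    total <- total + length(truth)
    truepos <- truepos + sum(vapply(pk, function(s) any(abs(truth - s) <= tol),
                                    TRUE))
    dets <- dets + length(pk)
  }
  expect_gte(hits / total, 0.95)     # recall
  expect_gte(truepos / dets, 0.95)   # precision
})

test_that("R-peak detector is scale invariant and silent on flat input", {
  cfg <- sim_config(fs = 125, duration = 20, n_leads = 1, seed = 5)
  sim <- synth_recording(cfg)
  x <- bandpass_filter(sim$recording, filter_spec(fs = 125))$signal[, 1]
  p1 <- detect_r_peaks(x, 125)
  p5 <- detect_r_peaks(5 * x, 125)
  expect_identical(as.integer(p1), as.integer(p5))
  expect_length(detect_r_peaks(rep(0, 5000), 125), 0)
})

test_that("time-domain features evaluate the RR definition", {
  fs <- 1000
  tf <- time_features(c(1.0, 1.8, 2.6) * fs, fs)
  expect_equal(tf$rr, c(0.8, 0.8))
  expect_equal(tf$mean_rr, 0.8)
  expect_equal(tf$mean_hr, 75)
  expect_equal(tf$sdnn, 0)
  expect_equal(60 / tf$mean_rr, tf$mean_hr, tolerance = 1e-9)

  tf2 <- time_features(c(1000, 2000), 1000)
  expect_equal(tf2$rr, 1.0)
  expect_equal(tf2$mean_hr, 60)

  tf1 <- time_features(c(500), 1000)
  expect_equal(tf1$n_beats, 1)
  expect_true(is.na(tf1$mean_rr))
})

test_that("periodogram locates tones and satisfies Parseval", {
  fs <- 100
  t <- (0:999) / fs
  x <- sin(2 * pi * 5 * t)
  psd <- power_spectrum(x, fs)
  ff <- band_powers(psd, wide_bands())
  expect_equal(ff$dominant_freq, 5)

  # Parseval: sum(power) * df = mean square, deterministic input
  expect_equal(sum(psd$power) * fs / length(x), mean(x^2), tolerance = 1e-6)

  # white noise: integral approximates the variance
  set.seed(8)
  w <- stats::rnorm(4096)
  pw <- power_spectrum(w, fs)
  expect_lt(abs(sum(pw$power) * fs / length(w) - mean(w^2)) / mean(w^2), 1e-9)
  expect_lt(abs(sum(pw$power) * fs / length(w) - stats::var(w)) / stats::var(w),
            0.05)

  # constant signal: all power at DC
  pc <- power_spectrum(rep(2, 64), fs)
  expect_gt(pc$power[1], 0)
  expect_lt(max(pc$power[-1]), 1e-9)
})

test_that("band powers integrate rectangles exactly", {
  freq <- seq(0, 0.5, by = 0.001)
  power <- ifelse(freq >= 0.04 & freq < 0.15, 1, 0)
  psd <- structure(list(freq = freq, power = power), class = "psd_curve")
  bp <- band_powers(psd, hrv_bands())
  expect_equal(bp$lf_power, 0.11, tolerance = 1e-9)
  expect_equal(bp$hf_power, 0, tolerance = 1e-12)

  zero <- structure(list(freq = freq, power = power * 0), class = "psd_curve")
  bz <- band_powers(zero, hrv_bands())
  expect_equal(bz$vlf_power + bz$lf_power + bz$hf_power, 0)
  expect_true(is.na(bz$lf_hf_ratio))

  eq <- structure(list(freq = freq, power = rep(1, length(freq))),
                  class = "psd_curve")
  # LF band is 0.11 wide, HF 0.25 wide; equal heights -> ratio = width ratio
  expect_equal(band_powers(eq, hrv_bands())$lf_hf_ratio, 0.11 / 0.25,
               tolerance = 1e-9)

  expect_error(band_powers(psd, list(vlf = c(0.003, 0.04), lf = c(0.04, 0.15),
                                     hf = c(0.15, 0.9))), "outside")
})

test_that("ApEn equals the brute-force oracle and ranks regularity", {
  expect_equal(approximate_entropy(rep(1, 50)), 0, tolerance = 1e-9)

  set.seed(17)
  for (i in 1:20) {
    n <- sample(30:200, 1)
    x <- stats::rnorm(n)
    r <- 0.2 * stats::sd(x)
    expect_equal(approximate_entropy(x, m = 2, r = r),
                 apen_oracle(x, 2, r), tolerance = 1e-12)
  }

  wins <- 0
  for (seed in 1:20) {
    set.seed(seed)
    noise <- stats::rnorm(1000)
    t <- (0:999) / 100
    sine <- sin(2 * pi * 1 * t)
    a_n <- approximate_entropy(noise, 2, 0.2 * stats::sd(noise))
    a_s <- approximate_entropy(sine, 2, 0.2 * stats::sd(sine))
    wins <- wins + (a_n > a_s)
  }
  expect_gte(wins, 19)
})

test_that("Poincare descriptors match the rotated-cloud oracle", {
  pc0 <- poincare(rep(0.8, 10))
  expect_equal(pc0$sd1, 0); expect_equal(pc0$sd2, 0)

  rot_oracle <- function(rr) {
    x <- rr[-length(rr)]; y <- rr[-1]
    u <- (x + y) / sqrt(2); v <- (x - y) / sqrt(2)
    sdp <- function(z) sqrt(mean((z - mean(z))^2))
    list(sd1 = sdp(v), sd2 = sdp(u))
  }
  for (rr in list(c(0.7, 0.9, 0.7, 0.9),
                  stats::runif(20, 0.6, 1.1),
                  c(0.8, 0.82, 0.78, 0.85, 0.8))) {
    pc <- poincare(rr)
    or <- rot_oracle(rr)
    expect_equal(pc$sd1, or$sd1, tolerance = 1e-9)
    expect_equal(pc$sd2, or$sd2, tolerance = 1e-9)
  }

  rr <- stats::runif(15, 0.7, 1.0)
  expect_equal(poincare(rr), poincare(rr + 0.1), tolerance = 1e-12)
})

test_that("feature tensors have the documented shape and symmetries", {
  cfg <- sim_config(fs = 125, duration = 60, n_leads = 2, seed = 9,
                    class_probs = c(N = 0.8, S = 0.06, V = 0.08, E = 0.06),
                    lead_gain = c(1, 1),
                    noise = list(baseline_amp = 0, baseline_freq = 0.3,
                                 white_sd = 0, powerline_amp = 0,
                                 powerline_freq = 50))
  sim <- synth_recording(cfg)
  filt <- bandpass_filter(sim$recording, filter_spec(fs = 125))
  segs <- segment_signal(filt, segmentation_spec(10, 0.5, 125))
  segs <- encode_and_label(segs, sim$annotations)
  ft <- extract_feature_tensor(segs, T = 5)
  d <- dim(ft$x)
  expect_equal(d[2], 5L)
  expect_equal(d[3], 2L)
  expect_equal(d[4], 28L)
  expect_equal(d[1], length(ft$labels))

  # identical leads (equal gain, no noise) give identical features
  expect_equal(max(abs(ft$x[, , 1, ] - ft$x[, , 2, ])), 0, tolerance = 1e-9)

  # deterministic: re-extraction is bitwise identical
  ft2 <- extract_feature_tensor(segs, T = 5)
  expect_identical(ft$x, ft2$x)

  # too many sub-windows is an error
  expect_error(extract_feature_tensor(segs, T = 1e5), "sub-windows")
})
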