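make_fm <- function(values) {
  # minimal feature_matrix scaffold with controlled columns
  n <- nrow(values)
  fm <- data.frame(frame_index = seq_len(n) + 2, time_s = (seq_len(n) + 1) / 30,
                   values)
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

test_that("literal selection takes the column with the largest mean, ties to fixed order", {
  vals <- matrix(runif(10 * 14), 10, 14, dimnames = list(NULL, FEATURE_NAMES))
  vals[, "chi_square"] <- 1000
  sel <- select_feature(make_fm(vals))
  expect_equal(sel$feature_name, "chi_square")
  expect_equal(sel$series, vals[, "chi_square"], ignore_attr = TRUE)

  tie <- matrix(0, 5, 14, dimnames = list(NULL, FEATURE_NAMES))
  tie[, "median"] <- 7; tie[, "ks"] <- 7
  sel2 <- select_feature(make_fm(tie))
  expect_equal(sel2$feature_name, "median")  # first in fixed order wins
})

test_that("selected series from a pulsatile clip oscillates at the truth frequency", {
  b <- make_pulse_bundle(bpm = 72, duration = 10, noise_sigma = 1,
                         frame_size = 64)
  pre <- preprocess_sequence(read_frames(b), preprocess_config(target_size = 64))
  sm <- sample_pixels(pre, max_pixels = 1024, seed = 1)
  fm <- compute_feature_matrix(sm, pre$timestamps)
  sel <- select_feature(fm)
  expect_lt(abs(fft_peak_hz(sel$series, 30) - 72 / 60), 0.1)
})

test_that("peak detection matches cycle-count and enumeration oracles", {
  t <- (0:299) / 30
  s <- sin(2 * pi * 1.2 * t)
  pk <- detect_peaks(s, t)
  expect_equal(length(pk$peak_times), 12)  # 1.2 Hz x 10 s

  expect_length(detect_peaks(rep(1, 100), (0:99) / 30)$peak_times, 0)

  pk2 <- detect_peaks(c(1, 5, 3, 7, 2), 0:4)
  expect_equal(pk2$peak_values, c(5, 7))
  expect_equal(pk2$M, 6)

  # flat-topped peaks from quantized data count once
  pk3 <- detect_peaks(c(0, 2, 2, 0, 1, 3, 0), 0:6)
  expect_equal(pk3$peak_values, c(2, 3))
})

test_that("peak spacing respects the physiological bound", {
  t <- (0:299) / 30
  s <- sin(2 * pi * 5 * t)  # 300 bpm: above max_bpm, peaks 0.2 s apart
  pk <- detect_peaks(s, t, max_bpm = 220)
  expect_true(all(diff(pk$peak_times) >= 60 / 220 - 1e-12))
})

test_that("series conditioning suppresses sub-midrange bumps without moving beat peaks", {
  t <- (0:299) / 30
  clean <- sin(2 * pi * 1.2 * t)
  # inject a small bump deep in each trough
  bumpy <- clean + 0.15 * pmax(0, sin(2 * pi * 1.2 * t + pi))^20
  raw <- detect_peaks(bumpy, t)
  screened <- detect_peaks(bumpy, t, min_height_frac = 0.5)
  expect_gt(length(raw$peak_times), 12)
  expect_equal(length(screened$peak_times), 12)
  # smoothing leaves the noiseless peak count unchanged
  sm <- detect_peaks(clean, t, smooth_window = 5)
  expect_equal(length(sm$peak_times), 12)
  expect_error(detect_peaks(clean, t, smooth_window = 4),
               class = "pulsebeat_config_error")
  expect_error(detect_peaks(clean, t, min_height_frac = 1),
               class = "pulsebeat_config_error")
})

test_that("running-mode estimation averages instantaneous rates", {
  mk <- function(times) {
    structure(list(feature_name = "mean", peak_times = times,
                   peak_values = rep(1, length(times)), M = 1,
                   series = NULL, times = NULL), class = "peak_set")
  }
  expect_equal(estimate_rate(mk(0:9))$bpm, 60)
  expect_equal(estimate_rate(mk(seq(0, 6.75, by = 0.75)))$bpm, 80)
  # uniform time-shift invariance
  expect_equal(estimate_rate(mk(0:9 + 123.4))$pre_round,
               estimate_rate(mk(0:9))$pre_round)
  # halving intervals doubles the pre-ceil estimate exactly
  tms <- cumsum(c(0, runif(8, 0.5, 1.2)))
  expect_equal(estimate_rate(mk(tms / 2))$pre_round,
               2 * estimate_rate(mk(tms))$pre_round)
  # ceil contract
  e <- estimate_rate(mk(cumsum(c(0, runif(5, 0.6, 1.1)))))
  expect_true(e$bpm - 1 < e$pre_round && e$pre_round <= e$bpm)
  expect_error(estimate_rate(mk(c(1, 1, 2))), class = "pulsebeat_input_error")
})

test_that("zero or one peak falls back to the 60 bpm initial rate in every mode", {
  empty <- detect_peaks(rep(0, 10), (0:9) / 30)
  one <- detect_peaks(c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0), (0:9) / 30)
  for (m in c("running", "top2", "literal")) {
    for (pk in list(empty, one)) {
      est <- estimate_rate(pk, mode = m)
      expect_equal(est$bpm, 60L)
      expect_equal(est$n_peaks_used, 0L)
    }
  }
})

test_that("top2 mode uses the gap between the two largest peaks", {
  pk <- detect_peaks(c(0, 9, 0, 0, 0, 0, 10, 0, 2, 0), 0:9 / 2)
  # largest peaks at t = 0.5 and t = 3.0 -> dt = 2.5 s -> 24 bpm
  expect_equal(estimate_rate(pk, mode = "top2")$bpm, 24L)
})

test_that("literal mode executes the published recurrence and is flagged", {
  pk <- detect_peaks(c(0, 1, 0, 1, 0, 1, 0), (0:6))
  est <- estimate_rate(pk, mode = "literal")
  # recurrence reduces to h / ((t - t_p) * 60) per event, ceiled:
  # h = 60 -> ceil(60/60) = 1 (t=1,dt=1) -> ceil(1/120) = 1 -> 1
  expect_equal(est$bpm, 1L)
  expect_true("non_physiological" %in% est$warnings)
})

test_that("rates classify against the 60/100 normal range", {
  expect_equal(classify_rate(59), "low")
  expect_equal(classify_rate(72), "normal")
  expect_equal(classify_rate(101), "high")
  expect_equal(classify_rate(60), "normal")
  expect_equal(classify_rate(100), "normal")
})
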