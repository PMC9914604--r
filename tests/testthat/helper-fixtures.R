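# Shared fixture builders. Everything is generated in code; nothing is
# stored on disk beyond the two transcribed result tables in extdata.

# A tiny deterministic RGB frame sequence with constant frames.
make_constant_sequence <- function(n = 5, size = 32, value = c(120, 110, 100),
                                   fps = 30) {
  frames <- lapply(seq_len(n), function(i) {
    array(rep(value, each = size * size), dim = c(size, size, 3))
  })
  frame_sequence(frames, fps = fps)
}

# Small pulsatile bundle used by several modules.
make_pulse_bundle <- function(bpm = 72, duration = 4, noise_sigma = 0,
                              seed = 1, frame_size = 64, ...) {
  generate_video(synth_spec(bpm = bpm, fps = 30, duration = duration,
                            frame_size = frame_size,
                            noise_sigma = noise_sigma, seed = seed, ...))
}

# Brute-force Jonckheere-Terpstra statistic by exhaustive pair enumeration.
jonckheere_brute <- function(groups) {
  k <- length(groups)
  J <- 0
  for (g in seq_len(k - 1)) for (h in seq(g + 1, k)) {
    for (x in groups[[g]]) for (y in groups[[h]]) {
      J <- J + (x < y) + 0.5 * (x == y)
    }
  }
  J
}

# Dominant frequency (Hz) of a series by FFT argmax over positive bins.
fft_peak_hz <- function(series, fps) {
  n <- length(series)
  sp <- Mod(stats::fft(series - mean(series)))[2:floor(n / 2)]
  which.max(sp) / (n / fps)
}

table3_pairs <- function() read_rate_pairs(evaluation_table_path("table3"))
table4_pairs <- function() read_rate_pairs(evaluation_table_path("table4"))
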