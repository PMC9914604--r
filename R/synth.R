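# Synthetic pulsatile video and signal generation with known ground truth.
#
# No public dataset accompanies the method this package implements, so the
# generator below stands in for real skin video: an elliptical "skin" patch
# whose mean intensity oscillates sinusoidally at a set heart rate, over a
# darker static background, with optional Gaussian pixel noise, linear
# illumination drift, and integer ROI jitter. Truth metadata (bpm, per-frame
# ellipse geometry, seed) is recorded so detectors and the full pipeline can
# be scored.

#' Specify a synthetic pulsatile video
#'
#' @param bpm ground-truth heart rate in beats per minute (40--220).
#' @param fps frame rate, frames per second.
#' @param duration clip length in seconds.
#' @param frame_size side of the square frame in pixels.
#' @param roi_center ellipse center `c(x, y)` in pixels (1-based, column x /
#'   row y); default frame center.
#' @param roi_axes ellipse semi-axes `c(ax, ay)` in pixels; default
#'   `(0.32, 0.24) * frame_size`, a face-like patch filling about a quarter
#'   of the frame.
#' @param base_rgb skin-tone RGB triple; the default (200, 160, 140) sits in
#'   the YCbCr chroma band classic skin detectors accept.
#' @param pulse_amplitude peak intensity swing of the pulse, in 0--255 units.
#'   Real rPPG intensity swings are on the order of 1 unit; the default 4
#'   keeps the signal visible at 8-bit quantization.
#' @param noise_sigma standard deviation of per-pixel Gaussian noise.
#' @param drift_per_s linear illumination drift, intensity units per second.
#' @param jitter_px maximum per-frame integer jitter of the ellipse center.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(bpm, fps = 30, duration = 10, frame_size = 128,
                       roi_center = NULL, roi_axes = NULL,
                       base_rgb = c(200, 160, 140), pulse_amplitude = 4,
                       noise_sigma = 2, drift_per_s = 0, jitter_px = 0,
                       seed = 1) {
  if (!is.numeric(bpm) || bpm < 40 || bpm > 220) {
    stop_config("'bpm' must lie in [40, 220]")
  }
  if (fps <= 0 || duration <= 0) stop_config("'fps' and 'duration' must be positive")
  if (pulse_amplitude < 0) stop_config("'pulse_amplitude' must be non-negative")
  if (noise_sigma < 0) stop_config("'noise_sigma' must be non-negative")
  if (!is_count(jitter_px) || jitter_px < 0) stop_config("'jitter_px' must be a non-negative integer")
  if (is.null(roi_center)) roi_center <- c(frame_size, frame_size) / 2
  if (is.null(roi_axes)) roi_axes <- round(c(0.32, 0.24) * frame_size)
  lo <- roi_center - roi_axes - jitter_px
  hi <- roi_center + roi_axes + jitter_px
  if (any(lo < 1) || any(hi > frame_size)) {
    stop_config("ellipse must fit inside the frame at maximum jitter")
  }
  structure(
    list(bpm = bpm, fps = fps, duration = duration, frame_size = frame_size,
         roi_center = roi_center, roi_axes = roi_axes, base_rgb = base_rgb,
         pulse_amplitude = pulse_amplitude, noise_sigma = noise_sigma,
         drift_per_s = drift_per_s, jitter_px = jitter_px,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Generate a synthetic pulsatile video bundle
#'
#' Pixels inside the (possibly jittered) ellipse take, per channel,
#' `base + A * sin(2 * pi * (bpm / 60) * t) + drift * t + N(0, sigma)`;
#' background pixels take `64 + N(0, sigma)`. Values are rounded half-up and
#' clipped to 0--255. The returned bundle is accepted directly by
#' [read_frames()] and can be written to a PNG directory with
#' [write_frames()].
#'
#' @param spec a [synth_spec].
#' @return A `frame_bundle`: list with `frames` (list of `H x W x 3` integer
#'   arrays), `fps`, and `meta` holding truth (`bpm`, `seed`, per-frame
#'   ellipse centers, axes).
#' @export
generate_video <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- round(spec$fps * spec$duration)
  s <- spec$frame_size
  tt <- (seq_len(n) - 1) / spec$fps
  coords_x <- matrix(rep(seq_len(s), each = s), nrow = s)   # column index
  coords_y <- matrix(rep(seq_len(s), times = s), nrow = s)  # row index
  frames <- vector("list", n)
  centers <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  with_seed(spec$seed, {
    for (i in seq_len(n)) {
      off <- if (spec$jitter_px > 0) {
        sample(seq(-spec$jitter_px, spec$jitter_px), 2, replace = TRUE)
      } else c(0L, 0L)
      cx <- spec$roi_center[1] + off[1]
      cy <- spec$roi_center[2] + off[2]
      centers[i, ] <- c(cx, cy)
      mask <- ((coords_x - cx) / spec$roi_axes[1])^2 +
        ((coords_y - cy) / spec$roi_axes[2])^2 <= 1
      pulse <- spec$pulse_amplitude * sin(2 * pi * (spec$bpm / 60) * tt[i]) +
        spec$drift_per_s * tt[i]
      fr <- array(0, dim = c(s, s, 3))
      for (ch in 1:3) {
        plane <- matrix(64, s, s)
        plane[mask] <- spec$base_rgb[ch] + pulse
        if (spec$noise_sigma > 0) {
          plane <- plane + matrix(stats::rnorm(s * s, 0, spec$noise_sigma), s, s)
        }
        fr[, , ch] <- plane
      }
      fr <- clip8(round_half_up(fr))
      storage.mode(fr) <- "integer"
      frames[[i]] <- fr
    }
  })
  structure(
    list(frames = frames, fps = spec$fps,
         meta = list(bpm = spec$bpm, seed = spec$seed, fps = spec$fps,
                     roi_axes = spec$roi_axes, roi_centers = centers,
                     frame_size = s, background = 64,
                     pulse_amplitude = spec$pulse_amplitude,
                     noise_sigma = spec$noise_sigma)),
    class = "frame_bundle"
  )
}

#' Generate the 1-D pulsatile signal alone
#'
#' Same temporal model as [generate_video()] but without imaging: a sampled
#' sinusoid at the grayscale skin baseline, plus drift and Gaussian noise.
#' Used to exercise peak detection and rate estimation in isolation.
#'
#' @param spec a [synth_spec].
#' @return list with `series`, `times` (seconds), and `truth` (bpm, seed).
#' @export
generate_signal <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- round(spec$fps * spec$duration)
  tt <- (seq_len(n) - 1) / spec$fps
  base <- 0.299 * spec$base_rgb[1] + 0.587 * spec$base_rgb[2] +
    0.114 * spec$base_rgb[3]
  series <- base + spec$pulse_amplitude * sin(2 * pi * (spec$bpm / 60) * tt) +
    spec$drift_per_s * tt
  if (spec$noise_sigma > 0) {
    series <- series + with_seed(spec$seed, stats::rnorm(n, 0, spec$noise_sigma))
  }
  list(series = series, times = tt,
       truth = list(bpm = spec$bpm, seed = spec$seed, fps = spec$fps))
}
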