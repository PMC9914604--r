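---
title: "Contactless heart-rate estimation by statistical feature mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless heart-rate estimation by statistical feature mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the method

Cardiac activity modulates the light reflected by skin: each beat changes
blood volume in the superficial vessels and with it the skin's apparent
intensity, by a fraction of a percent. Remote photoplethysmography (rPPG)
recovers the pulse from this modulation in ordinary video, with no
electrodes or wearables — useful wherever touch is undesirable
(screening stations, telehealth, infection control).

`pulsebeat` implements a statistical-feature variant of the rPPG pipeline:

1. **Ingest** — decode frames to RGB, attach timestamps `i / fps`
   (`read_frames()`).
2. **Locate skin** — one bounding box per frame around the face or hand
   (`detect_roi()`), then crop (`crop()`). Detection is a pluggable
   contract: the classical Haar-cascade face detector can back it, but the
   self-contained `skin_chroma` detector (YCbCr thresholds
   77 ≤ Cb ≤ 127, 133 ≤ Cr ≤ 173; largest connected component) is the
   default so the pipeline has no external model file.
3. **Condition frames** — grayscale (BT.601), bilinear rescale to a square
   working size, median filter, Gaussian blur
   (`preprocess_sequence()`).
4. **Feature battery** — for a fixed random subset of pixel positions
   (shared across frames), fourteen summary statistics per frame
   (`compute_feature_matrix()`): mean, median, variance, standard
   deviation of the current frame; Pearson correlation, chi-square
   histogram distance, RMSE, regression slope, Wilcoxon signed-rank W,
   Mann–Whitney U, Kolmogorov–Smirnov D against the previous frame; and
   Kruskal–Wallis H, Jonckheere–Terpstra J, Friedman chi-square over a
   three-frame window. All are used as *raw statistics*, never p-values:
   they are signal features whose magnitude is tracked over time.
5. **Select and mine** — pick the dominant feature column
   (`select_feature()`), detect beat peaks in its time series
   (`detect_peaks()`), and average instantaneous rates `60 / Δt` over
   successive peak intervals (`estimate_rate()`, `running` mode). The
   result is ceiled to an integer bpm and classified against the
   60–100 bpm normal resting range (`classify_rate()`).

Evaluation utilities (`error_percent()`, `summarize_rate_pairs()`) score
actual/predicted bpm pairs with the per-volunteer relative error
`100·|a − p|/a`, MAE, MSE, the share of exactly correct predictions, and
an accuracy figure defined as `100 − mean error %` (labelled *definition
D1* in reports: "accuracy" has no standard definition for this task, and
figures computed under D1 should not be equated with classifier-training
accuracies reported elsewhere).

## Why the per-frame statistics carry a pulse

Each statistic responds to the frame-to-frame intensity shift that the
pulse induces. The single-frame moments (mean, median) oscillate directly
with the blood-volume wave. The paired statistics (U, W, D, chi-square)
measure how far the current frame's intensity distribution has moved
relative to the previous frame, so they oscillate at the beat frequency
with a phase tied to the signal's slope; the three-frame trend statistics
(J, H, Friedman) behave similarly with a wider baseline. In measurements
on synthetic clips, the Jonckheere column — which the literal max-mean
selection rule picks, because J scales like the square of the sample size
— concentrates about 98% of its variance at the beat frequency.

## Estimation modes

The published per-event update this package descends from has the
recurrence `h_n = [h_n·(counter+1)/((t−t_p)·60)]/(counter+1)`, which
algebraically reduces to `h_n / ((t − t_p)·60)` per event: iterated, it
decays toward zero and is dimensionally inconsistent as a rate update.
`pulsebeat` therefore separates intent from letter:

* `running` (default) — the physiological reading: each peak interval
  `Δt` contributes an instantaneous rate `60/Δt` bpm and the estimate is
  their running mean. This is the mode all recovery results use.
* `top2` — one inter-beat interval, the time gap between the two largest
  peaks (the quantity `M`, the mean of the two largest peak values, is
  reported alongside).
* `literal` — the recurrence exactly as printed, ceiled each event,
  retained so the published procedure stays executable; its output is
  flagged `non_physiological` in every report.

With zero or one detected peak every mode returns the initial rate
`h_p = 60` bpm — the conventional resting baseline.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `target_size` | 227 px | square working size after ROI crop (the classical CNN input size; results are insensitive to it) |
| `median_kernel` | 3 | median window (salt noise); 1 disables |
| `gaussian_sigma` | 1.0 px | Gaussian blur (sensor noise); 0 disables |
| `enhance` | `FALSE` | global histogram equalization (see below) |
| `max_pixels` | 2048 | pixel sample per frame feeding the statistics |
| `smooth_window` | 5 frames (pipeline) | moving average on the selected series before peak finding |
| `min_height_frac` | 0.5 (pipeline) | amplitude screen: beat peaks must rise above this fraction of the series range |
| `min_bpm`, `max_bpm` | 40, 220 | physiological band; `60/max_bpm` is the minimum peak spacing |
| `h_p` | 60 bpm | initial rate, returned when no beat interval is measurable |

**Histogram equalization is off by default.** Global per-frame
equalization maps each frame through its own intensity CDF. A pure
baseline shift — precisely the pulsatile component — leaves the CDF's
shape unchanged, so equalized frames are (to first order) identical and
the pulse is cancelled. On a synthetic 72 bpm clip the pipeline estimates
73 bpm without equalization and 98 bpm with it. Equalization remains
available (`enhance = TRUE`) for display or for non-rPPG uses of the
preprocessing stack.

**Series conditioning before peak detection.** The selected feature
series concentrates its energy at the beat frequency, but broadband
frame-to-frame noise can still create tiny strict local maxima in the
flat troughs between beats; each one splits a beat interval and biases
the running mean upward. The pipeline therefore applies a centered
5-frame moving average (~1/6 s at 30 fps) to the selected series before
peak finding. The window is well below half the shortest admissible beat
period (`60/220 ≈ 0.27` s), so it cannot merge adjacent beats; windows
of 3, 5 and 7 frames behave equivalently on the validation grid, and 5
was fixed as the middle of that plateau. `detect_peaks()` itself defaults
to no smoothing, so its documented contract on raw series is unchanged.

**Amplitude screening.** On noiseless, heavily quantized input the
rank-statistic series develop a secondary bump each cycle (the statistic
sits near its ceiling during the systolic rise, near its floor during the
fall, and wobbles through mid-levels around the flat extremes), which
doubles the apparent rate if every local maximum counts as a beat. The
pipeline therefore also screens peaks by amplitude: a beat peak must rise
above the series midrange (`min_height_frac = 0.5` of the range above
the minimum). Fractions 0.3–0.7 behave identically on the validation
grids; 0.5 is the midpoint. This is the same role the height/prominence
arguments play in standard peak detectors. As with smoothing,
`detect_peaks()` defaults to no screening.

## Numerical conventions

* Pixel data live on the 0–255 integer grid; every resampling or
  filtering step rounds half-up back to that grid, so identical inputs
  give bit-identical outputs.
* Grayscale is BT.601 luma (0.299, 0.587, 0.114), rounded half-up.
* The median filter is exact: the 3×3 case runs through a 19-operation
  median exchange network (verified against brute force), other windows
  through direct medians; borders replicate edge pixels. The Gaussian
  blur is a separable truncated kernel (radius `3σ`) applied as banded
  Toeplitz matrix products with per-row renormalization at the borders.
  These replace the generic library filters for speed at video frame
  counts while keeping deterministic, testable semantics.
* Undefined statistics on degenerate windows (constant samples) are
  reported as 0: Pearson correlation, regression slope, Kruskal–Wallis
  and Friedman in their 0/0 tie-degenerate forms, and the Wilcoxon
  statistic when all differences are zero. One message per feature
  matrix notes the occurrence.
* Chi-square uses 16 equal-width bins on [0, 256) with expected counts
  equal to the mean of the two observed counts; bins empty in both
  histograms are dropped.
* Peak detection treats a run of equal values (common after integer
  quantization) as a single candidate at the run's first index, so
  flat-topped peaks count once; a plain strictly-greater rule would
  silently drop them.
* The final estimate is `ceiling(h_n − 10⁻⁹)`: the tolerance guard keeps
  an estimate a few ulps above an integer — which exact beat grids
  produce — from ceiling to the next integer.
* Ties in feature selection go to the first column in the fixed order;
  equal-valued adjacent peaks inside the minimum spacing drop the later
  one.

## The synthetic generator: what it does and does not show

No public dataset accompanies the method, so validation uses
`generate_video()`: an elliptical skin-toned patch (RGB 200, 160, 140 —
inside the chroma band the skin detector accepts) whose intensity
oscillates as `A·sin(2π·(bpm/60)·t)` over a darker background (64), with
per-pixel Gaussian noise, optional linear illumination drift, and integer
ROI jitter; all randomness flows from one seed, and truth metadata (bpm,
per-frame ellipse geometry, seed) is recorded. Defaults: 30 fps, 10 s,
128 px frames, amplitude 4, noise σ = 2 — amplitude is a few quantization
steps, like real rPPG, and σ = 2–3 matches consumer-sensor noise.

The generator emulates *periodicity, noise, drift and jitter only*. It
does not model real PPG waveform shape (systolic upstroke, dicrotic
notch), specular highlights, compression artifacts, motion, occlusion or
skin-tone diversity. Passing the recovery suite therefore shows the
pipeline extracts a known periodic intensity modulation under noise — a
necessary condition — not that it performs to any accuracy on real faces.

Recovery tests run the full pipeline at bpm ∈ {60, 72, 90, 120}, 30 fps,
10 s, noise σ = 3, seeds 1–3 (12 runs, the package's core acceptance
property, within ±2 bpm), plus a noise ladder σ ∈ {0, 2, 5, 10} at
72 bpm checking that error degrades monotonically. Problem sizes (10 s
clips, 128 px frames, 2048-pixel samples) are the package's validation
conditions; longer clips only average more beat intervals.

## Known limitations

* The result tables shipped in `inst/extdata/` reproduce their printed
  per-volunteer error cells to ≤ 0.002 (the cells mix round-half-up and
  truncation), but their printed MAE/MSE summaries (0.3/1.8 and
  0.142/1.82) are **not** arithmetic consequences of the printed pairs —
  recomputation gives 0.35/0.45 and 0.15/0.25. The package reports the
  recomputed values; the discrepancy is documented, not matched.
* Whether the original procedure iterates over frames or beats is
  unresolvable from its description; `running` and `literal` modes keep
  both readings available without claiming either produced the published
  tables.
* Single-subject, single-region estimation only: no continuous tracking,
  no heart-rate variability, no multi-person scenes.
* AVI/MP4 containers require an external frame extraction step; the
  package ingests PNG frame directories and array bundles.
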