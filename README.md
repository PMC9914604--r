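# pulsebeat

Contactless heart-rate estimation from video, for researchers and
engineers building touch-free vital-sign screening (remote
photoplethysmography, rPPG). Each heartbeat changes the blood volume in
superficial skin vessels and, with it, the intensity of light the skin
reflects; `pulsebeat` recovers the beat rate from that modulation in
ordinary video of a face or hand.

## The method

For a clip of `a` frames at known frame rate:

1. locate the skin region in every frame (pluggable detector; default is
   YCbCr skin-chroma thresholding, `77 ≤ Cb ≤ 127`, `133 ≤ Cr ≤ 173`,
   largest connected component) and crop it;
2. condition each crop: grayscale (BT.601), bilinear rescale to
   227 × 227, median filter (3 × 3), Gaussian blur (σ = 1);
3. for a fixed subsample of pixel positions shared across frames,
   compute a 14-statistic feature matrix `d` — per frame *i*: mean,
   median, variance, SD of frame *i*; Pearson *r*, χ² histogram
   distance, RMSE, regression slope, Wilcoxon signed-rank *W*,
   Mann–Whitney *U*, Kolmogorov–Smirnov *D* between frames *i* and
   *i−1*; Kruskal–Wallis *H*, Jonckheere–Terpstra *J*, Friedman χ² over
   frames *i−2 … i* (raw statistics, not p-values);
4. select the dominant feature column of `d`, detect beat peaks in its
   time series (after a 5-frame moving average and a midrange amplitude
   screen), and estimate

   bpm = ⌈ mean over successive peak intervals of 60 / Δt ⌉,

   where Δt is the inter-beat interval in seconds. With fewer than two
   peaks the estimate falls back to the initial rate h_p = 60 bpm.
   `M`, the mean of the two largest peaks, is reported alongside; rates
   are flagged low (< 60), normal, or high (> 100 bpm).

Evaluation over actual/predicted pairs uses
`error % = 100·|a − p| / a`, MAE, MSE, the exactly-correct fraction,
and `accuracy (D1) = 100 − mean error %`.

## Worked example

Estimate the rate of a synthetic 72 bpm clip (10 s, 30 fps, pixel noise
σ = 2) and score a bundled actual/predicted table:

```r
library(pulsebeat)

spec   <- synth_spec(bpm = 72, fps = 30, duration = 10,
                     noise_sigma = 2, seed = 1)
bundle <- generate_video(spec)
run_estimate(bundle, run_config())
#> pulsebeat: 72 bpm (running mode) from feature 'jonckheere' [11 peaks, flag: normal]

run_evaluate(evaluation_table_path("table3"))
#> Heart-rate evaluation over 20 pairs
#>  ...
#> MAE: 0.350 bpm   MSE: 0.450 bpm^2
#> accuracy (D1, 100 - mean error %): 99.554%
#> exactly correct: 70.0%
```

The estimator recovers the ground-truth 72 bpm exactly: the dominant
feature series (here the Jonckheere–Terpstra trend statistic) oscillates
at the pulse frequency, its 11 detected peaks give 10 inter-beat
intervals, and their mean instantaneous rate rounds up to 72. On the
bundled 20-volunteer table the maximum per-volunteer error is 3.125%,
14 of 20 predictions are exact (70%), and the recomputed MAE/MSE are
0.35 bpm / 0.45 bpm².

A command-line wrapper ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "pulsebeat.R", package = "pulsebeat"))')" \
    synth --bpm 72 --seed 1 --out clip.rds
Rscript .../pulsebeat.R estimate clip.rds --mode running --report report.json
Rscript .../pulsebeat.R evaluate pairs.csv --out eval.json
```

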