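Package: pulsebeat
Title: Contactless Heart-Rate Estimation from Video by Statistical
    Feature Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates an average heartbeat rate (bpm) from ordinary video
    of skin (face or hand) without physical contact, using remote
    photoplethysmography: a skin region of interest is located and cropped
    in every frame, frames are rescaled, denoised and converted to
    grayscale, a battery of fourteen per-frame summary statistics
    (including Wilcoxon, Mann-Whitney, Kolmogorov-Smirnov, Kruskal-Wallis,
    Jonckheere-Terpstra and Friedman statistics on sliding frame windows)
    is computed, the dominant feature series is mined for peaks, and the
    heart rate is estimated from inter-peak intervals. Also provides the
    evaluation metrics used to score actual/predicted bpm pairs (error
    percentage, MAE, MSE, accuracy, fraction correct) and a synthetic
    pulsatile-video generator with known ground-truth bpm for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
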