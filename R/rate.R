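# From feature matrix to beats per minute: select the dominant feature
# series, detect its peaks, and convert inter-peak intervals to a heart
# rate. Three estimation modes are provided: "running" (the default
# physiological reading: running mean of instantaneous rates 60 / dt over
# peak events), "top2" (one interval between the two largest peaks), and
# "literal" (the published per-event recurrence applied verbatim, kept for
# fidelity; its output is flagged non-physiological).

#' Select the dominant feature series
#'
#' With `normalize = FALSE` (the literal max-feature rule) the column whose
#' mean over rows is largest wins — in practice the large-magnitude rank
#' statistics. With `normalize = TRUE` every column is z-scored over rows
#' first and the column with the largest mean absolute z-score wins. Ties
#' go to the first column in the fixed order of [FEATURE_NAMES].
#'
#' @param matrix a `feature_matrix` from [compute_feature_matrix()].
#' @param normalize compare z-scored columns instead of raw means.
#' @return list with `feature_name`, `series` (numeric vector), and
#'   `times` (seconds, aligned with `series`).
#' @export
select_feature <- function(matrix, normalize = FALSE) {
  stopifnot(inherits(matrix, "feature_matrix"))
  vals <- as.matrix(matrix[, FEATURE_NAMES, drop = FALSE])
  if (nrow(vals) == 0L) stop_input("empty feature matrix")
  score <- if (normalize) {
    z <- scale(vals)
    z[, apply(vals, 2, stats::sd) == 0] <- 0
    colMeans(abs(z))
  } else {
    colMeans(vals)
  }
  best <- which.max(score)   # first maximum wins ties
  list(feature_name = FEATURE_NAMES[best],
       series = vals[, best],
       times = matrix$time_s)
}

#' Detect peaks in a feature series
#'
#' Local maxima (greater than the preceding value and greater than the next
#' distinct value, so flat-topped peaks from quantized data count once) are
#' filtered so consecutive peaks are at least `60 / max_bpm` seconds apart:
#' whenever two adjacent peaks are closer, the smaller is dropped and the
#' scan restarts. `M`, the mean of the two largest peak values, is the
#' summary quantity the selection step feeds forward.
#'
#' @param series numeric vector (length >= 3).
#' @param frame_times times in seconds, aligned with `series`.
#' @param min_bpm,max_bpm physiological plausibility bounds; `max_bpm` sets
#'   the minimum admissible peak spacing.
#' @param smooth_window odd moving-average window (in frames) applied to
#'   the series before peak finding; 1 (the default) disables it. The full
#'   pipeline conditions the selected feature series with a short window
#'   (5 frames at 30 fps, about 1/6 s — well below half the shortest beat
#'   period at `max_bpm`) to suppress broadband frame noise that otherwise
#'   seeds spurious local maxima in the flat troughs between beats.
#' @param min_height_frac amplitude screen in `[0, 1)`: discard local
#'   maxima below `min(series) + min_height_frac * (max(series) -
#'   min(series))`. 0 (the default) disables it. The pipeline uses 0.5 —
#'   beat peaks must rise above the series midrange — which rejects the
#'   secondary sub-midline bumps the rank-statistic series develop between
#'   beats (most visibly on noiseless quantized input).
#' @param feature_name optional label carried in the result.
#' @return A `peak_set`: list with `feature_name`, `peak_times`,
#'   `peak_values`, `M` (`NA` with fewer than 2 peaks), `series`, `times`.
#' @export
detect_peaks <- function(series, frame_times, min_bpm = 40, max_bpm = 220,
                         smooth_window = 1L, min_height_frac = 0,
                         feature_name = NA_character_) {
  if (length(series) < 3L) stop_input("'series' must have length >= 3")
  if (length(frame_times) != length(series)) {
    stop_input("'frame_times' must align with 'series'")
  }
  if (!is_count(smooth_window) || smooth_window < 1 || smooth_window %% 2 == 0) {
    stop_config("'smooth_window' must be an odd integer >= 1")
  }
  if (!is.numeric(min_height_frac) || min_height_frac < 0 || min_height_frac >= 1) {
    stop_config("'min_height_frac' must lie in [0, 1)")
  }
  if (smooth_window > 1L) series <- moving_average(series, smooth_window)
  idx <- local_maxima(series)
  if (min_height_frac > 0 && length(idx)) {
    floor_val <- min(series) + min_height_frac * diff(range(series))
    idx <- idx[series[idx] >= floor_val]
  }
  min_gap <- 60 / max_bpm
  repeat {
    if (length(idx) < 2L) break
    tms <- frame_times[idx]
    gaps <- diff(tms)
    bad <- which(gaps < min_gap)
    if (length(bad) == 0L) break
    b <- bad[1]
    drop <- if (series[idx[b]] >= series[idx[b + 1L]]) b + 1L else b
    idx <- idx[-drop]
  }
  vals <- series[idx]
  M <- if (length(vals) >= 2L) mean(sort(vals, decreasing = TRUE)[1:2]) else NA_real_
  structure(list(feature_name = feature_name,
                 peak_times = frame_times[idx], peak_values = vals,
                 M = M, series = series, times = frame_times),
            class = "peak_set")
}

# Centered moving average with edge replication; length-preserving.
moving_average <- function(s, w) {
  r <- (w - 1L) %/% 2L
  sp <- c(rep(s[1], r), s, rep(s[length(s)], r))
  as.numeric(stats::filter(sp, rep(1 / w, w), sides = 2))[r + seq_along(s)]
}

# Indices of local maxima with plateau support: a run of equal values is a
# single peak (first index of the run) when the previous distinct value is
# lower and the next distinct value is lower. Endpoints never qualify.
local_maxima <- function(s) {
  n <- length(s)
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- length(runs$values)
  if (k < 3L) return(integer(0))
  mid <- 2:(k - 1L)
  is_peak <- runs$values[mid] > runs$values[mid - 1L] &
    runs$values[mid] > runs$values[mid + 1L]
  starts[mid][is_peak]
}

#' Estimate the heart rate from a peak set
#'
#' * `running` (default): for successive peak pairs with interval
#'   `dt`, the instantaneous rate is `60 / dt` bpm; the estimate is the
#'   running mean of all instantaneous rates, ceiled to an integer.
#' * `top2`: one inter-beat interval — the time gap between the two largest
#'   peaks; `bpm = ceiling(60 / |dt|)`.
#' * `literal`: the published per-event recurrence
#'   `h_n = (h_n * (counter + 1)) / ((t - t_p) * 60) / (counter + 1)`,
#'   ceiled each event, applied verbatim over peak events. The recurrence
#'   reduces to `h_n / ((t - t_p) * 60)` per step and decays toward zero,
#'   so its output is reported with a `non_physiological` warning; it is
#'   retained so the published procedure stays executable and documentable.
#'
#' With zero or one detected peak, every mode returns the initial rate
#' `h_p` (60 bpm by convention) with `n_peaks_used = 0`.
#'
#' @param peaks a `peak_set` from [detect_peaks()].
#' @param mode `"running"`, `"top2"`, or `"literal"`.
#' @param h_p initial heart rate in bpm, the fallback when no beat interval
#'   is measurable.
#' @param low,high normal-range thresholds passed to [classify_rate()].
#' @return A `rate_estimate`: list with `bpm` (integer, ceiled),
#'   `pre_round` (the estimate before ceiling), `mode`, `n_peaks_used`,
#'   `M`, `flag` (low/normal/high), and `warnings` (character vector, may
#'   include `"non_physiological"`).
#' @export
estimate_rate <- function(peaks, mode = c("running", "top2", "literal"),
                          h_p = 60, low = 60, high = 100) {
  mode <- match.arg(mode)
  stopifnot(inherits(peaks, "peak_set"))
  tms <- peaks$peak_times
  if (length(tms) >= 2L && any(diff(tms) <= 0)) {
    stop_input("peak times must be strictly increasing")
  }
  warnings <- character(0)
  if (length(tms) < 2L) {
    pre <- h_p
    n_used <- 0L
  } else if (mode == "running") {
    rates <- 60 / diff(tms)
    pre <- mean(rates)
    n_used <- length(tms)
  } else if (mode == "top2") {
    ord <- order(peaks$peak_values, decreasing = TRUE)[1:2]
    dt <- abs(tms[ord[1]] - tms[ord[2]])
    if (dt == 0) stop_input("the two largest peaks coincide in time")
    pre <- 60 / dt
    n_used <- 2L
  } else {
    h <- h_p; t_p <- 0; counter <- 0
    for (t in tms) {
      h <- (h * (counter + 1)) / ((t - t_p) * 60) / (counter + 1)
      h <- ceiling(h)
      counter <- counter + 1
      t_p <- t
    }
    pre <- h
    n_used <- length(tms)
    warnings <- c(warnings, "non_physiological")
  }
  # tolerance guard: an estimate a few ulps above an integer (accumulated
  # floating error on exact beat grids) must not ceil to the next integer
  bpm <- as.integer(ceiling(pre - 1e-9))
  if (n_used > 0L && mode != "literal" && (bpm < 40 || bpm > 220)) {
    warnings <- c(warnings, "outside_physiological_bounds")
  }
  structure(list(bpm = bpm, pre_round = pre, mode = mode,
                 n_peaks_used = n_used, M = peaks$M,
                 flag = classify_rate(bpm, low, high), warnings = warnings),
            class = "rate_estimate")
}

#' Classify a heart rate against the normal resting range
#'
#' Cardiologists treat roughly 60--100 bpm as the normal resting range; a
#' value outside it is the alert condition contactless screening exists to
#' catch.
#'
#' @param bpm heart rate (non-negative).
#' @param low,high range thresholds.
#' @return `"low"` if `bpm < low`, `"high"` if `bpm > high`, else
#'   `"normal"`.
#' @export
classify_rate <- function(bpm, low = 60, high = 100) {
  if (bpm < 0) stop_input("'bpm' must be non-negative")
  if (bpm < low) "low" else if (bpm > high) "high" else "normal"
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("heart rate estimate: %d bpm (%s mode, %d peaks, flag: %s)\n",
              x$bpm, x$mode, x$n_peaks_used, x$flag))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}
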