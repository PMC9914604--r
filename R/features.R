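# Per-frame feature extraction: a fixed battery of 14 summary statistics of
# the ROI pixel intensities, computed on a sliding window of frames. The
# battery mixes single-frame moments, two-sample statistics on consecutive
# frames, and k-sample statistics on a three-frame window; its dominant
# column is later mined for periodicity.

#' Names of the 14 feature columns, in their fixed order
#' @export
FEATURE_NAMES <- c("mean", "median", "variance", "std", "correlation",
                   "chi_square", "rmse", "regression_slope", "wilcoxon",
                   "mann_whitney", "ks", "kruskal_wallis", "jonckheere",
                   "friedman")

#' Sample a fixed set of pixel positions from every frame
#'
#' Positions are drawn once, uniformly without replacement, and reused for
#' every frame of the sequence: the paired and blocked statistics
#' (Wilcoxon, Friedman) require pixelwise alignment across frames. When the
#' frame area does not exceed `max_pixels`, all pixels are used in
#' row-major order.
#'
#' @param sequence a preprocessed grayscale [frame_sequence].
#' @param max_pixels cap on the number of sampled positions.
#' @param seed seed for the position draw.
#' @return list with one element per frame: `values` (numeric vector),
#'   `frame_index`, and the shared `positions` (matrix of row, col).
#' @export
sample_pixels <- function(sequence, max_pixels = 2048L, seed = 1L) {
  stopifnot(inherits(sequence, "frame_sequence"))
  g1 <- sequence$gray[[1]] %||% sequence$frames[[1]]
  if (length(dim(g1)) != 2L) {
    stop_input("sample_pixels() expects a grayscale (preprocessed) sequence")
  }
  H <- nrow(g1); W <- ncol(g1)
  area <- H * W
  if (area <= max_pixels) {
    lin <- seq_len(area)                       # row-major enumeration
  } else {
    lin <- sort(with_seed(seed, sample.int(area, max_pixels)))
  }
  rows <- (lin - 1L) %/% W + 1L
  cols <- (lin - 1L) %% W + 1L
  positions <- cbind(row = rows, col = cols)
  lapply(seq_len(sequence$n_frames), function(i) {
    g <- sequence$gray[[i]] %||% sequence$frames[[i]]
    list(values = as.numeric(g[positions]), frame_index = i,
         positions = positions)
  })
}

#' Compute the 14-statistic feature matrix
#'
#' Row *i* (for the third frame onward) is computed from the pixel samples
#' of frames *i*, *i - 1*, *i - 2*:
#'
#' * `mean`, `median`, `variance` (divisor n - 1), `std` of frame *i*;
#' * `correlation` (Pearson), `chi_square` (paired 16-bin histograms over
#'   0--255), `rmse`, `regression_slope` (frame *i* on frame *i - 1*),
#'   `wilcoxon` (signed-rank W, zeros dropped), `mann_whitney` (U with
#'   midranks), `ks` (two-sample D) — all between frames *i* and *i - 1*;
#' * `kruskal_wallis` (H), `jonckheere` (J, group order *i - 2* <
#'   *i - 1* < *i*), `friedman` (chi-square, pixels as blocks) — over the
#'   three-frame window.
#'
#' Degenerate windows (constant or identical samples) follow the convention
#' that undefined statistics are reported as 0; one message is emitted per
#' matrix if this occurs.
#'
#' @param samples list of per-frame pixel samples from [sample_pixels()].
#' @param frame_times per-frame times in seconds, aligned with `samples`.
#' @return A data.frame of class `feature_matrix` with columns
#'   `frame_index`, `time_s`, and the 14 features in the order of
#'   [FEATURE_NAMES]. The first two frames produce no rows (window warm-up).
#' @export
compute_feature_matrix <- function(samples, frame_times) {
  n <- length(samples)
  if (n < 3L) stop_input("need at least 3 frames to compute features")
  if (length(frame_times) != n) {
    stop_input("'frame_times' must align with 'samples'")
  }
  rows <- 3:n
  out <- matrix(NA_real_, length(rows), length(FEATURE_NAMES),
                dimnames = list(NULL, FEATURE_NAMES))
  degenerate <- 0L
  for (j in seq_along(rows)) {
    i <- rows[j]
    x2 <- samples[[i]]$values        # frame i
    x1 <- samples[[i - 1L]]$values   # frame i - 1
    x0 <- samples[[i - 2L]]$values   # frame i - 2
    if (stats::var(x2) == 0 || stats::var(x1) == 0) degenerate <- degenerate + 1L
    out[j, ] <- c(
      mean(x2), stats::median(x2), stats::var(x2), stats::sd(x2),
      safe_cor(x2, x1),
      chi_square_hist_stat(x2, x1),
      rmse_stat(x2, x1),
      regression_slope(x1, x2),
      wilcoxon_signed_rank_stat(x2, x1),
      mann_whitney_u(x2, x1),
      ks_stat(x2, x1),
      kruskal_wallis_stat(list(x0, x1, x2)),
      jonckheere_stat(list(x0, x1, x2)),
      friedman_stat(cbind(x0, x1, x2))
    )
  }
  if (degenerate > 0L) {
    message("feature matrix: ", degenerate,
            " window(s) with constant samples; undefined statistics set to 0")
  }
  fm <- data.frame(frame_index = rows, time_s = frame_times[rows], out)
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Write a feature matrix to CSV
#'
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.csv(as.data.frame(fm), path, row.names = FALSE)
  invisible(path)
}
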