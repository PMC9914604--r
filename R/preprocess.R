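# Frame conditioning ahead of feature extraction: grayscale conversion,
# rescale to a square working size, two-stage denoising (median then
# Gaussian), and optional global histogram equalization.

#' Preprocessing configuration
#'
#' @param target_size output side length in pixels (square); the default 227
#'   matches the classical CNN input size the surrounding literature uses.
#' @param median_kernel odd window size of the median filter (salt-noise
#'   robustness); 1 disables it.
#' @param gaussian_sigma standard deviation, in pixels, of the Gaussian blur
#'   (sensor-noise smoothing); 0 disables it.
#' @param enhance apply global histogram equalization after denoising.
#'   Defaults to `FALSE`: per-frame equalization normalizes each frame's
#'   intensity histogram independently and therefore cancels the very
#'   frame-to-frame intensity shifts that carry the pulse (see the package
#'   vignette); enable it only for display or for non-photoplethysmographic
#'   uses.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_size = 227, median_kernel = 3,
                              gaussian_sigma = 1.0, enhance = FALSE) {
  if (!is_count(target_size) || target_size < 32) {
    stop_config("'target_size' must be an integer >= 32")
  }
  if (!is_count(median_kernel) || median_kernel < 1 || median_kernel %% 2 == 0) {
    stop_config("'median_kernel' must be an odd integer >= 1")
  }
  if (!is.numeric(gaussian_sigma) || gaussian_sigma < 0) {
    stop_config("'gaussian_sigma' must be >= 0")
  }
  structure(list(target_size = as.integer(target_size),
                 median_kernel = as.integer(median_kernel),
                 gaussian_sigma = gaussian_sigma, enhance = isTRUE(enhance)),
            class = "preprocess_config")
}

#' Preprocess a frame sequence
#'
#' Fixed processing order per frame: grayscale conversion (BT.601, if the
#' input is RGB), bilinear rescale to `target_size` square (direct
#' anisotropic resize, no letterboxing), median filter, Gaussian blur, and
#' optional global histogram equalization. Intermediate results are rounded
#' half-up to the 0--255 integer grid after each resampling/filtering step,
#' so identical input and configuration give bit-identical output.
#'
#' @param sequence a [frame_sequence] (RGB or grayscale frames).
#' @param config a [preprocess_config].
#' @return A grayscale [frame_sequence] whose `gray` field is populated.
#' @export
preprocess_sequence <- function(sequence, config = preprocess_config()) {
  stopifnot(inherits(sequence, "frame_sequence"),
            inherits(config, "preprocess_config"))
  out <- vector("list", sequence$n_frames)
  for (i in seq_len(sequence$n_frames)) {
    fr <- sequence$frames[[i]]
    g <- if (length(dim(fr)) == 3L) to_grayscale(fr) else fr
    g <- preprocess_frame(g, config)
    out[[i]] <- g
  }
  res <- frame_sequence(out, fps = sequence$fps,
                        timestamps = sequence$timestamps,
                        source_id = paste0(sequence$source_id, ":pre"))
  res$gray <- out
  res
}

preprocess_frame <- function(g, config) {
  s <- config$target_size
  if (!identical(dim(g), c(s, s))) {
    img <- EBImage::resize(EBImage::Image(g / 255), w = s, h = s,
                           filter = "bilinear")
    g <- clip8(round_half_up(EBImage::imageData(img) * 255))
  }
  if (config$median_kernel > 1L) {
    g <- median_filter(g, config$median_kernel)
  }
  if (config$gaussian_sigma > 0) {
    g <- clip8(round_half_up(gaussian_blur(g, config$gaussian_sigma)))
  }
  if (config$enhance) g <- equalize_hist(g)
  storage.mode(g) <- "integer"
  g
}

# Exact k x k median filter with edge-replicate padding. The common 3 x 3
# case runs through a fixed 19-comparison median network vectorized over
# all pixels; other window sizes take a direct (slower) row-median path.
median_filter <- function(g, k) {
  r <- (k - 1L) %/% 2L
  H <- nrow(g); W <- ncol(g)
  gp <- g[pmin(pmax(seq_len(H + 2L * r) - r, 1L), H),
          pmin(pmax(seq_len(W + 2L * r) - r, 1L), W)]
  shifts <- vector("list", k * k)
  m <- 1L
  for (dy in 0:(k - 1L)) for (dx in 0:(k - 1L)) {
    shifts[[m]] <- as.vector(gp[dy + seq_len(H), dx + seq_len(W)])
    m <- m + 1L
  }
  med <- if (k == 3L) median9(shifts) else {
    apply(do.call(cbind, shifts), 1L, stats::median)
  }
  matrix(med, H, W)
}

# Median of 9 values per pixel via a minimal exchange network
# (19 min/max operations), exact for any numeric input.
median9 <- function(p) {
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  p[[5]]
}

# Separable Gaussian blur: 1-D kernel truncated at 3*sigma with per-row
# renormalization at the borders, applied as banded Toeplitz matrix
# products along each axis. Deterministic and fast at the frame sizes used.
gaussian_blur <- function(g, sigma) {
  TH <- gaussian_toeplitz(nrow(g), sigma)
  TW <- if (ncol(g) == nrow(g)) TH else gaussian_toeplitz(ncol(g), sigma)
  TH %*% g %*% t(TW)   # t(): right factor must be column-stochastic
}

gaussian_toeplitz <- local({
  cache <- new.env(parent = emptyenv())
  function(n, sigma) {
    key <- paste0(n, "_", sigma)
    if (!is.null(cache[[key]])) return(cache[[key]])
    r <- max(1L, ceiling(3 * sigma))
    w <- exp(-(0:r)^2 / (2 * sigma^2))
    Tm <- matrix(0, n, n)
    for (d in 0:r) {
      idx <- seq_len(n - d)
      Tm[cbind(idx, idx + d)] <- w[d + 1L]
      Tm[cbind(idx + d, idx)] <- w[d + 1L]
    }
    Tm <- Tm / rowSums(Tm)
    cache[[key]] <- Tm
    Tm
  }
})

# Global histogram equalization on the 0--255 integer grid: map each level v
# to round(255 * cdf(v)). A constant image (one occupied bin) maps to 255.
equalize_hist <- function(g) {
  counts <- tabulate(as.vector(g) + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(g)
  lut <- round_half_up(255 * cdf)
  matrix(lut[g + 1L], nrow = nrow(g))
}
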