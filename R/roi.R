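# Skin-region localization: find the face/hand patch in each frame and crop
# it. The classical pipeline calls a Viola-Jones face detector here; that
# detector is prior art consumed, not contributed, so it sits behind a
# pluggable contract. Two self-contained detectors (skin-chroma thresholding
# and a fixed center box) guarantee the pipeline runs without any external
# cascade model file.

#' Detect the skin region of interest in every frame
#'
#' Returns exactly one bounding box per frame. Supported detector specs:
#'
#' * `"skin_chroma"` — threshold in YCbCr chroma (`77 <= Cb <= 127`,
#'   `133 <= Cr <= 173`), then take the bounding box of the largest
#'   connected component. Self-contained; works on any skin-toned patch.
#' * `"center_box"` — a centered box covering 50% of each dimension.
#' * `"x,y,w,h"` (or a numeric length-4 vector) — a fixed box, 0-based
#'   top-left corner.
#' * `"cascade"` — reserved for an external Haar-cascade face detector. No
#'   cascade engine is linked in this package, so this spec downgrades to
#'   `skin_chroma` with a warning; the contract exists so a cascade-backed
#'   detector can be dropped in without touching the pipeline.
#'
#' When a detector finds nothing in frame *i* the box from frame *i - 1* is
#' carried forward; if frame 1 has no detection, the `center_box` fallback
#' is used. Detections smaller than 8 px in either dimension are treated as
#' no detection (too small to carry a pulsatile signal).
#'
#' @param sequence a [frame_sequence] with RGB frames.
#' @param detector detector spec (see above).
#' @param smooth if `TRUE`, apply a running median (window 5) to the box
#'   coordinates to damp frame-to-frame jitter. Off by default.
#' @return data.frame with columns `frame_index`, `x`, `y`, `w`, `h`,
#'   `score` (0-based `x`, `y`; `score` is `NA` for geometric detectors).
#' @export
detect_roi <- function(sequence, detector = "skin_chroma", smooth = FALSE) {
  stopifnot(inherits(sequence, "frame_sequence"))
  fixed <- NULL
  if (is.numeric(detector) && length(detector) == 4L) {
    fixed <- as.integer(detector)
    detector <- "fixed_box"
  } else if (is.character(detector) && length(detector) == 1L &&
             grepl("^[0-9]+,[0-9]+,[0-9]+,[0-9]+$", detector)) {
    fixed <- as.integer(strsplit(detector, ",")[[1]])
    detector <- "fixed_box"
  }
  if (!detector %in% c("cascade", "skin_chroma", "fixed_box", "center_box")) {
    stop_config("unknown detector: '", detector, "'")
  }
  if (detector == "cascade") {
    warning("no Haar-cascade engine is linked; falling back to skin_chroma")
    detector <- "skin_chroma"
  }
  n <- sequence$n_frames
  boxes <- data.frame(frame_index = seq_len(n), x = NA_integer_,
                      y = NA_integer_, w = NA_integer_, h = NA_integer_,
                      score = NA_real_)
  for (i in seq_len(n)) {
    fr <- sequence$frames[[i]]
    d <- dim(fr)
    H <- d[1]; W <- d[2]
    box <- switch(detector,
      skin_chroma = detect_skin_chroma(fr),
      center_box  = center_box(W, H),
      fixed_box   = {
        if (fixed[1] < 0 || fixed[2] < 0 || fixed[1] + fixed[3] > W ||
            fixed[2] + fixed[4] > H || fixed[3] < 8 || fixed[4] < 8) {
          stop_input("fixed box (", paste(fixed, collapse = ","),
                     ") outside ", W, "x", H, " frame bounds")
        }
        fixed
      })
    if (is.null(box)) {
      box <- if (i == 1L) center_box(W, H) else
        unlist(boxes[i - 1L, c("x", "y", "w", "h")], use.names = FALSE)
    }
    boxes[i, c("x", "y", "w", "h")] <- as.list(box)
  }
  if (isTRUE(smooth)) {
    for (col in c("x", "y", "w", "h")) {
      boxes[[col]] <- as.integer(stats::runmed(boxes[[col]], 5))
    }
    d1 <- dim(sequence$frames[[1]])
    boxes$x <- pmin(pmax(boxes$x, 0L), d1[2] - boxes$w)
    boxes$y <- pmin(pmax(boxes$y, 0L), d1[1] - boxes$h)
  }
  boxes
}

center_box <- function(W, H) {
  w <- floor(W / 2); h <- floor(H / 2)
  c(floor((W - w) / 2), floor((H - h) / 2), w, h)
}

# YCbCr (BT.601, full range) chroma threshold skin mask; box = bounding box
# of the largest 4-connected component. Returns NULL when nothing usable.
detect_skin_chroma <- function(frame) {
  R <- frame[, , 1L]; G <- frame[, , 2L]; B <- frame[, , 3L]
  Cb <- 128 - 0.168736 * R - 0.331264 * G + 0.5 * B
  Cr <- 128 + 0.5 * R - 0.418688 * G - 0.081312 * B
  mask <- Cb >= 77 & Cb <= 127 & Cr >= 133 & Cr <= 173
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  tab <- tabulate(labm[labm > 0])
  best <- which.max(tab)
  idx <- which(labm == best, arr.ind = TRUE)
  y0 <- min(idx[, 1]); y1 <- max(idx[, 1])
  x0 <- min(idx[, 2]); x1 <- max(idx[, 2])
  w <- x1 - x0 + 1L; h <- y1 - y0 + 1L
  if (w < 8L || h < 8L) return(NULL)
  c(x0 - 1L, y0 - 1L, w, h)   # 0-based corner
}

#' Crop a frame sequence to per-frame bounding boxes
#'
#' @param sequence a [frame_sequence].
#' @param boxes data.frame as returned by [detect_roi()], one row per frame.
#' @return A new [frame_sequence] of crops; timestamps and fps preserved.
#' @export
crop <- function(sequence, boxes) {
  stopifnot(inherits(sequence, "frame_sequence"))
  if (nrow(boxes) != sequence$n_frames) {
    stop_input("need exactly one box per frame (", sequence$n_frames,
               " frames, ", nrow(boxes), " boxes)")
  }
  out <- vector("list", sequence$n_frames)
  for (i in seq_len(sequence$n_frames)) {
    fr <- sequence$frames[[i]]
    d <- dim(fr)
    b <- boxes[i, ]
    if (b$x < 0 || b$y < 0 || b$x + b$w > d[2] || b$y + b$h > d[1]) {
      stop_input("box for frame ", i, " exceeds frame bounds")
    }
    rows <- (b$y + 1):(b$y + b$h)
    cols <- (b$x + 1):(b$x + b$w)
    out[[i]] <- if (length(d) == 3L) fr[rows, cols, , drop = FALSE] else
      fr[rows, cols, drop = FALSE]
  }
  frame_sequence(out, fps = sequence$fps, timestamps = sequence$timestamps,
                 source_id = paste0(sequence$source_id, ":crop"))
}

# Intersection-over-union of two (x, y, w, h) boxes; used to score detectors
# against generator truth.
box_iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}
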