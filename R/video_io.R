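# Frame ingestion: turn a directory of still frames or an array bundle into
# a uniform, timestamped RGB frame sequence, and convert color to grayscale.

#' Construct a frame sequence
#'
#' A `frame_sequence` is the package's uniform in-memory representation of a
#' video clip: an ordered list of frames (RGB `H x W x 3` integer arrays or,
#' after preprocessing, grayscale `H x W` matrices with values in 0--255),
#' one timestamp per frame in seconds, and the frame rate.
#'
#' @param frames list of frames; each an integer array `H x W x 3` (RGB) or
#'   an `H x W` matrix (grayscale), values in `[0, 255]`.
#' @param fps frames per second (positive number).
#' @param timestamps optional vector of per-frame times in seconds, strictly
#'   increasing; defaults to `(seq_along(frames) - 1) / fps`.
#' @param gray optional list of grayscale twins (`H x W` matrices), one per
#'   frame and matching each frame's spatial size.
#' @param source_id free-text provenance label.
#' @return An object of class `frame_sequence` with fields `frames`,
#'   `timestamps`, `fps`, `n_frames`, `gray`, `source_id`.
#' @seealso [read_frames()], [to_grayscale()]
#' @export
frame_sequence <- function(frames, fps, timestamps = NULL, gray = NULL,
                           source_id = "memory") {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_input("'frames' must be a non-empty list of image arrays")
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop_config("'fps' must be a single positive number")
  }
  n <- length(frames)
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1) / fps
  if (length(timestamps) != n) {
    stop_input("length(timestamps) must equal the number of frames")
  }
  if (any(diff(timestamps) <= 0)) {
    stop_input("timestamps must be strictly increasing")
  }
  for (f in frames) {
    d <- dim(f)
    if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L))) {
      stop_input("each frame must be an H x W x 3 RGB array or an H x W matrix")
    }
    rng <- range(f)
    if (rng[1] < 0 || rng[2] > 255) stop_input("pixel values must lie in [0, 255]")
  }
  if (!is.null(gray)) {
    if (length(gray) != n) stop_input("length(gray) must equal the number of frames")
    for (i in seq_len(n)) {
      if (!identical(dim(gray[[i]]), dim(frames[[i]])[1:2])) {
        stop_input("gray frame ", i, " does not match its RGB twin's size")
      }
    }
  }
  structure(
    list(frames = frames, timestamps = as.numeric(timestamps), fps = fps,
         n_frames = n, gray = gray, source_id = source_id),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "frame_sequence: %d frames, %dx%d%s, %.6g fps, %.3f s [%s]\n",
    x$n_frames, d[1], d[2],
    if (length(d) == 3L) " RGB" else " gray",
    x$fps, x$timestamps[x$n_frames] - x$timestamps[1], x$source_id))
  invisible(x)
}

#' Read frames from a directory, bundle, or bundle file
#'
#' Ingests one of: a directory of sequentially named PNG images
#' (lexicographic order is temporal order; an optional `meta.json` in the
#' directory may carry `fps` and generator truth metadata), a
#' [frame_bundle] object as produced by [generate_video()], or a path to an
#' `.rds` file holding such a bundle. Frames are normalized to RGB channel
#' order with integer values in 0--255.
#'
#' Video containers (AVI/MP4) are not decodable with the decoders this
#' package links against; extract frames to a PNG directory first (for
#' example with `ffmpeg -i in.mp4 frames/frame_%05d.png`).
#'
#' @param source directory path, `.rds` bundle path, or `frame_bundle`.
#' @param fps_override frame rate to use when the source carries none.
#' @return A [frame_sequence] with timestamps `i / fps` (i = 0, 1, ...)
#'   unless the source provides its own.
#' @export
read_frames <- function(source, fps_override = NULL) {
  if (inherits(source, "frame_bundle")) {
    return(bundle_to_sequence(source, fps_override))
  }
  if (!is.character(source) || length(source) != 1L) {
    stop_input("'source' must be a path or a frame_bundle")
  }
  if (!file.exists(source)) stop_input("source does not exist: ", source)
  if (dir.exists(source)) return(read_frame_dir(source, fps_override))
  ext <- tolower(tools::file_ext(source))
  if (ext == "rds") {
    bundle <- readRDS(source)
    if (!inherits(bundle, "frame_bundle")) {
      stop_input("not a frame bundle: ", source)
    }
    return(bundle_to_sequence(bundle, fps_override, source_id = source))
  }
  if (ext %in% c("avi", "mp4", "mov", "mkv", "webm")) {
    stop_input("cannot decode video container '", source,
               "': no video decoder is linked; extract frames to a PNG ",
               "directory and point read_frames() at it")
  }
  stop_input("unsupported source: ", source)
}

read_frame_dir <- function(path, fps_override) {
  files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop_input("no frames found in directory: ", path)
  meta <- NULL
  meta_path <- file.path(path, "meta.json")
  if (file.exists(meta_path)) meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  fps <- fps_override %||% meta$fps
  if (is.null(fps)) {
    stop_config("frame rate unrecoverable from '", path,
                "': supply fps_override or a meta.json with an fps field")
  }
  frames <- lapply(files, read_png_frame)
  seq <- frame_sequence(frames, fps = as.numeric(fps), source_id = path)
  attr(seq, "meta") <- meta
  seq
}

read_png_frame <- function(file) {
  a <- png::readPNG(file)
  a <- round_half_up(a * 255)
  d <- dim(a)
  if (length(d) == 2L) {
    a <- array(rep(a, 3L), dim = c(d, 3L))      # expand gray to RGB
  } else if (d[3] == 4L) {
    a <- a[, , 1:3, drop = FALSE]               # drop alpha
  } else if (d[3] == 2L) {
    a <- array(rep(a[, , 1L], 3L), dim = c(d[1:2], 3L))
  }
  storage.mode(a) <- "integer"
  a
}

bundle_to_sequence <- function(bundle, fps_override = NULL, source_id = NULL) {
  fps <- fps_override %||% bundle$fps
  seq <- frame_sequence(bundle$frames, fps = fps,
                        source_id = source_id %||% "frame_bundle")
  attr(seq, "meta") <- bundle$meta
  seq
}

#' Write a frame sequence or bundle to a PNG directory
#'
#' Writes one losslessly encoded PNG per frame (`frame_00001.png`, ...) plus
#' a `meta.json` holding the frame rate and, for synthetic bundles, the
#' ground-truth metadata, so [read_frames()] round-trips the arrays
#' bit-exactly.
#'
#' @param x a [frame_sequence] or [frame_bundle].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(x, dir) {
  if (inherits(x, "frame_bundle")) x <- bundle_to_sequence(x)
  if (!inherits(x, "frame_sequence")) stop_input("'x' must be a frame sequence or bundle")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(x$n_frames)) {
    f <- x$frames[[i]]
    png::writePNG(f / 255, file.path(dir, sprintf("frame_%05d.png", i)))
  }
  meta <- attr(x, "meta") %||% list()
  meta$fps <- x$fps
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Convert an RGB frame to grayscale
#'
#' BT.601 luma: `0.299 R + 0.587 G + 0.114 B`, rounded half-up to integers
#' in 0--255. Applied to an image whose three channels are equal it returns
#' that channel unchanged.
#'
#' @param frame `H x W x 3` RGB array (values 0--255).
#' @return `H x W` integer matrix.
#' @export
to_grayscale <- function(frame) {
  d <- dim(frame)
  if (is.null(d) || length(d) != 3L || d[3] != 3L) {
    stop_input("to_grayscale() expects an H x W x 3 RGB array")
  }
  g <- round_half_up(0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] +
                       0.114 * frame[, , 3L])
  storage.mode(g) <- "integer"
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
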