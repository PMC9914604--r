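# End-to-end wiring: source -> ROI -> preprocess -> features -> rate, with
# a resolved configuration embedded in every report for provenance.

#' Build a resolved run configuration
#'
#' Defaults < config file < explicit arguments. The resolved configuration
#' is fully JSON-serializable and embedded verbatim in every report.
#'
#' @param detector ROI detector spec (see [detect_roi()]).
#' @param roi_smooth median-smooth ROI boxes over time.
#' @param preprocess a [preprocess_config()].
#' @param max_pixels pixel-sample cap per frame (see [sample_pixels()]).
#' @param normalize_features use z-scored feature selection (see
#'   [select_feature()]).
#' @param mode rate-estimation mode (see [estimate_rate()]).
#' @param smooth_window odd moving-average window (frames) conditioning the
#'   selected feature series before peak detection (see [detect_peaks()]).
#' @param min_height_frac amplitude screen for peak detection: beat peaks
#'   must rise above this fraction of the series range above its minimum
#'   (see [detect_peaks()]).
#' @param min_bpm,max_bpm physiological bounds for peak detection.
#' @param h_p initial heart rate (bpm) used when no beats are measurable.
#' @param fps_override frame rate when the source carries none.
#' @param seed seed for pixel sampling.
#' @param config_file optional JSON file whose top-level keys override the
#'   defaults above (flat keys; `preprocess` may be a nested object).
#' @return A `run_config` list.
#' @export
run_config <- function(detector = "skin_chroma", roi_smooth = FALSE,
                       preprocess = preprocess_config(), max_pixels = 2048L,
                       normalize_features = FALSE,
                       mode = c("running", "top2", "literal"),
                       smooth_window = 5L, min_height_frac = 0.5,
                       min_bpm = 40, max_bpm = 220,
                       h_p = 60, fps_override = NULL, seed = 1L,
                       config_file = NULL) {
  mode <- match.arg(mode)
  cfg <- list(detector = detector, roi_smooth = roi_smooth,
              preprocess = unclass(preprocess), max_pixels = max_pixels,
              normalize_features = normalize_features, mode = mode,
              smooth_window = smooth_window,
              min_height_frac = min_height_frac, min_bpm = min_bpm,
              max_bpm = max_bpm, h_p = h_p,
              fps_override = fps_override, seed = as.integer(seed))
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop_input("config file not found: ", config_file)
    file_cfg <- jsonlite::read_json(config_file, simplifyVector = TRUE)
    for (k in names(file_cfg)) {
      if (k == "preprocess") {
        cfg$preprocess[names(file_cfg$preprocess)] <- file_cfg$preprocess
      } else cfg[[k]] <- file_cfg[[k]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full contactless heart-rate pipeline
#'
#' Executes ingestion, ROI detection and cropping, preprocessing, feature
#' extraction, feature selection, peak detection, and rate estimation, and
#' optionally writes a JSON report. The report is written atomically (no
#' partial files on error).
#'
#' @param source frame directory, `.rds` bundle path, or `frame_bundle`.
#' @param config a [run_config()].
#' @param report optional path for a JSON report.
#' @return A `rate_report`: list with `bpm`, `mode`, `feature_name`,
#'   `n_peaks`, `M`, `flag`, `warnings`, `config`, `schema_version`.
#' @export
run_estimate <- function(source, config = run_config(), report = NULL) {
  stopifnot(inherits(config, "run_config"))
  seq <- read_frames(source, fps_override = config$fps_override)
  boxes <- detect_roi(seq, detector = config$detector,
                      smooth = config$roi_smooth)
  roi_seq <- crop(seq, boxes)
  pp <- do.call(preprocess_config, config$preprocess)
  pre <- preprocess_sequence(roi_seq, pp)
  samples <- sample_pixels(pre, max_pixels = config$max_pixels,
                           seed = config$seed)
  fm <- compute_feature_matrix(samples, pre$timestamps)
  sel <- select_feature(fm, normalize = config$normalize_features)
  peaks <- detect_peaks(sel$series, sel$times, min_bpm = config$min_bpm,
                        max_bpm = config$max_bpm,
                        smooth_window = config$smooth_window,
                        min_height_frac = config$min_height_frac,
                        feature_name = sel$feature_name)
  est <- estimate_rate(peaks, mode = config$mode, h_p = config$h_p)
  rep <- structure(
    list(bpm = est$bpm, mode = est$mode, feature_name = sel$feature_name,
         n_peaks = length(peaks$peak_times), M = peaks$M,
         flag = est$flag, warnings = est$warnings,
         source_id = seq$source_id, config = unclass(config),
         schema_version = 1L),
    class = "rate_report")
  if (!is.null(report)) write_report_json(rep, report)
  rep
}

write_report_json <- function(rep, path) {
  tmp <- paste0(path, ".tmp")
  out <- unclass(rep)
  out$M <- if (is.na(out$M)) NULL else out$M
  jsonlite::write_json(out, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf(
    "pulsebeat: %d bpm (%s mode) from feature '%s' [%d peaks, flag: %s]\n",
    x$bpm, x$mode, x$feature_name, x$n_peaks, x$flag))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a CSV of actual/predicted pairs
#'
#' @param pairs_csv CSV path (see [read_rate_pairs()] for the format).
#' @param report optional JSON output path.
#' @return An `evaluation_report` (see [summarize_rate_pairs()]).
#' @export
run_evaluate <- function(pairs_csv, report = NULL) {
  rep <- summarize_rate_pairs(read_rate_pairs(pairs_csv))
  if (!is.null(report)) write_evaluation_report(rep, report)
  rep
}
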