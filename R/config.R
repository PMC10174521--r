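#' Analysis configuration
#'
#' Bundles every tunable parameter of the detection pipeline. The defaults are
#' the configuration validated on the synthetic ground-truth datasets (see the
#' methods vignette for the calibration rationale).
#'
#' @param sg_order polynomial order of the temporal Savitzky-Golay filter
#'   (integer >= 1; the method fixes this at 3).
#' @param sg_window odd integer window length (> `sg_order`), or `"auto"` to
#'   derive one from the frame count via [auto_window()].
#' @param blur_sigma xy Gaussian blur in pixels applied before thresholding
#'   (>= 0; 0 disables blurring).
#' @param threshold_method one of `"otsu"`, `"yen"`, `"triangle"`.
#' @param threshold_mode `"global"` (one threshold per channel over the whole
#'   stack) or `"per_frame"` (one per channel and frame).
#' @param threshold_bins number of uniform histogram bins used by the
#'   threshold search.
#' @param min_event_voxels discard sites with fewer 4-D voxels than this.
#' @param min_event_frames discard sites spanning fewer frames than this.
#' @param connectivity `"face"` (8 neighbours in 4-D) or `"full"` (80).
#' @param amplitude_method `"mean"` (delta f = peak cross-section mean) or
#'   `"peak_voxel"` (peak single-voxel intensity).
#' @param seed optional integer seed recorded in run manifests.
#' @return A validated list of class `AnalysisConfig`.
#' @export
analysis_config <- function(sg_order = 3L,
                            sg_window = "auto",
                            blur_sigma = 0.35,
                            threshold_method = c("yen", "otsu", "triangle"),
                            threshold_mode = c("global", "per_frame"),
                            threshold_bins = 4096L,
                            min_event_voxels = 8L,
                            min_event_frames = 2L,
                            connectivity = c("face", "full"),
                            amplitude_method = c("mean", "peak_voxel"),
                            seed = NULL) {
  threshold_method <- match.arg(threshold_method)
  threshold_mode <- match.arg(threshold_mode)
  connectivity <- match.arg(connectivity)
  amplitude_method <- match.arg(amplitude_method)
  sg_order <- as.integer(sg_order)
  if (sg_order < 1L) stop("sg_order must be >= 1", call. = FALSE)
  if (!identical(sg_window, "auto")) {
    sg_window <- as.integer(sg_window)
    if (sg_window %% 2L == 0L || sg_window <= sg_order)
      stop("sg_window must be odd and greater than sg_order, or \"auto\"",
           call. = FALSE)
  }
  if (!is.numeric(blur_sigma) || blur_sigma < 0)
    stop("blur_sigma must be a non-negative number", call. = FALSE)
  threshold_bins <- as.integer(threshold_bins)
  if (threshold_bins < 2L) stop("threshold_bins must be >= 2", call. = FALSE)
  min_event_voxels <- as.integer(min_event_voxels)
  min_event_frames <- as.integer(min_event_frames)
  if (min_event_voxels < 1L || min_event_frames < 1L)
    stop("minimum size filters must be >= 1 (1 disables them)", call. = FALSE)
  structure(list(sg_order = sg_order, sg_window = sg_window,
                 blur_sigma = blur_sigma, threshold_method = threshold_method,
                 threshold_mode = threshold_mode, threshold_bins = threshold_bins,
                 min_event_voxels = min_event_voxels,
                 min_event_frames = min_event_frames,
                 connectivity = connectivity,
                 amplitude_method = amplitude_method,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "AnalysisConfig")
}

#' The configuration used by the synthetic validation harness
#'
#' Identical to [analysis_config()] defaults except that the Savitzky-Golay
#' window is fixed at 41 frames, matched to the temporal band of the synthetic
#' Gaussian pulse (sigma_t = 10 frames) rather than derived from the recording
#' length.
#' @param ... overrides forwarded to [analysis_config()].
#' @return An `AnalysisConfig`.
#' @export
validation_config <- function(...) {
  args <- list(...)
  if (is.null(args$sg_window)) args$sg_window <- 41L
  do.call(analysis_config, args)
}

#' Read / write an AnalysisConfig as YAML or JSON
#'
#' The format is chosen from the file extension (".yaml"/".yml" or ".json").
#' @param path file path.
#' @return `read_config()` returns an `AnalysisConfig`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(path)
  do.call(analysis_config, vals[!vapply(vals, is.null, TRUE)])
}

#' @rdname read_config
#' @param config an `AnalysisConfig`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "AnalysisConfig"))
  vals <- unclass(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(vals, path)
  else jsonlite::write_json(vals, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
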