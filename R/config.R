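#' Pipeline configuration defaults
#'
#' Collects every tunable threshold of the co-localization, tracking,
#' mosaicking and scoring stages in one list, so acceptance probes and the
#' command line can read and override them from a single YAML file.
#'
#' Key values and their provenance:
#' * `inlier_accept_threshold = 6` - a registration is accepted only when
#'   its RANSAC inlier count is strictly greater than this (7 or more).
#' * `mosaic_max_frames = 40` - maximum number of dermoscopic frames that
#'   can be stitched into one mosaic.
#' * `ransac_inlier_tol_px = 3`, `ransac_max_iters = 2000` - RANSAC
#'   residual tolerance (at reference scale) and hypothesis count.
#' * `tracking_confidence_threshold = 6` - inter-frame motion inlier count
#'   below or at which dead-reckoning is not trusted (same strict semantics
#'   as the global gate); `tracking_max_coast = 25` caps the number of
#'   consecutive extrapolated frames.
#' * `patch_size_px = 128`, `patch_stride_px = 64`,
#'   `patch_score_threshold = 50` - heatmap patch grid and the score (in
#'   percent) below which patches are suppressed.
#' * detector settings (`detector_contrast`, `detector_edge`,
#'   `detector_sigma0`, `detector_scales`) for the keypoint stage.
#' * `match_cross_check = FALSE` - optional symmetric match filter; the
#'   default is plain one-way nearest-neighbor matching.
#' * `heatmap_per_patch_color = FALSE` - retained patches are colored by
#'   the frame's global score; per-patch coloring is a diagnostic mode.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `bcc_config`.
#' @examples
#' cfg <- bcc_config(ransac_max_iters = 500)
#' cfg$inlier_accept_threshold
#' @export
bcc_config <- function(...) {
  cfg <- list(
    inlier_accept_threshold = 6L,
    mosaic_max_frames = 40L,
    ransac_inlier_tol_px = 3,
    ransac_max_iters = 2000L,
    tracking_confidence_threshold = 6L,
    tracking_max_coast = 25L,
    patch_size_px = 128L,
    patch_stride_px = 64L,
    patch_score_threshold = 50,
    detector_contrast = 0.03,
    detector_edge = 10,
    detector_sigma0 = 1.6,
    detector_scales = 3L,
    match_cross_check = FALSE,
    heatmap_per_patch_color = FALSE
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad))
      bcc_error("bccmap_bad_config",
                paste("unknown config fields:", paste(bad, collapse = ", ")))
    cfg[names(dots)] <- dots
  }
  counts <- c("inlier_accept_threshold", "mosaic_max_frames",
              "ransac_max_iters", "tracking_confidence_threshold",
              "tracking_max_coast", "patch_size_px", "patch_stride_px")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      bcc_error("bccmap_bad_config", paste(f, "must be a positive count"))
  stopifnot(cfg$ransac_inlier_tol_px > 0)
  class(cfg) <- "bcc_config"
  cfg
}

#' Read / write configuration as YAML
#'
#' The shipped defaults live at
#' `system.file("extdata", "default_config.yaml", package = "bccmap")`.
#' A config file may also carry a `calibrations:` section overriding the
#' built-in [default_calibrations()] profiles.
#'
#' @param path File path.
#' @param config A `bcc_config` (for writing).
#' @return `load_config()` returns a list with elements `config`
#'   (a `bcc_config`) and `calibrations` (profile list).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    bcc_error("bccmap_bad_input", paste("config file not found:", path))
  raw <- yaml::read_yaml(path)
  cal <- default_calibrations()
  if (!is.null(raw$calibrations)) {
    for (nm in names(raw$calibrations))
      cal[[nm]] <- calibration_from_list(raw$calibrations[[nm]])
    raw$calibrations <- NULL
  }
  cfg <- do.call(bcc_config, raw)
  list(config = cfg, calibrations = cal)
}

#' @rdname load_config
#' @param calibrations Optional named list of `calibration_profile`s to
#'   embed in the file.
#' @export
save_config <- function(config, path, calibrations = NULL) {
  out <- unclass(config)
  if (!is.null(calibrations))
    out$calibrations <- lapply(calibrations, calibration_to_list)
  yaml::write_yaml(out, path)
  invisible(path)
}
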