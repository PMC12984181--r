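#' Calibration profiles: physical-to-pixel mapping per imaging modality
#'
#' A calibration profile ties an image modality to its physical field of
#' view (FOV) and pixel dimensions, from which the pixel pitch (micrometers
#' per pixel) is derived per axis.  The built-in defaults
#' ([default_calibrations()]) describe the co-localized dermoscopy / LC-OCT
#' system this package models: a wide-field contact video-dermoscope, the
#' circular color surface image captured through the LC-OCT probe, and the
#' LC-OCT scan geometries themselves.
#'
#' The physical origin is the top-left corner of the FOV and coincides with
#' the center of pixel `(0, 0)`; a point at `(u, v)` millimeters maps to
#' pixel `(u / pitch_x, v / pitch_y)` (pitch in mm).  For the circular
#' surface modality the FOV is a single diameter and maps to the inscribed
#' circle of the square image.
#'
#' @param modality One of `"dermoscope"`, `"surface"`, `"lcoct_vertical"`,
#'   `"lcoct_horizontal"`, `"lcoct_3d"`, or a custom label.
#' @param fov Physical extent in mm: `c(width, height)`, or a single
#'   diameter when `circular = TRUE`.
#' @param image_shape Pixel dimensions `c(width, height)`.
#' @param circular Logical; `TRUE` only for the round surface-image FOV.
#' @return An object of class `calibration_profile` with fields `modality`,
#'   `fov`, `image_shape`, `circular` and `pixel_pitch` (um/px, per axis).
#' @examples
#' calib <- default_calibrations()
#' calib$surface$pixel_pitch   # 6.5 um/px
#' @export
calibration_profile <- function(modality, fov, image_shape, circular = FALSE) {
  stopifnot(is.character(modality), length(modality) == 1)
  if (circular) {
    stopifnot(length(fov) == 1, fov > 0)
    fov_wh <- c(fov, fov)
  } else {
    stopifnot(length(fov) == 2, all(fov > 0))
    fov_wh <- fov
  }
  stopifnot(length(image_shape) == 2, all(image_shape >= 1))
  pitch <- fov_wh * 1000 / image_shape  # um per pixel
  stopifnot(all(pitch > 0))
  structure(list(modality = modality, fov = fov,
                 image_shape = as.integer(image_shape),
                 circular = isTRUE(circular),
                 pixel_pitch = pitch),
            class = "calibration_profile")
}

#' @rdname calibration_profile
#' @export
default_calibrations <- function() {
  list(
    dermoscope       = calibration_profile("dermoscope", c(13.3, 8.9),
                                           c(5536, 3692)),
    surface          = calibration_profile("surface", 2.6, c(400, 400),
                                           circular = TRUE),
    lcoct_vertical   = calibration_profile("lcoct_vertical", c(1.2, 0.4),
                                           c(2048, 680)),
    lcoct_horizontal = calibration_profile("lcoct_horizontal", c(1.2, 0.5),
                                           c(2048, 850)),
    lcoct_3d         = calibration_profile("lcoct_3d", c(1.2, 0.5),
                                           c(1200, 500))
  )
}

#' Scale ratio between two calibration profiles
#'
#' The registration model is rotation + translation only, so images of
#' different pixel pitch must be brought to a common micrometer-per-pixel
#' scale before feature extraction.  Resampling the source image by the
#' returned ratio puts it at the destination's scale.
#'
#' @param src,dst `calibration_profile` objects.
#' @return The unitless ratio `src pitch / dst pitch` (mean over axes).  A
#'   warning of class `bccmap_anisotropic_pitch` is raised when the per-axis
#'   ratios disagree by more than 1 percent.
#' @export
scale_factor <- function(src, dst) {
  stopifnot(inherits(src, "calibration_profile"),
            inherits(dst, "calibration_profile"))
  ratio <- src$pixel_pitch / dst$pixel_pitch
  if (abs(ratio[1] / ratio[2] - 1) > 0.01)
    warning(warningCondition(
      sprintf("anisotropic pitch ratio (%.4f vs %.4f) between %s and %s",
              ratio[1], ratio[2], src$modality, dst$modality),
      class = "bccmap_anisotropic_pitch"))
  mean(ratio)
}

#' Convert between physical (mm) and pixel coordinates
#'
#' @param calib A `calibration_profile`.
#' @param pts An `n x 2` matrix (or length-2 vector) of `(x, y)` points, in
#'   mm for `mm_to_px()` and in pixels for `px_to_mm()`.
#' @param warn Warn (class `bccmap_out_of_fov`) when a point falls outside
#'   the FOV; the conversion is still returned.
#' @return An `n x 2` matrix of converted coordinates.
#' @export
mm_to_px <- function(calib, pts, warn = TRUE) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  pitch_mm <- calib$pixel_pitch / 1000
  fov_wh <- if (calib$circular) c(calib$fov, calib$fov) else calib$fov
  if (warn && any(pts[, 1] < 0 | pts[, 1] > fov_wh[1] |
                  pts[, 2] < 0 | pts[, 2] > fov_wh[2]))
    warning(warningCondition("point outside calibrated FOV",
                             class = "bccmap_out_of_fov"))
  cbind(pts[, 1] / pitch_mm[1], pts[, 2] / pitch_mm[2])
}

#' @rdname mm_to_px
#' @export
px_to_mm <- function(calib, pts, warn = TRUE) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  pitch_mm <- calib$pixel_pitch / 1000
  out <- cbind(pts[, 1] * pitch_mm[1], pts[, 2] * pitch_mm[2])
  fov_wh <- if (calib$circular) c(calib$fov, calib$fov) else calib$fov
  if (warn && any(out[, 1] < 0 | out[, 1] > fov_wh[1] |
                  out[, 2] < 0 | out[, 2] > fov_wh[2]))
    warning(warningCondition("point outside calibrated FOV",
                             class = "bccmap_out_of_fov"))
  out
}

#' @export
print.calibration_profile <- function(x, ...) {
  fov <- if (x$circular) sprintf("%.2f mm diameter (circular)", x$fov)
         else sprintf("%.2f x %.2f mm", x$fov[1], x$fov[2])
  cat(sprintf("<calibration_profile> %s: %s, %d x %d px, pitch %.3f x %.3f um/px\n",
              x$modality, fov, x$image_shape[1], x$image_shape[2],
              x$pixel_pitch[1], x$pixel_pitch[2]))
  invisible(x)
}

# serialization used by config files and sessions
calibration_to_list <- function(calib) {
  list(modality = calib$modality, fov = calib$fov,
       image_shape = calib$image_shape, circular = calib$circular)
}

calibration_from_list <- function(x) {
  calibration_profile(x$modality, unlist(x$fov), unlist(x$image_shape),
                      isTRUE(x$circular))
}
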