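#' Phantom specification
#'
#' Describes a synthetic dermoscopy-like phantom with known ground truth:
#' a textured skin-like background (multi-octave band-pass noise plus
#' scattered elliptical pigment blobs), a lesion with a radially sigmoid
#' BCC-probability field, and four colored ink arcs marking the excision
#' margin per clock quadrant.  Phantoms stand in for clinical images in
#' every test: identical spec + seed always yields a bit-identical phantom.
#'
#' The probability field is `p(r) = plateau * plogis((edge_mm - r) / slope_mm)`
#' (r = distance from the lesion center in mm): approximately `plateau`
#' inside the lesion, exactly half the plateau at `r = edge_mm`, and
#' falling to zero outside.  An optional angular lobe confines the positive
#' region to a clock-angle range, emulating lesions with only some
#' quadrants involved.
#'
#' @param canvas_shape Phantom pixel dimensions `c(width, height)`.  The
#'   default (960 x 642 px over the 13.3 x 8.9 mm dermoscope FOV) keeps
#'   whole-pipeline simulations tractable; pitch relationships mirror the
#'   clinical geometry.
#' @param fov_mm Physical extent `c(width, height)` in mm.
#' @param surface_shape,surface_fov_mm Pixel size and circular-FOV diameter
#'   of simulated surface frames (192 px over 2.6 mm by default).
#' @param texture_sigmas,texture_weights Gaussian blur scales (px) and
#'   relative weights of the band-pass noise octaves.
#' @param blob_density Pigment blobs per mm^2.
#' @param lesion_center_mm Lesion center (default: FOV center).
#' @param lesion_radius_mm Nominal lesion radius.
#' @param plateau Field plateau value in percent.
#' @param edge_mm Radius at which the field crosses half the plateau.
#' @param slope_mm Sigmoid slope scale.
#' @param angular_lobe Optional `c(from, to)` clock angles (radians,
#'   12 o'clock = 0, clockwise) outside which the field is suppressed.
#' @param margin_radius_mm Radius of the inked margin circle
#'   (lesion radius + 2-3 mm safety distance).
#' @param ink_colors Quadrant ink colors (black, red, green, purple scheme).
#' @param seed Integer seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(canvas_shape = c(960, 642),
                         fov_mm = c(13.3, 8.9),
                         surface_shape = 192,
                         surface_fov_mm = 2.6,
                         texture_sigmas = c(1, 2, 4, 8),
                         texture_weights = c(0.35, 1, 0.8, 0.6),
                         blob_density = 1.2,
                         lesion_center_mm = NULL,
                         lesion_radius_mm = 0.9,
                         plateau = 100,
                         edge_mm = 2.7,
                         slope_mm = 0.35,
                         angular_lobe = NULL,
                         margin_radius_mm = 3,
                         ink_colors = c("12-3" = "black", "3-6" = "red",
                                        "6-9" = "green", "9-12" = "purple"),
                         seed = 1L) {
  if (is.null(lesion_center_mm)) lesion_center_mm <- fov_mm / 2
  spec <- list(canvas_shape = as.integer(canvas_shape), fov_mm = fov_mm,
               surface_shape = as.integer(surface_shape),
               surface_fov_mm = surface_fov_mm,
               texture_sigmas = texture_sigmas,
               texture_weights = texture_weights,
               blob_density = blob_density,
               lesion_center_mm = lesion_center_mm,
               lesion_radius_mm = lesion_radius_mm,
               plateau = plateau, edge_mm = edge_mm, slope_mm = slope_mm,
               angular_lobe = angular_lobe,
               margin_radius_mm = margin_radius_mm,
               ink_colors = ink_colors, seed = as.integer(seed))
  stopifnot(spec$plateau >= 0, spec$plateau <= 100, spec$slope_mm > 0)
  class(spec) <- "phantom_spec"
  spec
}

#' Evaluate the ground-truth probability field
#'
#' @param spec A `phantom_spec`.
#' @param pts_mm `n x 2` matrix of points in mm.
#' @return Field values in `[0, 100]`.
#' @export
phantom_field <- function(spec, pts_mm) {
  if (is.null(dim(pts_mm))) pts_mm <- matrix(pts_mm, ncol = 2)
  dx <- pts_mm[, 1] - spec$lesion_center_mm[1]
  dy <- pts_mm[, 2] - spec$lesion_center_mm[2]
  r <- sqrt(dx^2 + dy^2)
  p <- spec$plateau * stats::plogis((spec$edge_mm - r) / spec$slope_mm)
  if (!is.null(spec$angular_lobe)) {
    a <- atan2(dx, -dy) %% (2 * pi)
    lo <- spec$angular_lobe[1] %% (2 * pi)
    hi <- spec$angular_lobe[2] %% (2 * pi)
    inside <- if (lo <= hi) a >= lo & a <= hi else a >= lo | a <= hi
    p <- p * ifelse(inside, 1, 0.02)
  }
  pmin(pmax(p, 0), 100)
}

#' Generate a dermoscopy-like phantom
#'
#' @param spec A [phantom_spec()].
#' @return A `bcc_phantom`: list with `image` (`h x w x 3` RGB in `[0, 1]`),
#'   `field` (matrix of ground-truth probabilities in percent, one value per
#'   pixel), `calib` / `surface_calib` (calibration profiles of the phantom
#'   canvas and of simulated surface frames), `center_px`,
#'   `margin_radius_px` and the spec itself.  Deterministic per seed.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  w <- spec$canvas_shape[1]; h <- spec$canvas_shape[2]
  calib <- calibration_profile("dermoscope", spec$fov_mm, c(w, h))
  surface_calib <- calibration_profile("surface", spec$surface_fov_mm,
                                       rep(spec$surface_shape, 2),
                                       circular = TRUE)
  pitch_mm <- calib$pixel_pitch / 1000
  img <- with_seed(spec$seed, {
    # band-pass noise octaves
    tex <- matrix(0, h, w)
    for (k in seq_along(spec$texture_sigmas)) {
      n <- matrix(stats::rnorm(h * w), h, w)
      s <- spec$texture_sigmas[k]
      band <- cpp_gauss_blur(n, s) - cpp_gauss_blur(n, 2 * s)
      tex <- tex + spec$texture_weights[k] * band / stats::sd(band)
    }
    tex <- tex / stats::sd(tex)
    base <- c(0.80, 0.60, 0.55)       # skin tone
    mod <- c(0.10, 0.13, 0.12)        # per-channel texture contrast
    img <- array(0, c(h, w, 3))
    for (c in 1:3) img[, , c] <- clamp01(base[c] + mod[c] * tex)
    # pigment-network proxy: darker elliptical blobs
    n_blob <- round(spec$blob_density * prod(spec$fov_mm))
    bx <- stats::runif(n_blob, 0, spec$fov_mm[1])
    by <- stats::runif(n_blob, 0, spec$fov_mm[2])
    brad <- stats::runif(n_blob, 0.08, 0.3)
    becc <- stats::runif(n_blob, 0.5, 1)
    bang <- stats::runif(n_blob, 0, pi)
    bdark <- stats::runif(n_blob, 0.15, 0.4)
    for (b in seq_len(n_blob)) {
      rx_px <- brad[b] / pitch_mm[1]
      cx <- bx[b] / pitch_mm[1]; cy <- by[b] / pitch_mm[2]
      half <- ceiling(2.5 * rx_px)
      xs <- max(0, floor(cx - half)):min(w - 1, ceiling(cx + half))
      ys <- max(0, floor(cy - half)):min(h - 1, ceiling(cy + half))
      if (!length(xs) || !length(ys)) next
      gx <- matrix(rep(xs, each = length(ys)), length(ys)) - cx
      gy <- matrix(rep(ys, length(xs)), length(ys)) - cy
      u <- gx * cos(bang[b]) + gy * sin(bang[b])
      v <- (-gx * sin(bang[b]) + gy * cos(bang[b])) / becc[b]
      g <- exp(-(u^2 + v^2) / (2 * (rx_px / 1.8)^2))
      for (c in 1:3)
        img[ys + 1, xs + 1, c] <- img[ys + 1, xs + 1, c] * (1 - bdark[b] * g)
    }
    img
  })
  # inked margin arcs, one color per clock quadrant, small gaps between
  center_px <- as.numeric(mm_to_px(calib, spec$lesion_center_mm, warn = FALSE))
  r_px <- spec$margin_radius_mm / mean(pitch_mm)
  qstart <- c(0, pi / 2, pi, 3 * pi / 2)
  for (q in 1:4) {
    a <- seq(qstart[q] + 0.06, qstart[q] + pi / 2 - 0.06, length.out = 160)
    px <- center_px[1] + r_px * sin(a)
    py <- center_px[2] - r_px * cos(a)
    img <- set_px(img, px, py, col_to_rgb01(spec$ink_colors[q]), width = 2)
  }
  # ground-truth field sampled at every pixel
  xs_mm <- (0:(w - 1)) * pitch_mm[1]
  ys_mm <- (0:(h - 1)) * pitch_mm[2]
  pts <- cbind(rep(xs_mm, each = h), rep(ys_mm, w))
  field <- matrix(phantom_field(spec, pts), h, w)
  structure(list(image = clamp01(img), field = field, calib = calib,
                 surface_calib = surface_calib, center_px = center_px,
                 margin_radius_px = r_px, spec = spec),
            class = "bcc_phantom")
}

#' @export
print.bcc_phantom <- function(x, ...) {
  cat(sprintf("<bcc_phantom> %d x %d px (%.1f x %.1f mm), lesion at (%.0f, %.0f) px, seed %d\n",
              x$spec$canvas_shape[1], x$spec$canvas_shape[2],
              x$spec$fov_mm[1], x$spec$fov_mm[2],
              x$center_px[1], x$center_px[2], x$spec$seed))
  invisible(x)
}

#' @export
plot.bcc_phantom <- function(x, ...) {
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  d <- dim(x$image)
  graphics::plot.window(c(0, d[2]), c(d[1], 0), asp = 1)
  graphics::rasterImage(x$image, 0, d[1], d[2], 0)
  invisible(x)
}

#' Probe path along the margin circle
#'
#' Ground-truth poses sampling the inked margin at a fixed angular step,
#' with the probe oriented along the sweep direction, emulating an operator
#' following the colored margin lines in a continuous manner.
#'
#' @param phantom A `bcc_phantom`.
#' @param n_frames Number of frames.
#' @param start_angle,end_angle Clock angles (radians, 12 o'clock = 0,
#'   clockwise positive) swept by the probe.
#' @param radius_mm Sweep radius (default: the inked margin radius).
#' @param jitter_px,jitter_theta Per-frame uniform jitter on position (ref
#'   px) and orientation (radians), emulating hand-held wobble.
#' @param seed Integer seed for the jitter draw.
#' @return A `probe_path`: list of true poses (ref-scale surface ->
#'   reference px, the convention of [colocalize()]) plus the sampled
#'   angles.  Errors with class `bccmap_path_out_of_bounds` if any FOV
#'   leaves the canvas.
#' @export
probe_path <- function(phantom, n_frames, start_angle = 0,
                       end_angle = 2 * pi, radius_mm = NULL,
                       jitter_px = 0, jitter_theta = 0, seed = 1L) {
  spec <- phantom$spec
  if (is.null(radius_mm)) radius_mm <- spec$margin_radius_mm
  r_px <- radius_mm / mean(phantom$calib$pixel_pitch / 1000)
  angles <- seq(start_angle, end_angle, length.out = n_frames)
  s <- scale_factor(phantom$surface_calib, phantom$calib)
  u_c <- s * (spec$surface_shape - 1) / 2   # FOV center, ref-scale frame px
  jit <- with_seed(seed, list(
    dx = stats::runif(n_frames, -jitter_px, jitter_px),
    dy = stats::runif(n_frames, -jitter_px, jitter_px),
    dth = stats::runif(n_frames, -jitter_theta, jitter_theta)))
  w <- spec$canvas_shape[1]; h <- spec$canvas_shape[2]
  poses <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    a <- angles[i]
    c_px <- phantom$center_px + r_px * c(sin(a), -cos(a)) +
      c(jit$dx[i], jit$dy[i])
    th <- a + jit$dth[i]
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    t <- c_px - as.numeric(Rm %*% c(u_c, u_c))
    pose <- rigid_pose(th, t[1], t[2])
    # only the inscribed circular FOV carries image content
    r_fov <- s * (spec$surface_shape - 1) / 2
    if (c_px[1] < r_fov || c_px[1] > w - 1 - r_fov ||
        c_px[2] < r_fov || c_px[2] > h - 1 - r_fov)
      bcc_error("bccmap_path_out_of_bounds",
                sprintf("frame %d field of view leaves the phantom canvas", i))
    poses[[i]] <- pose
  }
  structure(list(poses = poses, angles = angles, radius_mm = radius_mm,
                 scale = s),
            class = "probe_path")
}

#' Simulate the surface-image stream of a probe sweep
#'
#' Each frame is the phantom resampled (bicubic) through its true pose at
#' the surface pixel pitch, masked to the circular FOV, with optional
#' additive Gaussian pixel noise, per-frame illumination gain and defocus
#' blur.
#'
#' @param phantom A `bcc_phantom`.
#' @param path A [probe_path()].
#' @param noise_sd Additive Gaussian noise standard deviation (image units,
#'   e.g. `5/255`).
#' @param gain_sd Standard deviation of the per-frame multiplicative
#'   illumination gain around 1.
#' @param blur_sigma Defocus blur sigma in px (0 = none).
#' @param seed Integer seed for the noise draw.
#' @return List with `frames` (list of `h x w x 3` arrays at raw surface
#'   scale) and `poses` (the true poses, for recovery-error scoring).
#' @export
simulate_surface_stream <- function(phantom, path, noise_sd = 0,
                                    gain_sd = 0, blur_sigma = 0, seed = 1L) {
  n <- length(path$poses)
  shape <- phantom$spec$surface_shape
  s <- path$scale
  frames <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      fr <- sample_rigid(phantom$image, shape, shape, path$poses[[i]],
                         prescale = s)
      if (gain_sd > 0) fr <- fr * (1 + stats::rnorm(1, 0, gain_sd))
      if (blur_sigma > 0)
        for (c in 1:3) fr[, , c] <- cpp_gauss_blur(fr[, , c], blur_sigma)
      if (noise_sd > 0) fr <- fr + array(stats::rnorm(length(fr), 0, noise_sd),
                                         dim(fr))
      fr <- clamp01(fr)
      m <- circle_mask(shape, shape)
      for (c in 1:3) { ch <- fr[, , c]; ch[!m] <- 0; fr[, , c] <- ch }
      fr
    })
  })
  list(frames = frames, poses = path$poses)
}

#' Simulate an LC-OCT-like vertical B-scan frame
#'
#' Produces a grayscale frame with a bright epidermal entrance line, a
#' speckled dermal band and dark basaloid-lobule ellipses, whose in-band
#' bright-pixel fraction is calibrated to the phantom's ground-truth
#' probability at the probe position - so [reference_density_scorer()]
#' recovers the field value to within a few points.  Bright speckle is
#' spatially clumped around the lobules so patch heatmaps show structure.
#'
#' @param phantom A `bcc_phantom`.
#' @param pose The probe pose (ref-scale surface -> reference px) at which
#'   the scan is taken; the field is read at the FOV center.
#' @param bscan_cfg List: `shape` `c(width, height)` px (default
#'   `c(1024, 340)`, half the clinical vertical-scan raster),
#'   `intensity_cutoff` and `band` matching the scorer.
#' @param seed Integer seed.
#' @return Grayscale matrix in `[0, 1]`, with attribute `field_value` (the
#'   ground-truth probability the frame encodes).
#' @export
simulate_bscan <- function(phantom, pose,
                           bscan_cfg = list(shape = c(1024, 340),
                                            intensity_cutoff = 0.5,
                                            band = c(0.15, 0.85)),
                           seed = 1L) {
  shape <- bscan_cfg$shape %||% c(1024, 340)
  cutoff <- bscan_cfg$intensity_cutoff %||% 0.5
  band <- bscan_cfg$band %||% c(0.15, 0.85)
  w <- shape[1]; h <- shape[2]
  s <- scale_factor(phantom$surface_calib, phantom$calib)
  u_c <- s * (phantom$spec$surface_shape - 1) / 2
  pos_ref <- transform_points(pose, c(u_c, u_c))[1, ]
  pos_mm <- px_to_mm(phantom$calib, pos_ref, warn = FALSE)
  p <- as.numeric(phantom_field(phantom$spec, pos_mm))
  r0 <- max(1L, 1L + floor(band[1] * h))
  r1 <- min(h, ceiling(band[2] * h))
  frame <- with_seed(seed, {
    depth <- matrix(rep(seq_len(h) / h, w), h, w)
    frame <- 0.30 * exp(-3 * depth) + 0.04 +
      matrix(stats::rnorm(h * w, 0, 0.05), h, w)
    # bright epidermal entrance band
    er <- max(2L, round(0.06 * h))
    frame[1:er, ] <- 0.75 + matrix(stats::rnorm(er * w, 0, 0.05), er, w)
    # dark lobules, count scaling with the local probability
    n_lob <- round(p / 100 * 12)
    lx <- stats::runif(max(n_lob, 1), 0.05 * w, 0.95 * w)
    ly <- stats::runif(max(n_lob, 1), r0 + 0.1 * (r1 - r0),
                       r1 - 0.1 * (r1 - r0))
    lr <- stats::runif(max(n_lob, 1), 0.04, 0.10) * h
    if (n_lob > 0) {
      for (b in seq_len(n_lob)) {
        xs <- max(1, floor(lx[b] - 2 * lr[b])):min(w, ceiling(lx[b] + 2 * lr[b]))
        ys <- max(1, floor(ly[b] - 1.4 * lr[b])):min(h, ceiling(ly[b] + 1.4 * lr[b]))
        gx <- matrix(rep(xs, each = length(ys)), length(ys)) - lx[b]
        gy <- matrix(rep(ys, length(xs)), length(ys)) - ly[b]
        g <- exp(-(gx^2 / (1.6 * lr[b])^2 + gy^2 / lr[b]^2))
        frame[ys, xs] <- frame[ys, xs] * (1 - 0.85 * g) + 0.02 * g
      }
    }
    frame <- clamp01(frame)
    # calibrate the in-band bright-pixel fraction to the field value
    sub <- frame[r0:r1, , drop = FALSE]
    n_band <- length(sub)
    target <- round(p / 100 * n_band)
    bright <- sub >= cutoff
    cur <- sum(bright)
    if (cur < target) {
      # promote pixels, preferentially near the lobules (spatial clumping)
      cand <- which(!bright)
      wgt <- rep(1e-3, length(cand))
      if (n_lob > 0) {
        cy <- (cand - 1) %% nrow(sub) + r0
        cx <- (cand - 1) %/% nrow(sub) + 1
        for (b in seq_len(n_lob))
          wgt <- wgt + exp(-((cx - lx[b])^2 + (cy - ly[b])^2) /
                             (2 * (2.5 * lr[b])^2))
      }
      pick <- sample(cand, target - cur, prob = wgt)
      sub[pick] <- cutoff + 0.25 * stats::runif(length(pick))
    } else if (cur > target) {
      pick <- sample(which(bright), cur - target)
      sub[pick] <- cutoff - 0.05 - 0.2 * stats::runif(length(pick))
    }
    frame[r0:r1, ] <- sub
    frame
  })
  frame <- clamp01(frame)
  attr(frame, "field_value") <- p
  frame
}

`%||%` <- function(a, b) if (is.null(a)) b else a
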