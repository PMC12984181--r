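#' Scored probe trajectory in dermoscopy coordinates
#'
#' As the probe sweeps the marked lateral margins, every frame with an
#' effective pose (locked or coasting) contributes a scored sample: the
#' acquisition marker geometry (a line for vertical scans, a rectangle for
#' horizontal scans or 3-D stacks) placed by the tracker's pose, plus the
#' frame's BCC score in percent.  Rendering the trajectory over the
#' dermoscopy image gives the color-coded acquisition path from blue
#' (score 0) to yellow (score 100).
#'
#' Quadrants follow the clinical clock convention: angles are measured from
#' the lesion center with 12 o'clock along -y (image up) and clockwise
#' positive, partitioning the margin into 12-3, 3-6, 6-9 and 9-12 o'clock
#' arcs, by default inked black, red, green and purple respectively.
#'
#' @param center Lesion center `(x, y)` in reference px (defines the clock
#'   frame).
#' @param quadrant_colors Named character vector of display colors for the
#'   four quadrants.
#' @return An empty `margin_trajectory`.
#' @export
trajectory_init <- function(center,
                            quadrant_colors = c("12-3" = "black",
                                                "3-6" = "red",
                                                "6-9" = "green",
                                                "9-12" = "purple")) {
  stopifnot(length(center) == 2,
            identical(names(quadrant_colors), c("12-3", "3-6", "6-9", "9-12")))
  structure(list(samples = list(), center = as.numeric(center),
                 quadrant_colors = quadrant_colors),
            class = "margin_trajectory")
}

#' @export
print.margin_trajectory <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<margin_trajectory> %d scored sample(s), lesion center (%.0f, %.0f)\n",
              n, x$center[1], x$center[2]))
  if (n) {
    sc <- vapply(x$samples, `[[`, numeric(1), "score")
    cat(sprintf("  scores: min %.1f / median %.1f / max %.1f %%\n",
                min(sc), stats::median(sc), max(sc)))
  }
  invisible(x)
}

#' Marker geometries in surface coordinates
#'
#' The LC-OCT acquisition footprint within the (reference-scaled) surface
#' frame: a line segment across the FOV center for vertical B-scans, or a
#' rectangle for horizontal scans and 3-D volumes.
#'
#' @param calib_surface,calib_reference Calibration profiles; the marker is
#'   expressed at reference scale, matching tracker poses.
#' @param length_mm,width_mm Physical scan extent (defaults: the 1.2 mm
#'   scan line; 0.5 mm swath for rectangles).
#' @return List with `type` (`"line"` or `"rect"`) and `points` (2 x 2 or
#'   4 x 2 matrix in ref-scale surface px).
#' @export
marker_line <- function(calib_surface, calib_reference, length_mm = 1.2) {
  s <- scale_factor(calib_surface, calib_reference)
  c_px <- s * (calib_surface$image_shape - 1) / 2
  half <- length_mm * 1000 / calib_reference$pixel_pitch[1] / 2
  list(type = "line",
       points = rbind(c(c_px[1] - half, c_px[2]), c(c_px[1] + half, c_px[2])))
}

#' @rdname marker_line
#' @export
marker_rect <- function(calib_surface, calib_reference, length_mm = 1.2,
                        width_mm = 0.5) {
  s <- scale_factor(calib_surface, calib_reference)
  c_px <- s * (calib_surface$image_shape - 1) / 2
  hx <- length_mm * 1000 / calib_reference$pixel_pitch[1] / 2
  hy <- width_mm * 1000 / calib_reference$pixel_pitch[2] / 2
  list(type = "rect",
       points = rbind(c(c_px[1] - hx, c_px[2] - hy),
                      c(c_px[1] + hx, c_px[2] - hy),
                      c(c_px[1] + hx, c_px[2] + hy),
                      c(c_px[1] - hx, c_px[2] + hy)))
}

#' Append a scored sample to the trajectory
#'
#' Frames on which the tracker is LOST carry no pose; they are skipped with
#' a warning (class `bccmap_lost_frame`) and the trajectory is unchanged.
#'
#' @param traj A `margin_trajectory`.
#' @param pose The tracker's effective pose for the frame (surface ->
#'   reference, from [step_tracker()]), or `NULL` when LOST.
#' @param marker Marker geometry ([marker_line()] / [marker_rect()]).
#' @param score BCC score in `[0, 100]`.
#' @param frame_index Acquisition order index.
#' @return The grown (or unchanged) trajectory.
#' @export
record_sample <- function(traj, pose, marker, score, frame_index) {
  if (is.null(pose)) {
    warning(warningCondition(
      sprintf("frame %d skipped: tracker LOST, no effective pose",
              frame_index),
      class = "bccmap_lost_frame"))
    return(traj)
  }
  stopifnot(score >= 0, score <= 100)
  src <- attr(pose, "source")
  traj$samples[[length(traj$samples) + 1]] <- list(
    frame_index = as.integer(frame_index), pose = pose, marker = marker,
    score = as.numeric(score),
    source = if (is.null(src)) "global" else src)
  traj
}

# clock-frame angle in [0, 2*pi): 12 o'clock = -y, clockwise positive
clock_angle <- function(pts, center) {
  dx <- pts[, 1] - center[1]; dy <- pts[, 2] - center[2]
  (atan2(dx, -dy)) %% (2 * pi)
}

clock_quadrant <- function(angle) {
  q <- findInterval(angle %% (2 * pi), c(0, pi / 2, pi, 3 * pi / 2))
  c("12-3", "3-6", "6-9", "9-12")[q]
}

# ---- raster drawing helpers (deterministic, base R) ---------------------

set_px <- function(img, x, y, col, width = 2) {
  h <- dim(img)[1]; w <- dim(img)[2]
  off <- if (width >= 2) expand.grid(dx = -1:1, dy = -1:1) else
    data.frame(dx = 0, dy = 0)
  if (width == 2) off <- off[abs(off$dx) + abs(off$dy) <= 1, ]
  for (k in seq_len(nrow(off))) {
    xi <- round(x) + off$dx[k] + 1
    yi <- round(y) + off$dy[k] + 1
    keep <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    if (!any(keep)) next
    for (c in 1:3)
      img[cbind(yi[keep], xi[keep], c)] <- col[c]
  }
  img
}

draw_segment <- function(img, p0, p1, col, width = 2, dashed = FALSE,
                         dash_len = 4) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len / 0.5) + 1L)
  tt <- seq(0, 1, length.out = n)
  xs <- p0[1] + tt * (p1[1] - p0[1])
  ys <- p0[2] + tt * (p1[2] - p0[2])
  if (dashed) {
    # dashes counted outward from the segment center so the centroid is
    # always drawn (color-probe invariant holds for coasting samples too)
    s <- abs(tt - 0.5) * len
    on <- (floor(s / dash_len) %% 2) == 0
    xs <- xs[on]; ys <- ys[on]
  }
  set_px(img, xs, ys, col, width)
}

draw_circle <- function(img, center, radius, col, width = 2) {
  n <- max(16L, ceiling(2 * pi * radius))
  a <- seq(0, 2 * pi, length.out = n)
  set_px(img, center[1] + radius * cos(a), center[2] + radius * sin(a),
         col, width)
}

col_to_rgb01 <- function(col) as.numeric(grDevices::col2rgb(col)) / 255

# marker segments (as list of 2x2 matrices) after applying a pose
marker_segments <- function(marker, pose) {
  pts <- transform_points(pose, marker$points)
  if (marker$type == "line") list(pts)
  else lapply(1:4, function(i) pts[c(i, i %% 4 + 1), , drop = FALSE])
}

marker_centroid <- function(marker, pose) {
  colMeans(transform_points(pose, marker$points))
}

#' Render the color-coded acquisition path
#'
#' Draws every sample's marker at its tracked position, stroked in
#' [score_to_color()] of its score; consecutive samples closer than two FOV
#' radii are joined by straight segments with linearly interpolated color,
#' larger jumps are left unconnected.  Samples whose pose was extrapolated
#' (coasting) are drawn dashed.  The latest sample additionally receives
#' the circular FOV outline and an arrow showing probe orientation.
#' Rendering is deterministic.
#'
#' @param image Dermoscopy RGB array (or grayscale matrix) in `[0, 1]`.
#' @param traj A non-empty `margin_trajectory`.
#' @param calib_surface,calib_reference Calibration profiles (for the FOV
#'   radius).
#' @return The annotated `h x w x 3` RGB array.
#' @export
render_overlay <- function(image, traj, calib_surface, calib_reference) {
  if (length(traj$samples) == 0)
    bcc_error("bccmap_bad_input", "trajectory is empty")
  img <- if (is.matrix(image)) array(rep(image, 3), c(dim(image), 3)) else image
  s <- scale_factor(calib_surface, calib_reference)
  fov_r <- s * min(calib_surface$image_shape) / 2
  cents <- t(vapply(traj$samples, function(sm)
    marker_centroid(sm$marker, sm$pose), numeric(2)))
  # path segments first (so markers draw on top)
  if (nrow(cents) > 1) {
    for (i in seq_len(nrow(cents) - 1)) {
      d <- sqrt(sum((cents[i + 1, ] - cents[i, ])^2))
      if (d >= 2 * fov_r) next
      s0 <- traj$samples[[i]]$score; s1 <- traj$samples[[i + 1]]$score
      nseg <- max(2L, ceiling(d / 3))
      tt <- seq(0, 1, length.out = nseg + 1)
      for (k in seq_len(nseg)) {
        col <- score_to_color(s0 + (tt[k] + tt[k + 1]) / 2 * (s1 - s0))[1, ] / 255
        img <- draw_segment(img,
                            cents[i, ] + tt[k] * (cents[i + 1, ] - cents[i, ]),
                            cents[i, ] + tt[k + 1] * (cents[i + 1, ] - cents[i, ]),
                            col, width = 1)
      }
    }
  }
  for (i in seq_along(traj$samples)) {
    sm <- traj$samples[[i]]
    col <- score_to_color(sm$score)[1, ] / 255
    dashed <- identical(sm$source, "extrapolated")
    for (seg in marker_segments(sm$marker, sm$pose))
      img <- draw_segment(img, seg[1, ], seg[2, ], col, width = 2,
                          dashed = dashed)
  }
  # live marker: FOV circle + orientation arrow on the newest sample
  last <- traj$samples[[length(traj$samples)]]
  fov_center <- transform_points(last$pose,
                                 s * (calib_surface$image_shape - 1) / 2)[1, ]
  white <- c(1, 1, 1)
  img <- draw_circle(img, fov_center, fov_r, white, width = 1)
  tip <- transform_points(last$pose,
                          rbind(s * (calib_surface$image_shape - 1) / 2 -
                                  c(0, 0.8 * fov_r)))[1, ]
  # arrow shaft starts off-center so the marker centroid keeps its score color
  shaft0 <- fov_center + 0.35 * (tip - fov_center)
  img <- draw_segment(img, shaft0, tip, white, width = 1)
  for (wing in c(-1, 1)) {
    ang <- atan2(tip[2] - fov_center[2], tip[1] - fov_center[1])
    w_ang <- ang + pi + wing * pi / 7
    img <- draw_segment(img, tip,
                        tip + 0.25 * fov_r * c(cos(w_ang), sin(w_ang)),
                        white, width = 1)
  }
  clamp01(img)
}

#' Per-quadrant margin coverage report
#'
#' Measures, for each clock quadrant, the fraction of the marked margin
#' path lying within `gap_tol_mm` of any recorded acquisition marker, and
#' lists the uncovered arcs (gaps) that remain.  This mirrors the clinical
#' requirement of imaging sequentially along the inked margins of every
#' quadrant without leaving gaps.
#'
#' @param traj A `margin_trajectory`.
#' @param margin_path `n x 2` matrix of reference-px vertices of the marked
#'   margin, forming a closed simple polyline (last vertex equal to the
#'   first, or it is an error of class `bccmap_open_path`).
#' @param gap_tol_mm Capture distance in mm.
#' @param calib_reference Reference calibration (converts the tolerance to
#'   px and gap lengths back to mm).
#' @return List with `coverage` (named fractions for `12-3`, `3-6`, `6-9`,
#'   `9-12`) and `gaps` (data frame: quadrant, start/end clock angle in
#'   radians, arc length in mm).
#' @export
coverage_report <- function(traj, margin_path, gap_tol_mm,
                            calib_reference) {
  if (nrow(margin_path) < 4 ||
      sqrt(sum((margin_path[1, ] - margin_path[nrow(margin_path), ])^2)) > 1e-6)
    bcc_error("bccmap_open_path",
              "margin path must be closed (last vertex equal to the first)")
  pitch_mm <- mean(calib_reference$pixel_pitch) / 1000
  tol_px <- gap_tol_mm / pitch_mm
  # densify the path: points every ~ tol/5 px, tracking arc length
  pts <- NULL; seglen <- NULL
  for (i in seq_len(nrow(margin_path) - 1)) {
    p0 <- margin_path[i, ]; p1 <- margin_path[i + 1, ]
    len <- sqrt(sum((p1 - p0)^2))
    n <- max(1L, ceiling(len / max(tol_px / 5, 0.5)))
    tt <- (seq_len(n) - 0.5) / n
    pts <- rbind(pts, cbind(p0[1] + tt * (p1[1] - p0[1]),
                            p0[2] + tt * (p1[2] - p0[2])))
    seglen <- c(seglen, rep(len / n, n))
  }
  quad <- clock_quadrant(clock_angle(pts, traj$center))
  covered <- rep(FALSE, nrow(pts))
  if (length(traj$samples)) {
    segs <- do.call(c, lapply(traj$samples, function(sm)
      marker_segments(sm$marker, sm$pose)))
    for (seg in segs) {
      a <- seg[1, ]; b <- seg[2, ]
      ab <- b - a
      ab2 <- sum(ab^2)
      tt <- if (ab2 < 1e-12) rep(0, nrow(pts)) else
        pmin(pmax(((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / ab2,
                  0), 1)
      dx <- pts[, 1] - (a[1] + tt * ab[1])
      dy <- pts[, 2] - (a[2] + tt * ab[2])
      covered <- covered | (dx * dx + dy * dy <= tol_px^2)
      if (all(covered)) break
    }
  }
  qnames <- c("12-3", "3-6", "6-9", "9-12")
  coverage <- vapply(qnames, function(q) {
    sel <- quad == q
    if (!any(sel)) return(NA_real_)
    sum(seglen[sel & covered]) / sum(seglen[sel])
  }, numeric(1))
  # gaps: maximal uncovered runs along the (cyclic) path
  gaps <- data.frame(quadrant = character(), start_angle = numeric(),
                     end_angle = numeric(), length_mm = numeric(),
                     stringsAsFactors = FALSE)
  if (any(!covered)) {
    runs <- rle(!covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    ang <- clock_angle(pts, traj$center)
    for (k in which(runs$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      gaps <- rbind(gaps, data.frame(
        quadrant = clock_quadrant(ang[i0]),
        start_angle = ang[i0], end_angle = ang[i1],
        length_mm = sum(seglen[i0:i1]) * pitch_mm,
        stringsAsFactors = FALSE))
    }
    # merge the wrap-around gap (first and last run both uncovered)
    if (length(runs$values) > 1 && runs$values[1] && runs$values[length(runs$values)]) {
      n <- nrow(gaps)
      gaps$length_mm[1] <- gaps$length_mm[1] + gaps$length_mm[n]
      gaps$start_angle[1] <- gaps$start_angle[n]
      gaps <- gaps[-n, , drop = FALSE]
    }
  }
  list(coverage = coverage, gaps = gaps)
}
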