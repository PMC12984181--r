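#' Incremental dermoscopic mosaicking
#'
#' Builds a wide-field composite from overlapping dermoscopic frames when a
#' lesion exceeds a single field of view.  Each newly acquired frame is
#' registered (same keypoint + RANSAC pipeline, dermoscope-to-dermoscope,
#' scale 1) against the *current composite* - not pairwise against the
#' previous frame - and blended in with linear distance-to-edge feathering.
#' Up to `config$mosaic_max_frames` (default 40) frames can be stitched.
#'
#' @param first_frame Matrix or RGB array in `[0, 1]`.
#' @param config A [bcc_config()].
#' @return `mosaic_start()` returns a `dermoscopy_mosaic` with one frame at
#'   the identity pose whose canvas equals the input bit-exactly.
#' @export
mosaic_start <- function(first_frame, config = bcc_config()) {
  d <- dim(first_frame)
  nc <- if (is_rgb(first_frame)) 3L else 1L
  m <- structure(list(
    frames = list(list(pose = pose_identity())),
    origin = c(0, 0),              # canvas px of first-frame origin
    canvas = first_frame,
    acc = NULL,                    # feathered accumulators, built lazily
    composite_features = NULL,
    frame_shape = c(d[2], d[1]),
    n_channels = nc,
    config = config
  ), class = "dermoscopy_mosaic")
  m$composite_features <- init_reference(first_frame, config)
  m
}

#' @export
print.dermoscopy_mosaic <- function(x, ...) {
  d <- dim(x$canvas)
  cat(sprintf("<dermoscopy_mosaic> %d frame(s), canvas %d x %d px, cap %d\n",
              mosaic_count(x), d[2], d[1], x$config$mosaic_max_frames))
  invisible(x)
}

#' @rdname mosaic_start
#' @param m A `dermoscopy_mosaic`.
#' @export
mosaic_count <- function(m) length(m$frames)

# lazily build the weighted accumulators from the stored first frame
ensure_acc <- function(m) {
  if (!is.null(m$acc)) return(m)
  d <- dim(m$canvas)
  first <- m$canvas
  patch <- cpp_warp_patch(as.numeric(first), as.integer(dim(first)),
                          0, 0, 0, 0L, 0L, d[2], d[1])
  m$acc <- list(wval = patch$wval, w = patch$w)
  m
}

mosaic_register <- function(m, frame, seed) {
  feats <- tryCatch(init_reference(frame, m$config),
                    bccmap_empty_reference = function(e) e)
  if (inherits(feats, "condition"))
    return(registration_result(NULL, 0L, integer(), FALSE,
                               reason = conditionMessage(feats)))
  matches <- match_nearest(feats, m$composite_features, m$config)
  if (nrow(matches$pairs) < 2)
    return(registration_result(NULL, 0L, integer(), FALSE,
                               reason = "fewer than 2 matches"))
  qpos <- feats$keypoints[matches$pairs[, 1], 1:2, drop = FALSE]
  rpos <- m$composite_features$keypoints[matches$pairs[, 2], 1:2,
                                         drop = FALSE]
  est <- tryCatch(
    estimate_rigid(qpos, rpos, tol_px = m$config$ransac_inlier_tol_px,
                   max_iters = m$config$ransac_max_iters, seed = seed),
    bccmap_degenerate_geometry = function(e) NULL)
  if (is.null(est))
    return(registration_result(NULL, 0L, integer(), FALSE,
                               reason = "degenerate geometry"))
  registration_result(est$pose, length(est$inliers), est$inliers,
                      gate_reliability(length(est$inliers), m$config),
                      n_matches = nrow(matches$pairs))
}

#' Stitch one more frame into a mosaic
#'
#' Registers `frame` against the current composite, stores its pose in
#' first-frame coordinates, expands the canvas to the union of transformed
#' frame rectangles and re-blends.  Composite keypoints are recomputed after
#' insertion so subsequent frames register against the updated mosaic.
#'
#' @param m A `dermoscopy_mosaic`.
#' @param frame Matrix or RGB array, same shape as the first frame.
#' @param seed Integer seed for the RANSAC draw.
#' @return The grown `dermoscopy_mosaic`.  Errors: class
#'   `bccmap_mosaic_full` when the frame cap is already reached, and class
#'   `bccmap_insufficient_overlap` when the reliability gate rejects the
#'   registration.
#' @export
mosaic_add <- function(m, frame, seed = 1L) {
  if (mosaic_count(m) >= m$config$mosaic_max_frames)
    bcc_error("bccmap_mosaic_full",
              sprintf("mosaic already holds the maximum of %d frames",
                      m$config$mosaic_max_frames))
  reg <- mosaic_register(m, frame, seed)
  if (!reg$accepted)
    bcc_error("bccmap_insufficient_overlap",
              sprintf("frame rejected by the reliability gate (%d inliers%s)",
                      reg$inlier_count,
                      if (is.null(reg$reason)) "" else
                        paste0("; ", reg$reason)))
  m <- ensure_acc(m)
  d <- dim(frame)
  # pose maps frame px -> current canvas px; store in first-frame coords
  pose_canvas <- reg$pose
  pose_first <- rigid_pose(pose_canvas$theta,
                           pose_canvas$t[1] - m$origin[1],
                           pose_canvas$t[2] - m$origin[2])
  corners <- transform_points(pose_canvas,
                              rbind(c(0, 0), c(d[2] - 1, 0),
                                    c(0, d[1] - 1), c(d[2] - 1, d[1] - 1)))
  dc <- dim(m$acc$w)
  x0 <- min(0, floor(min(corners[, 1])))
  y0 <- min(0, floor(min(corners[, 2])))
  x1 <- max(dc[2] - 1, ceiling(max(corners[, 1])))
  y1 <- max(dc[1] - 1, ceiling(max(corners[, 2])))
  new_w <- x1 - x0 + 1; new_h <- y1 - y0 + 1
  if (x0 < 0 || y0 < 0 || new_w > dc[2] || new_h > dc[1]) {
    # grow accumulators; existing content shifts by (-x0, -y0)
    wval <- array(0, c(new_h, new_w, m$n_channels))
    w <- matrix(0, new_h, new_w)
    ys <- (1:dc[1]) - y0; xs <- (1:dc[2]) - x0
    old_wval <- m$acc$wval
    if (length(dim(old_wval)) == 2) old_wval <- array(old_wval, c(dc, 1))
    wval[ys, xs, ] <- old_wval
    w[ys, xs] <- m$acc$w
    m$acc <- list(wval = wval, w = w)
    m$origin <- m$origin - c(x0, y0)
    pose_canvas <- rigid_pose(pose_canvas$theta,
                              pose_canvas$t[1] - x0, pose_canvas$t[2] - y0)
  }
  # blend the new frame into the accumulators over its bounding box
  dc <- dim(m$acc$w)
  bx0 <- max(0, floor(min(corners[, 1]) - x0))
  by0 <- max(0, floor(min(corners[, 2]) - y0))
  bx1 <- min(dc[2] - 1, ceiling(max(corners[, 1]) - x0))
  by1 <- min(dc[1] - 1, ceiling(max(corners[, 2]) - y0))
  patch <- cpp_warp_patch(as.numeric(frame), as.integer(dim(frame)),
                          pose_canvas$theta, pose_canvas$t[1],
                          pose_canvas$t[2], as.integer(bx0), as.integer(by0),
                          as.integer(bx1 - bx0 + 1),
                          as.integer(by1 - by0 + 1))
  ys <- (by0 + 1):(by1 + 1); xs <- (bx0 + 1):(bx1 + 1)
  pv <- patch$wval
  if (length(dim(pv)) == 2) pv <- array(pv, c(dim(pv), 1))
  m$acc$wval[ys, xs, ] <- m$acc$wval[ys, xs, , drop = FALSE] + pv
  m$acc$w[ys, xs] <- m$acc$w[ys, xs] + patch$w
  m$frames[[length(m$frames) + 1]] <-
    list(pose = pose_first, inlier_count = reg$inlier_count)
  m$canvas <- mosaic_render(m)
  m$composite_features <- init_reference(m$canvas, m$config)
  m
}

#' Render the mosaic composite
#'
#' Deterministic: the composite is the feather-weighted average of all
#' stitched frames; pixels covered by a single frame reproduce that frame
#' (up to interpolation at subpixel poses).
#'
#' @param m A `dermoscopy_mosaic`.
#' @return The composite image (matrix or `h x w x 3` array in `[0, 1]`).
#' @export
mosaic_render <- function(m) {
  if (is.null(m$acc)) return(m$canvas)
  w <- m$acc$w
  w_safe <- ifelse(w > 0, w, 1)
  out <- m$acc$wval
  for (c in seq_len(dim(out)[3])) out[, , c] <- clamp01(out[, , c] / w_safe)
  if (m$n_channels == 1) out <- out[, , 1]
  out
}

#' Live field-of-view marker relative to the first frame
#'
#' Registers a live dermoscopic frame against the current composite and, if
#' the reliability gate accepts, returns the live FOV rectangle in
#' first-frame coordinates together with the fraction of the live FOV that
#' overlaps already-covered canvas (coverage guidance for the operator).
#'
#' @param m A `dermoscopy_mosaic`.
#' @param live_frame Matrix or RGB array, same shape as the mosaic frames.
#' @param seed Integer seed for the RANSAC draw.
#' @return `NULL` when the gate rejects; otherwise a list with `pose`
#'   (frame -> first-frame coords), `rect` (4 x 2 matrix of transformed
#'   frame corners) and `overlap` (fraction in `[0, 1]`).
#' @export
mosaic_live_position <- function(m, live_frame, seed = 1L) {
  reg <- mosaic_register(m, live_frame, seed)
  if (!reg$accepted) return(NULL)
  d <- dim(live_frame)
  pose_canvas <- reg$pose
  pose_first <- rigid_pose(pose_canvas$theta,
                           pose_canvas$t[1] - m$origin[1],
                           pose_canvas$t[2] - m$origin[2])
  rect <- transform_points(pose_first,
                           rbind(c(0, 0), c(d[2] - 1, 0),
                                 c(d[2] - 1, d[1] - 1), c(0, d[1] - 1)))
  # overlap: fraction of live-frame samples landing on covered canvas
  m <- ensure_acc(m)
  step <- 4
  gx <- seq(0, d[2] - 1, by = step); gy <- seq(0, d[1] - 1, by = step)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  cpts <- transform_points(pose_canvas, pts)
  ix <- round(cpts[, 1]) + 1; iy <- round(cpts[, 2]) + 1
  dc <- dim(m$acc$w)
  inside <- ix >= 1 & ix <= dc[2] & iy >= 1 & iy <= dc[1]
  covered <- logical(nrow(pts))
  covered[inside] <- m$acc$w[cbind(iy[inside], ix[inside])] > 0
  list(pose = pose_first, rect = rect, overlap = mean(covered),
       inlier_count = reg$inlier_count)
}
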