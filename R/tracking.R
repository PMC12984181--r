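#' Inter-frame motion estimation on the surface stream
#'
#' Estimates the rigid motion between two successive surface frames with the
#' same keypoint / descriptor / RANSAC machinery used for global
#' co-localization, at the raw surface scale.  The inlier count of the fit
#' serves as a tracking confidence score.
#'
#' @param prev_frame,cur_frame Matrices or RGB arrays of identical shape.
#' @param config A [bcc_config()].
#' @param seed Integer seed for the RANSAC draw.
#' @return List with `delta` (a [rigid_pose()] mapping previous-frame pixel
#'   coordinates to current-frame pixel coordinates, or `NULL`) and
#'   `confidence` (inlier count; 0 on textureless frames).
#' @export
interframe_motion <- function(prev_frame, cur_frame, config = bcc_config(),
                              seed = 1L) {
  if (!identical(dim(prev_frame)[1:2], dim(cur_frame)[1:2]))
    bcc_error("bccmap_bad_input", "frames must have the same shape")
  detect_masked <- function(fr) {
    g <- apply_circle_mask(luminance(fr))
    ks <- detect_keypoints(g, config)
    if (n_keypoints(ks) > 0) {
      d <- dim(g)
      cx <- (d[2] - 1) / 2; cy <- (d[1] - 1) / 2
      rmax <- min(d) / 2
      kp <- ks$keypoints
      r <- sqrt((kp[, 1] - cx)^2 + (kp[, 2] - cy)^2)
      ks <- subset_keypoints(ks, r <= rmax - pmax(6, 3 * kp[, 3]))
    }
    ks
  }
  kp_prev <- detect_masked(prev_frame)
  kp_cur <- detect_masked(cur_frame)
  if (n_keypoints(kp_prev) < 2 || n_keypoints(kp_cur) < 2)
    return(list(delta = NULL, confidence = 0L))
  # delta maps prev -> cur, so the previous frame is the query
  matches <- match_nearest(kp_prev, kp_cur, config)
  if (nrow(matches$pairs) < 2)
    return(list(delta = NULL, confidence = 0L))
  qpos <- kp_prev$keypoints[matches$pairs[, 1], 1:2, drop = FALSE]
  rpos <- kp_cur$keypoints[matches$pairs[, 2], 1:2, drop = FALSE]
  est <- tryCatch(
    estimate_rigid(qpos, rpos, tol_px = config$ransac_inlier_tol_px,
                   max_iters = config$ransac_max_iters, seed = seed),
    bccmap_degenerate_geometry = function(e) NULL)
  if (is.null(est)) return(list(delta = NULL, confidence = 0L))
  list(delta = est$pose, confidence = length(est$inliers))
}

#' Tracker state for the LOCKED / COASTING / LOST machine
#'
#' While global co-localization succeeds the tracker is `LOCKED` and simply
#' relays the registered pose.  When the reliability gate rejects a frame
#' but inter-frame motion is confident, the tracker `COASTING`s: it
#' extrapolates the last reliable pose through the accumulated inter-frame
#' deltas (dead reckoning).  When that confidence collapses too - typically
#' lost probe contact or too-fast motion - temporal tracking is reset and
#' the state is `LOST` until a registration succeeds again.
#'
#' @return `tracker_init()` returns a fresh `tracker_state` (status
#'   `"LOST"`, no reliable pose).
#' @export
tracker_init <- function() {
  structure(list(status = "LOST", last_reliable_pose = NULL,
                 cumulative_delta = pose_identity(), frames_coasted = 0L),
            class = "tracker_state")
}

#' @export
print.tracker_state <- function(x, ...) {
  cat(sprintf("<tracker_state> %s%s\n", x$status,
              if (x$status == "COASTING")
                sprintf(" (%d frames coasted)", x$frames_coasted) else ""))
  invisible(x)
}

#' Advance the tracker by one frame
#'
#' @param state A `tracker_state`.
#' @param reg The frame's `registration_result` (from [colocalize()]), or
#'   `NULL` when global registration was not attempted.
#' @param delta_result Result of [interframe_motion()] for this frame (or
#'   `NULL`).  The delta is expressed at raw surface scale and is converted
#'   through `scale` internally.
#' @param config A [bcc_config()].
#' @param scale Scale factor from raw surface pixels to reference pixels
#'   (see [scale_factor()]).
#' @return List with `state` (updated `tracker_state`) and `pose` (the
#'   effective surface -> reference pose, or `NULL` when `LOST`).  The
#'   emitted pose carries attribute `source`: `"global"` when locked,
#'   `"extrapolated"` when coasting.  A successful registration always
#'   resets accumulated drift and is emitted unblended.
#' @export
step_tracker <- function(state, reg, delta_result = NULL,
                         config = bcc_config(), scale = 1) {
  if (!is.null(reg) && isTRUE(reg$accepted)) {
    state$status <- "LOCKED"
    state$last_reliable_pose <- reg$pose
    state$cumulative_delta <- pose_identity()
    state$frames_coasted <- 0L
    pose <- reg$pose
    attr(pose, "source") <- "global"
    return(list(state = state, pose = pose))
  }
  confident <- !is.null(delta_result) && !is.null(delta_result$delta) &&
    delta_result$confidence > config$tracking_confidence_threshold
  can_coast <- !is.null(state$last_reliable_pose) && state$status != "LOST" &&
    state$frames_coasted < config$tracking_max_coast
  if (confident && can_coast) {
    # conjugate the raw-surface-scale delta into reference-scale units
    d <- delta_result$delta
    d_ref <- rigid_pose(d$theta, scale * d$t[1], scale * d$t[2])
    # deltas accumulate right-to-left (oldest first)
    state$cumulative_delta <- pose_compose(d_ref, state$cumulative_delta)
    state$frames_coasted <- state$frames_coasted + 1L
    state$status <- "COASTING"
    pose <- pose_compose(state$last_reliable_pose,
                         pose_invert(state$cumulative_delta))
    attr(pose, "source") <- "extrapolated"
    return(list(state = state, pose = pose))
  }
  # temporal tracking is reset
  state$status <- "LOST"
  state$last_reliable_pose <- NULL
  state$cumulative_delta <- pose_identity()
  state$frames_coasted <- 0L
  list(state = state, pose = NULL)
}
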