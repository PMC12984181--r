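#' Keypoint detection
#'
#' Detects scale- and rotation-invariant keypoints and computes 128-element
#' gradient-histogram descriptors, using a difference-of-Gaussian scale-space
#' pyramid with subpixel refinement, edge-response rejection and
#' dominant-orientation assignment.  Detection is deterministic: the same
#' image and settings always yield the same keypoints.
#'
#' @param img Grayscale matrix or RGB array in `[0, 1]` (RGB is reduced to
#'   luminance first; see [luminance()]).
#' @param config A [bcc_config()] providing the detector settings.
#' @return A `keypoint_set`: list with `keypoints` (n x 5 matrix: `x`, `y`,
#'   `sigma`, `angle`, `response`; 0-based pixel coords) and `descriptors`
#'   (n x 128 matrix, unit-normalized).
#' @export
detect_keypoints <- function(img, config = bcc_config()) {
  g <- luminance(img)
  res <- cpp_detect_features(g,
                             contrast_thresh = config$detector_contrast,
                             edge_thresh = config$detector_edge,
                             sigma0 = config$detector_sigma0,
                             n_scales = as.integer(config$detector_scales))
  structure(list(keypoints = res$keypoints, descriptors = res$descriptors,
                 image_shape = c(ncol(g), nrow(g))),
            class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set> %d keypoints (image %d x %d px)\n",
              nrow(x$keypoints), x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

n_keypoints <- function(ks) nrow(ks$keypoints)

subset_keypoints <- function(ks, idx) {
  structure(list(keypoints = ks$keypoints[idx, , drop = FALSE],
                 descriptors = ks$descriptors[idx, , drop = FALSE],
                 image_shape = ks$image_shape),
            class = "keypoint_set")
}

#' Initialize the wide-field reference
#'
#' Runs keypoint detection on the dermoscopy reference image (or mosaic
#' composite).  This is the one-off initialization of the co-localization
#' pipeline; every incoming surface frame is then matched against the
#' returned features.
#'
#' @param reference_image Grayscale matrix or RGB array in `[0, 1]`, minimum
#'   dimension 64 px.
#' @param config A [bcc_config()].
#' @param mask Optional logical matrix; keypoints outside it are discarded.
#' @return A `keypoint_set`.  Errors with class `bccmap_empty_reference`
#'   when no keypoint is found (e.g. a flat, textureless image).
#' @export
init_reference <- function(reference_image, config = bcc_config(),
                           mask = NULL) {
  d <- dim(reference_image)
  if (min(d[1], d[2]) < 64)
    bcc_error("bccmap_bad_input", "reference image must be at least 64 px")
  ks <- detect_keypoints(reference_image, config)
  if (!is.null(mask) && n_keypoints(ks) > 0) {
    kp <- ks$keypoints
    keep <- mask[cbind(pmin(pmax(round(kp[, 2]) + 1, 1), d[1]),
                       pmin(pmax(round(kp[, 1]) + 1, 1), d[2]))]
    ks <- subset_keypoints(ks, keep)
  }
  if (n_keypoints(ks) == 0)
    bcc_error("bccmap_empty_reference",
              "no keypoints found in reference image")
  ks
}

#' Extract features from a circular surface frame
#'
#' The surface frame is first resampled to the reference pixel pitch
#' ([scale_factor()]; bicubic interpolation), because the registration model
#' has no scale term, then masked to its inscribed circular FOV.  Keypoints
#' too close to the mask boundary are discarded, and keypoint positions are
#' reported at the reference scale.
#'
#' @param surface_frame Matrix or RGB array matching `calib_surface`'s pixel
#'   shape, values in `[0, 1]`.
#' @param calib_surface,calib_reference `calibration_profile`s of the frame
#'   and of the reference image.
#' @param config A [bcc_config()].
#' @return A `keypoint_set` at reference scale.  Errors with class
#'   `bccmap_empty_frame` when nothing is detected (e.g. a blank frame).
#' @export
extract_surface_features <- function(surface_frame, calib_surface,
                                     calib_reference,
                                     config = bcc_config()) {
  d <- dim(surface_frame)
  if (d[1] != calib_surface$image_shape[2] ||
      d[2] != calib_surface$image_shape[1])
    bcc_error("bccmap_bad_input",
              sprintf("frame is %d x %d px but surface calibration says %d x %d",
                      d[2], d[1], calib_surface$image_shape[1],
                      calib_surface$image_shape[2]))
  s <- scale_factor(calib_surface, calib_reference)
  g <- luminance(surface_frame)
  g <- resample_image(g, s)
  g <- apply_circle_mask(g)
  ks <- detect_keypoints(g, config)
  if (n_keypoints(ks) > 0) {
    # drop detections riding on the artificial mask boundary
    d2 <- dim(g)
    cx <- (d2[2] - 1) / 2; cy <- (d2[1] - 1) / 2
    rmax <- min(d2) / 2
    kp <- ks$keypoints
    r <- sqrt((kp[, 1] - cx)^2 + (kp[, 2] - cy)^2)
    keep <- r <= rmax - pmax(6, 3 * kp[, 3])
    ks <- subset_keypoints(ks, keep)
  }
  if (n_keypoints(ks) == 0)
    bcc_error("bccmap_empty_frame", "no keypoints found in surface frame")
  ks
}

#' Nearest-descriptor matching
#'
#' Associates every query descriptor with the reference descriptor at
#' minimum Euclidean distance (plain one-way nearest neighbor; ties broken
#' by the lowest reference index).  An optional symmetric cross-check filter
#' (`config$match_cross_check`) keeps only mutual nearest neighbors; it is
#' off by default.
#'
#' @param query,reference `keypoint_set`s (both non-empty).
#' @return A `match_set`: list with `pairs` (n x 2 matrix of 1-based query /
#'   reference indices) and `distance` (descriptor distances, >= 0).
#' @export
match_nearest <- function(query, reference, config = bcc_config()) {
  if (n_keypoints(query) == 0 || n_keypoints(reference) == 0)
    bcc_error("bccmap_bad_input", "cannot match empty keypoint sets")
  qd <- query$descriptors; rd <- reference$descriptors
  d2 <- outer(rowSums(qd^2), rowSums(rd^2), "+") - 2 * tcrossprod(qd, rd)
  nn <- max.col(-d2, ties.method = "first")
  dist <- sqrt(pmax(d2[cbind(seq_len(nrow(qd)), nn)], 0))
  keep <- rep(TRUE, nrow(qd))
  if (isTRUE(config$match_cross_check)) {
    back <- apply(d2, 2, which.min)   # best query for each reference
    keep <- back[nn] == seq_len(nrow(qd))
  }
  structure(list(pairs = cbind(query = which(keep), reference = nn[keep]),
                 distance = dist[keep]),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set> %d pairs, median descriptor distance %.3f\n",
              nrow(x$pairs), stats::median(x$distance)))
  invisible(x)
}

# closed-form least-squares rotation + translation (2-D Procrustes/Kabsch),
# reflection excluded by construction
procrustes_rigid <- function(qpos, rpos) {
  qc <- colMeans(qpos); rc <- colMeans(rpos)
  qq <- sweep(qpos, 2, qc); rr <- sweep(rpos, 2, rc)
  theta <- atan2(sum(qq[, 1] * rr[, 2] - qq[, 2] * rr[, 1]),
                 sum(qq[, 1] * rr[, 1] + qq[, 2] * rr[, 2]))
  ct <- cos(theta); st <- sin(theta)
  t <- rc - c(ct * qc[1] - st * qc[2], st * qc[1] + ct * qc[2])
  rigid_pose(theta, t[1], t[2])
}

pose_residuals <- function(pose, qpos, rpos) {
  pred <- transform_points(pose, qpos)
  sqrt(rowSums((pred - rpos)^2))
}

#' RANSAC rigid-transform estimation
#'
#' Estimates the rotation + translation best aligning matched keypoint
#' positions, robust to mismatches.  Minimal samples of two point pairs are
#' drawn for `max_iters` hypotheses; the hypothesis with the most inliers
#' (residual below `tol_px`) wins, is refined by closed-form least-squares
#' rotation + translation (2-D Procrustes) over its inlier set, and pairs
#' not conforming to the refined transform are discarded.  Reflections are
#' excluded: the estimate is always a proper rotation.
#'
#' @param qpos,rpos `n x 2` matrices of matched query / reference positions
#'   (same scale), `n >= 2`.
#' @param tol_px Inlier residual tolerance in pixels.
#' @param max_iters Number of RANSAC hypotheses.
#' @param seed Integer seed making the estimate reproducible.
#' @return List with `pose` (a [rigid_pose()]: query -> reference) and
#'   `inliers` (indices of conforming pairs).  Errors with class
#'   `bccmap_degenerate_geometry` when every sampled pair is coincident.
#' @export
estimate_rigid <- function(qpos, rpos, tol_px = 3, max_iters = 2000,
                           seed = 1L) {
  stopifnot(nrow(qpos) == nrow(rpos), ncol(qpos) == 2, ncol(rpos) == 2)
  n <- nrow(qpos)
  if (n < 2)
    bcc_error("bccmap_bad_input", "need at least 2 matched pairs")
  max_iters <- as.integer(max_iters)
  sel <- with_seed(seed, {
    i1 <- sample.int(n, max_iters, replace = TRUE)
    i2 <- sample.int(n, max_iters, replace = TRUE)
    cbind(i1, i2)
  })
  dqx <- qpos[sel[, 2], 1] - qpos[sel[, 1], 1]
  dqy <- qpos[sel[, 2], 2] - qpos[sel[, 1], 2]
  drx <- rpos[sel[, 2], 1] - rpos[sel[, 1], 1]
  dry <- rpos[sel[, 2], 2] - rpos[sel[, 1], 2]
  valid <- (dqx^2 + dqy^2) > 1e-12 & (drx^2 + dry^2) > 1e-12
  if (!any(valid))
    bcc_error("bccmap_degenerate_geometry",
              "all sampled point pairs are coincident")
  a <- atan2(dry, drx) - atan2(dqy, dqx)
  ct <- cos(a); st <- sin(a)
  tx <- rpos[sel[, 1], 1] - (ct * qpos[sel[, 1], 1] - st * qpos[sel[, 1], 2])
  ty <- rpos[sel[, 1], 2] - (st * qpos[sel[, 1], 1] + ct * qpos[sel[, 1], 2])
  # residuals of every match under every hypothesis (n x max_iters)
  predx <- outer(qpos[, 1], ct) - outer(qpos[, 2], st) +
    matrix(tx, n, max_iters, byrow = TRUE)
  predy <- outer(qpos[, 1], st) + outer(qpos[, 2], ct) +
    matrix(ty, n, max_iters, byrow = TRUE)
  res2 <- (predx - rpos[, 1])^2 + (predy - rpos[, 2])^2
  ninl <- colSums(res2 < tol_px^2)
  ninl[!valid] <- -1L
  best <- which.max(ninl)
  if (ninl[best] < 2)
    bcc_error("bccmap_degenerate_geometry",
              "no hypothesis with at least 2 inliers")
  inl <- which(res2[, best] < tol_px^2)
  # refine: Procrustes over inliers, re-select, refine again
  for (pass in 1:2) {
    pose <- procrustes_rigid(qpos[inl, , drop = FALSE],
                             rpos[inl, , drop = FALSE])
    inl_new <- which(pose_residuals(pose, qpos, rpos) < tol_px)
    if (length(inl_new) < 2) break
    inl <- inl_new
  }
  list(pose = pose, inliers = inl)
}

#' Reliability gate on the inlier count
#'
#' A localization is regarded reliable only when the number of RANSAC
#' inliers is strictly above the configured threshold (default 6, i.e.
#' accept at 7 or more, reject at 6 or fewer).
#'
#' @param inlier_count Non-negative count.
#' @param config A [bcc_config()].
#' @return Logical: accepted?
#' @export
gate_reliability <- function(inlier_count, config = bcc_config()) {
  inlier_count > config$inlier_accept_threshold
}

registration_result <- function(pose, inlier_count, inlier_indices,
                                accepted, source = "global",
                                n_matches = NA_integer_, reason = NULL) {
  structure(list(pose = pose, inlier_count = as.integer(inlier_count),
                 inlier_indices = inlier_indices, accepted = accepted,
                 source = source, n_matches = n_matches, reason = reason),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %s (%s), inliers = %d%s\n",
              if (x$accepted) "ACCEPTED" else "REJECTED", x$source,
              x$inlier_count,
              if (!is.null(x$pose)) paste0(", pose ", format(x$pose)) else ""))
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Co-localize one surface frame within the reference
#'
#' Orchestrates the full per-frame pipeline: surface feature extraction
#' (scale-normalized, circular-masked), nearest-descriptor matching, RANSAC
#' rigid estimation and the inlier-count reliability gate.  Failures that
#' would kill a live stream (blank frame, no matches, degenerate geometry)
#' are converted into rejected results instead of errors.
#'
#' @param surface_frame Matrix or RGB array in `[0, 1]`.
#' @param reference_features `keypoint_set` from [init_reference()].
#' @param calib_surface,calib_reference `calibration_profile`s.
#' @param config A [bcc_config()].
#' @param seed Integer seed for the RANSAC draw.
#' @return A `registration_result` with fields `pose` (surface -> reference
#'   px at reference scale; `NULL` when nothing could be estimated),
#'   `inlier_count`, `inlier_indices`, `accepted` and `source = "global"`.
#'   A rejected result still carries the (unreliable) pose for diagnostics.
#' @export
colocalize <- function(surface_frame, reference_features, calib_surface,
                       calib_reference, config = bcc_config(), seed = 1L) {
  feats <- tryCatch(
    extract_surface_features(surface_frame, calib_surface, calib_reference,
                             config),
    bccmap_empty_frame = function(e) e)
  if (inherits(feats, "condition"))
    return(registration_result(NULL, 0L, integer(), FALSE,
                               reason = conditionMessage(feats)))
  matches <- match_nearest(feats, reference_features, config)
  if (nrow(matches$pairs) < 2)
    return(registration_result(NULL, 0L, integer(), FALSE,
                               n_matches = nrow(matches$pairs),
                               reason = "fewer than 2 matches"))
  qpos <- feats$keypoints[matches$pairs[, 1], 1:2, drop = FALSE]
  rpos <- reference_features$keypoints[matches$pairs[, 2], 1:2, drop = FALSE]
  est <- tryCatch(
    estimate_rigid(qpos, rpos, tol_px = config$ransac_inlier_tol_px,
                   max_iters = config$ransac_max_iters, seed = seed),
    bccmap_degenerate_geometry = function(e) e)
  if (inherits(est, "condition"))
    return(registration_result(NULL, 0L, integer(), FALSE,
                               n_matches = nrow(matches$pairs),
                               reason = conditionMessage(est)))
  registration_result(est$pose, length(est$inliers), est$inliers,
                      gate_reliability(length(est$inliers), config),
                      n_matches = nrow(matches$pairs))
}
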