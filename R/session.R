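#' Run the co-localization pipeline over a frame stream
#'
#' Executes, per frame and in order: global registration against the
#' reference ([colocalize()]), inter-frame motion against the previous
#' frame ([interframe_motion()]), the LOCKED / COASTING / LOST tracker
#' step, optional scoring, and trajectory recording.  Rejected frames are
#' data, not errors: the stream always runs to completion.
#'
#' @param reference Dermoscopy reference: an image array, a file path, or a
#'   `dermoscopy_mosaic` (its composite is used).
#' @param frames A list of frame arrays, or a directory of PNG/TIFF frames
#'   (read in lexicographic order).
#' @param calib_surface,calib_reference Calibration profiles.
#' @param config A [bcc_config()].
#' @param seed Integer master seed; per-frame RANSAC seeds are derived from
#'   it, so identical inputs + seed reproduce the session exactly.
#' @param score_fn Optional `function(frame, index) -> score` in `[0, 100]`
#'   (e.g. scoring a co-acquired B-scan); recorded per frame.
#' @param marker Marker geometry for the trajectory
#'   (default [marker_line()]).
#' @param lesion_center Lesion center `(x, y)` in reference px for the
#'   trajectory clock frame (default: reference image center).
#' @return A `bcc_session`: per-frame records (pose, inlier count, accepted
#'   flag, tracker status, score, source), the trajectory, config snapshot
#'   and seeds.
#' @export
run_colocalize_stream <- function(reference, frames, calib_surface,
                                  calib_reference, config = bcc_config(),
                                  seed = 1L, score_fn = NULL,
                                  marker = NULL, lesion_center = NULL) {
  ref_path <- NA_character_
  if (is.character(reference)) {
    ref_path <- reference
    reference <- read_image(reference)
  } else if (inherits(reference, "dermoscopy_mosaic")) {
    reference <- mosaic_render(reference)
  }
  frame_paths <- NULL
  if (is.character(frames)) {
    if (!dir.exists(frames))
      bcc_error("bccmap_bad_input",
                paste("frames directory not found:", frames))
    frame_paths <- sort(list.files(frames, pattern = "\\.(png|tiff?)$",
                                   full.names = TRUE, ignore.case = TRUE))
    if (!length(frame_paths))
      bcc_error("bccmap_bad_input",
                paste("no frames found in directory:", frames))
    frames <- lapply(frame_paths, read_image)
  }
  if (!length(frames))
    bcc_error("bccmap_bad_input", "empty frame list")
  ref_features <- init_reference(reference, config)
  s <- scale_factor(calib_surface, calib_reference)
  if (is.null(marker)) marker <- marker_line(calib_surface, calib_reference)
  if (is.null(lesion_center))
    lesion_center <- (dim(reference)[2:1] - 1) / 2
  traj <- trajectory_init(lesion_center)
  tracker <- tracker_init()
  records <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fseed <- (seed * 1000L + i) %% .Machine$integer.max
    reg <- colocalize(frames[[i]], ref_features, calib_surface,
                      calib_reference, config, seed = fseed)
    delta <- if (i > 1)
      interframe_motion(frames[[i - 1]], frames[[i]], config, seed = fseed)
    else NULL
    stepped <- step_tracker(tracker, reg, delta, config, scale = s)
    tracker <- stepped$state
    score <- if (!is.null(score_fn)) {
      val <- score_fn(frames[[i]], i)
      min(max(as.numeric(val), 0), 100)
    } else NA_real_
    if (!is.null(stepped$pose) && !is.na(score))
      traj <- record_sample(traj, stepped$pose, marker, score, i)
    pose <- stepped$pose
    records[[i]] <- list(
      index = i,
      file = if (!is.null(frame_paths)) frame_paths[i] else NA_character_,
      pose = if (!is.null(pose))
        list(theta = pose$theta, tx = pose$t[1], ty = pose$t[2]) else NULL,
      inlier_count = reg$inlier_count,
      accepted = reg$accepted,
      status = tracker$status,
      source = if (is.null(pose)) NA_character_ else attr(pose, "source"),
      score = score)
    message(sprintf(
      "frame %3d: status=%-8s inliers=%3d accepted=%-5s score=%s",
      i, tracker$status, reg$inlier_count, reg$accepted,
      if (is.na(score)) "NA" else sprintf("%.1f", score)))
  }
  structure(list(
    version = as.character(utils::packageVersion("bccmap")),
    reference = list(path = ref_path,
                     shape = c(dim(reference)[2], dim(reference)[1])),
    calibrations = list(surface = calibration_to_list(calib_surface),
                        reference = calibration_to_list(calib_reference)),
    config = unclass(config),
    seed = as.integer(seed),
    frames = records,
    trajectory = list(center = traj$center,
                      samples = lapply(traj$samples, function(sm) list(
                        frame_index = sm$frame_index,
                        pose = list(theta = sm$pose$theta,
                                    tx = sm$pose$t[1], ty = sm$pose$t[2]),
                        score = sm$score, source = sm$source)))),
    class = "bcc_session")
}

#' @export
print.bcc_session <- function(x, ...) {
  acc <- vapply(x$frames, function(f) isTRUE(f$accepted), logical(1))
  cat(sprintf("<bcc_session> %d frames, %d accepted (%.0f%%), %d trajectory samples\n",
              length(x$frames), sum(acc), 100 * mean(acc),
              length(x$trajectory$samples)))
  invisible(x)
}

#' Rebuild a `margin_trajectory` from a session
#'
#' @param session A `bcc_session`.
#' @param marker Marker geometry to attach to each sample.
#' @return A `margin_trajectory` usable with [render_overlay()] and
#'   [coverage_report()].
#' @export
session_trajectory <- function(session, marker) {
  traj <- trajectory_init(unlist(session$trajectory$center))
  for (sm in session$trajectory$samples) {
    pose <- rigid_pose(sm$pose$theta, sm$pose$tx, sm$pose$ty)
    attr(pose, "source") <- sm$source
    traj$samples[[length(traj$samples) + 1]] <-
      list(frame_index = sm$frame_index, pose = pose, marker = marker,
           score = sm$score, source = sm$source)
  }
  traj
}

# ---- session persistence -------------------------------------------------

#' Save / load a session as JSON
#'
#' Sessions serialize to a documented JSON layout; `save -> load -> save`
#' is byte-stable.  `load_session()` validates the schema and reports the
#' JSON-pointer-like path of the first offending field in an error of class
#' `bccmap_schema_error`; unknown extra fields (e.g. written by a newer
#' minor version) load with a warning.
#'
#' @param session A `bcc_session`.
#' @param path JSON file path.
#' @export
save_session <- function(session, path) {
  ser <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                                      null = "null", na = "null",
                                      pretty = TRUE)
  # canonicalize through one parse so freshly built and reloaded sessions
  # serialize to identical bytes
  canonical <- jsonlite::parse_json(ser(unclass(session)))
  writeLines(ser(canonical), path)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  if (!file.exists(path))
    bcc_error("bccmap_bad_input", paste("session file not found:", path))
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e)
      bcc_error("bccmap_schema_error",
                paste("not parseable as JSON:", conditionMessage(e))))
  validate_session(raw)
  known <- c("version", "reference", "calibrations", "config", "seed",
             "frames", "trajectory")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    warning(warningCondition(
      sprintf("session carries unknown fields (%s); written by a newer version?",
              paste(extra, collapse = ", ")),
      class = "bccmap_forward_compat"))
  structure(raw, class = "bcc_session")
}

fail_schema <- function(pointer, why) {
  bcc_error("bccmap_schema_error",
            sprintf("invalid session at %s: %s", pointer, why),
            pointer = pointer)
}

validate_session <- function(raw) {
  need <- function(field, pointer) {
    if (is.null(raw[[field]])) fail_schema(paste0(pointer, field), "missing")
  }
  for (f in c("version", "config", "seed", "frames", "trajectory"))
    need(f, "/")
  if (!is.numeric(raw$seed) && !is.integer(raw$seed))
    fail_schema("/seed", "must be a number")
  for (i in seq_along(raw$frames)) {
    fr <- raw$frames[[i]]
    ptr <- sprintf("/frames/%d/", i)
    for (f in c("index", "inlier_count", "accepted", "status"))
      if (is.null(fr[[f]])) fail_schema(paste0(ptr, f), "missing")
    if (!fr$status %in% c("LOCKED", "COASTING", "LOST"))
      fail_schema(paste0(ptr, "status"),
                  paste("unknown tracker status", fr$status))
    if (!is.null(fr$pose))
      for (f in c("theta", "tx", "ty"))
        if (is.null(fr$pose[[f]]))
          fail_schema(paste0(ptr, "pose/", f), "missing")
  }
  if (is.null(raw$trajectory$center))
    fail_schema("/trajectory/center", "missing")
  for (i in seq_along(raw$trajectory$samples)) {
    sm <- raw$trajectory$samples[[i]]
    ptr <- sprintf("/trajectory/samples/%d/", i)
    for (f in c("frame_index", "pose", "score"))
      if (is.null(sm[[f]])) fail_schema(paste0(ptr, f), "missing")
  }
  invisible(TRUE)
}
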