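#' Rigid 2-D poses (rotation + translation)
#'
#' A rigid pose maps source-image pixel coordinates into destination-image
#' pixel coordinates as `x' = R(theta) x + t`, with
#' `R = [cos -sin; sin cos]` acting on `(x, y)`.  Coordinates are 0-based
#' with the origin at the top-left pixel center, x rightward and y downward;
#' `theta` is measured counter-clockwise in that frame.  The model has no
#' scale term: images of different physical pixel pitch must be resampled to
#' a common scale (see [scale_factor()]) before a pose between them is
#' meaningful.
#'
#' @param theta Rotation angle in radians.
#' @param tx,ty Translation in destination-image pixels.
#' @return An object of class `rigid_pose`.
#' @seealso [pose_compose()], [pose_invert()], [transform_points()]
#' @examples
#' p <- rigid_pose(pi / 2, 10, -4)
#' transform_points(p, cbind(1, 0))  # -> (10, -3)
#' @export
rigid_pose <- function(theta = 0, tx = 0, ty = 0) {
  stopifnot(is.finite(theta), is.finite(tx), is.finite(ty))
  structure(list(theta = unname(wrap_angle(theta)),
                 t = unname(c(tx, ty))),
            class = "rigid_pose")
}

#' @rdname rigid_pose
#' @export
pose_identity <- function() rigid_pose(0, 0, 0)

#' @param p A `rigid_pose`.
#' @rdname rigid_pose
#' @export
is_rigid_pose <- function(p) inherits(p, "rigid_pose")

#' Rotation matrix of a pose
#' @param p A `rigid_pose`.
#' @return The 2 x 2 rotation matrix (determinant +1).
#' @export
pose_rotation <- function(p) {
  ct <- cos(p$theta); st <- sin(p$theta)
  matrix(c(ct, st, -st, ct), 2, 2)
}

#' Compose two rigid poses
#'
#' `pose_compose(a, b)` returns the pose that applies `b` first, then `a`
#' (function composition `a o b`).  Composition is associative and rigid
#' poses form a group under it.
#'
#' @param a,b `rigid_pose` objects.
#' @return A `rigid_pose`.
#' @export
pose_compose <- function(a, b) {
  Ra <- pose_rotation(a)
  t <- as.numeric(Ra %*% b$t) + a$t
  rigid_pose(a$theta + b$theta, t[1], t[2])
}

#' Invert a rigid pose
#'
#' @param p A `rigid_pose`.
#' @return The pose `q` with `pose_compose(q, p)` equal to the identity.
#' @export
pose_invert <- function(p) {
  Rt <- t(pose_rotation(p))
  t <- as.numeric(-Rt %*% p$t)
  rigid_pose(-p$theta, t[1], t[2])
}

#' Apply a rigid pose to points
#'
#' @param p A `rigid_pose`.
#' @param pts An `n x 2` matrix (or length-2 vector) of `(x, y)` source
#'   pixel coordinates.
#' @return An `n x 2` matrix of destination pixel coordinates.  Pairwise
#'   distances are preserved (the map is an isometry).
#' @export
transform_points <- function(p, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  stopifnot(ncol(pts) == 2, all(is.finite(pts)))
  out <- pts %*% t(pose_rotation(p))
  out[, 1] <- out[, 1] + p$t[1]
  out[, 2] <- out[, 2] + p$t[2]
  out
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat(sprintf("<rigid_pose> theta = %.6f rad (%.3f deg), t = (%.3f, %.3f) px\n",
              x$theta, x$theta * 180 / pi, x$t[1], x$t[2]))
  invisible(x)
}

#' @export
format.rigid_pose <- function(x, ...) {
  sprintf("(theta=%.4f, tx=%.2f, ty=%.2f)", x$theta, x$t[1], x$t[2])
}

# angular distance between two poses, radians in [0, pi]
pose_angle_diff <- function(a, b) abs(wrap_angle(a$theta - b$theta))

# translation distance between two poses, px
pose_trans_diff <- function(a, b) sqrt(sum((a$t - b$t)^2))
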