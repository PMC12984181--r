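# trajectory recording, overlay rendering, quadrant coverage

mk_pose_at <- function(center, theta = 0, marker) {
  # pose placing the marker centroid at `center` with orientation theta
  c0 <- colMeans(marker$points)
  Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  t <- center - as.numeric(Rm %*% c0)
  rigid_pose(theta, t[1], t[2])
}

test_that("recording appends scored samples and skips LOST frames with a warning", {
  ph <- test_phantom()
  mk <- marker_line(ph$surface_calib, ph$calib)
  traj <- trajectory_init(c(480, 321))
  p <- rigid_pose(0.1, 200, 150)
  attr(p, "source") <- "global"
  traj <- record_sample(traj, p, mk, 10, 1)
  expect_length(traj$samples, 1)
  expect_identical(traj$samples[[1]]$score, 10)
  expect_warning(traj2 <- record_sample(traj, NULL, mk, 50, 2),
                 class = "bccmap_lost_frame")
  expect_length(traj2$samples, 1)
  expect_error(record_sample(traj, p, mk, 150, 3))
})

test_that("sample poses equal simulator ground truth on an accepted sweep", {
  ph <- test_phantom()
  ref <- test_reference()
  st <- test_stream()
  mk <- marker_line(ph$surface_calib, ph$calib)
  traj <- trajectory_init(ph$center_px)
  for (i in seq_along(st$frames)) {
    reg <- colocalize(st$frames[[i]], ref, ph$surface_calib, ph$calib,
                      seed = i)
    if (reg$accepted) {
      pose <- reg$pose
      attr(pose, "source") <- "global"
      traj <- record_sample(traj, pose, mk, 42, i)
    }
  }
  expect_gte(length(traj$samples), 7)
  for (sm in traj$samples) {
    truth <- st$poses[[sm$frame_index]]
    expect_lt(sqrt(sum((sm$pose$t - truth$t)^2)), 0.5)
  }
})

test_that("rendered markers carry the exact colormap color at their centroids", {
  ph <- test_phantom()
  mk <- marker_line(ph$surface_calib, ph$calib)
  traj <- trajectory_init(ph$center_px)
  centers <- rbind(c(250, 200), c(650, 200), c(480, 500))
  scores <- c(0, 100, 37)
  for (i in 1:3) {
    p <- mk_pose_at(centers[i, ], theta = 0.3 * i, marker = mk)
    attr(p, "source") <- if (i == 3) "extrapolated" else "global"
    traj <- record_sample(traj, p, mk, scores[i], i)
  }
  img <- render_overlay(ph$image, traj, ph$surface_calib, ph$calib)
  for (i in 1:3) {
    want <- score_to_color(scores[i])[1, ] / 255
    got <- img[round(centers[i, 2]) + 1, round(centers[i, 1]) + 1, ]
    expect_equal(as.numeric(got), unname(want), tolerance = 1e-9)
  }
  # one blue and one yellow marker are present
  expect_true(any(img[, , 3] == 1 & img[, , 1] == 0))
  expect_true(any(img[, , 1] == 1 & img[, , 2] == 1 & img[, , 3] == 0))
  # deterministic rendering
  img2 <- render_overlay(ph$image, traj, ph$surface_calib, ph$calib)
  expect_identical(img, img2)
  expect_error(render_overlay(ph$image, trajectory_init(c(1, 1)),
                              ph$surface_calib, ph$calib),
               class = "bccmap_bad_input")
})

test_that("quadrant assignment follows the clock convention", {
  ctr <- c(100, 100)
  # 12 o'clock = -y, then clockwise: +x is 3 o'clock, +y is 6, -x is 9
  a <- bccmap:::clock_angle(rbind(c(100, 50), c(150, 100),
                                  c(100, 150), c(50, 100)), ctr)
  expect_equal(a, c(0, pi / 2, pi, 3 * pi / 2), tolerance = 1e-12)
  expect_identical(bccmap:::clock_quadrant(c(0.1, 1.7, 3.3, 5.0)),
                   c("12-3", "3-6", "6-9", "9-12"))
})

circle_path <- function(center, r_px, n = 720) {
  a <- seq(0, 2 * pi, length.out = n + 1)
  cbind(center[1] + r_px * sin(a), center[2] - r_px * cos(a))
}

test_that("coverage matches a brute-force geometric oracle per quadrant", {
  ph <- test_phantom()
  mk <- marker_line(ph$surface_calib, ph$calib)
  ctr <- ph$center_px
  r_px <- ph$margin_radius_px
  path <- circle_path(ctr, r_px)
  gap_tol <- 0.5
  # samples covering only the 12-3 arc
  traj <- trajectory_init(ctr)
  angles <- seq(0.05, pi / 2 - 0.05, length.out = 12)
  for (i in seq_along(angles)) {
    cpt <- ctr + r_px * c(sin(angles[i]), -cos(angles[i]))
    p <- mk_pose_at(cpt, theta = angles[i], marker = mk)
    traj <- record_sample(traj, p, mk, 20, i)
  }
  rep <- coverage_report(traj, path, gap_tol, ph$calib)
  expect_gt(rep$coverage[["12-3"]], 0.9)
  expect_lt(max(rep$coverage[["3-6"]], rep$coverage[["9-12"]]), 0.25)
  expect_lt(rep$coverage[["6-9"]], 0.05)
  # independent oracle: dense points vs point-to-segment distance, by quadrant
  tol_px <- gap_tol / (mean(ph$calib$pixel_pitch) / 1000)
  aa <- seq(0, 2 * pi, length.out = 3000)[-1]
  pts <- cbind(ctr[1] + r_px * sin(aa), ctr[2] - r_px * cos(aa))
  segs <- lapply(traj$samples, function(sm)
    transform_points(sm$pose, sm$marker$points))
  dmin <- rep(Inf, nrow(pts))
  for (sg in segs) {
    ab <- sg[2, ] - sg[1, ]; ab2 <- sum(ab^2)
    tt <- pmin(pmax(((pts[, 1] - sg[1, 1]) * ab[1] +
                       (pts[, 2] - sg[1, 2]) * ab[2]) / ab2, 0), 1)
    d <- sqrt((pts[, 1] - sg[1, 1] - tt * ab[1])^2 +
                (pts[, 2] - sg[1, 2] - tt * ab[2])^2)
    dmin <- pmin(dmin, d)
  }
  quad <- bccmap:::clock_quadrant(aa)
  for (q in c("12-3", "3-6", "6-9", "9-12")) {
    want <- mean(dmin[quad == q] <= tol_px)
    expect_equal(rep$coverage[[q]], want, tolerance = 0.02)
  }
  # gaps land in the uncovered quadrants
  expect_gt(nrow(rep$gaps), 0)
  expect_false("12-3" %in% rep$gaps$quadrant &&
                 nrow(rep$gaps[rep$gaps$quadrant == "12-3", ]) > 1)
})

test_that("coverage is zero for an empty trajectory, one for a dense sweep, and monotone", {
  ph <- test_phantom()
  mk <- marker_line(ph$surface_calib, ph$calib)
  ctr <- ph$center_px
  r_px <- ph$margin_radius_px
  path <- circle_path(ctr, r_px)
  traj <- trajectory_init(ctr)
  rep0 <- coverage_report(traj, path, 0.5, ph$calib)
  expect_true(all(rep0$coverage == 0))
  # open polyline is rejected
  expect_error(coverage_report(traj, path[1:100, ], 0.5, ph$calib),
               class = "bccmap_open_path")
  # dense full sweep covers every quadrant completely, monotonically
  angles <- seq(0, 2 * pi, length.out = 60)
  prev <- rep(0, 4)
  for (i in seq_along(angles)) {
    cpt <- ctr + r_px * c(sin(angles[i]), -cos(angles[i]))
    traj <- record_sample(traj, mk_pose_at(cpt, angles[i], mk), mk, 5, i)
    if (i %% 15 == 0) {
      cov <- coverage_report(traj, path, 0.5, ph$calib)$coverage
      expect_true(all(cov >= prev - 1e-12))
      expect_true(all(cov >= 0 & cov <= 1))
      prev <- cov
    }
  }
  repf <- coverage_report(traj, path, 0.5, ph$calib)
  expect_true(all(repf$coverage == 1))
  expect_identical(nrow(repf$gaps), 0L)
})
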