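# keypoint detection, matching, RANSAC estimation, reliability gate

test_that("reference initialization is deterministic and rejects flat images", {
  expect_error(init_reference(matrix(0.5, 128, 128)),
               class = "bccmap_empty_reference")
  expect_error(init_reference(matrix(0.5, 32, 32)),
               class = "bccmap_bad_input")
  ph <- test_phantom()
  a <- init_reference(ph$image)
  b <- init_reference(ph$image)
  expect_identical(a$keypoints, b$keypoints)
  expect_identical(a$descriptors, b$descriptors)
  expect_gt(nrow(a$keypoints), 0)
})

test_that("keypoint detection is stable under a 180-degree rotation", {
  ph <- test_phantom()
  g <- luminance(ph$image)
  rot <- g[nrow(g):1, ncol(g):1]
  n0 <- nrow(detect_keypoints(g)$keypoints)
  n1 <- nrow(detect_keypoints(rot)$keypoints)
  expect_lt(abs(n0 - n1) / n0, 0.02)
})

test_that("surface features from an identity-pose crop line up with reference keypoints", {
  ph <- test_phantom()
  ref <- test_reference()
  s <- scale_factor(ph$surface_calib, ph$calib)
  # truth pose: pure translation, so frame coords + t = reference coords
  u_c <- s * (ph$spec$surface_shape - 1) / 2
  pose <- rigid_pose(0, 300 - u_c, 250 - u_c)
  frame <- bccmap:::sample_rigid(ph$image, ph$spec$surface_shape,
                                 ph$spec$surface_shape, pose, prescale = s)
  feats <- extract_surface_features(frame, ph$surface_calib, ph$calib)
  expect_gt(nrow(feats$keypoints), 20)
  # deterministic
  feats2 <- extract_surface_features(frame, ph$surface_calib, ph$calib)
  expect_identical(feats$keypoints, feats2$keypoints)
  # most frame keypoints should sit within a pixel of some reference keypoint
  mapped <- transform_points(pose, feats$keypoints[, 1:2])
  d2 <- outer(rowSums(mapped^2), rowSums(ref$keypoints[, 1:2]^2), "+") -
    2 * mapped %*% t(ref$keypoints[, 1:2])
  nearest <- sqrt(pmax(apply(d2, 1, min), 0))
  expect_gt(mean(nearest < 1.5), 0.5)
  # blank frame errors
  expect_error(
    extract_surface_features(
      array(0, c(ph$spec$surface_shape, ph$spec$surface_shape, 3)),
      ph$surface_calib, ph$calib),
    class = "bccmap_empty_frame")
})

test_that("nearest-descriptor matching equals exhaustive search with index tie-breaks", {
  mk <- function(desc) {
    n <- nrow(desc)
    structure(list(keypoints = cbind(x = seq_len(n), y = 0, sigma = 1,
                                     angle = 0, response = 1),
                   descriptors = desc, image_shape = c(100, 100)),
              class = "keypoint_set")
  }
  set.seed(104)
  q <- matrix(stats::runif(5 * 8), 5, 8)
  r <- matrix(stats::runif(3 * 8), 3, 8)
  ms <- match_nearest(mk(q), mk(r))
  # brute-force O(N * M) oracle
  for (i in 1:5) {
    d <- apply(r, 1, function(rr) sqrt(sum((q[i, ] - rr)^2)))
    expect_equal(unname(ms$pairs[i, 2]), unname(which.min(d)))
    expect_equal(ms$distance[i], min(d), tolerance = 1e-12)
  }
  # each query appears exactly once
  expect_equal(unname(ms$pairs[, 1]), 1:5)
  # identity: zero distances, self-matches
  ms2 <- match_nearest(mk(r), mk(r))
  expect_equal(unname(ms2$pairs[, 2]), 1:3)
  expect_equal(ms2$distance, rep(0, 3), tolerance = 1e-12)
  # orthogonal unit descriptors: all distances sqrt(2), tie -> lowest index
  q3 <- rbind(c(1, 0, 0, 0))
  r3 <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  ms3 <- match_nearest(mk(q3), mk(r3))
  expect_equal(unname(ms3$pairs[1, 2]), 1L)
  expect_equal(ms3$distance[1], sqrt(2), tolerance = 1e-12)
})

test_that("RANSAC recovers exact and contaminated rigid correspondences", {
  set.seed(105)
  truth <- rigid_pose(0.3, 40, -12)
  q <- matrix(stats::runif(20, 0, 200), 10, 2)
  r <- transform_points(truth, q)
  est <- estimate_rigid(q, r, seed = 42)
  expect_pose_equal(est$pose, truth, tol = 1e-6)
  expect_equal(sort(est$inliers), 1:10)
  # add 20 uniform-random outliers
  qo <- rbind(q, matrix(stats::runif(40, 0, 200), 20, 2))
  ro <- rbind(r, matrix(stats::runif(40, 0, 200), 20, 2))
  est2 <- estimate_rigid(qo, ro, seed = 42)
  expect_pose_equal(est2$pose, truth, tol = 1e-3)
  expect_true(all(1:10 %in% est2$inliers))
  # identical positions give the identity
  est3 <- estimate_rigid(q, q, seed = 1)
  expect_pose_equal(est3$pose, pose_identity(), tol = 1e-9)
  # coincident points cannot define a rotation
  ones <- matrix(1, 5, 2)
  expect_error(estimate_rigid(ones, ones + 3, seed = 1),
               class = "bccmap_degenerate_geometry")
  # determinism: same seed, same result
  est4 <- estimate_rigid(qo, ro, seed = 42)
  expect_identical(est4, est2)
})

test_that("refined pose equals the closed-form least-squares fit on its inliers", {
  set.seed(106)
  for (k in 1:20) {
    truth <- random_pose()
    n <- sample(5:40, 1)
    q <- matrix(stats::runif(2 * n, 0, 300), n, 2)
    r <- transform_points(truth, q) +
      matrix(stats::rnorm(2 * n, 0, 0.5), n, 2)
    # sprinkle outliers
    n_out <- sample(0:10, 1)
    if (n_out > 0) {
      q <- rbind(q, matrix(stats::runif(2 * n_out, 0, 300), n_out, 2))
      r <- rbind(r, matrix(stats::runif(2 * n_out, 0, 300), n_out, 2))
    }
    est <- estimate_rigid(q, r, seed = k)
    # independent SVD-based oracle on the final inlier set
    oracle <- svd_rigid(q[est$inliers, , drop = FALSE],
                        r[est$inliers, , drop = FALSE])
    expect_lt(abs(bccmap:::wrap_angle(est$pose$theta - oracle$theta)), 1e-6)
    expect_lt(sqrt(sum((est$pose$t - oracle$t)^2)), 1e-6)
    # every reported inlier satisfies the pose within tolerance
    res <- bccmap:::pose_residuals(est$pose, q, r)
    expect_true(all(res[est$inliers] < 3))
  }
})

test_that("the reliability gate accepts strictly above the threshold", {
  cfg <- bcc_config()
  for (n in 0:20)
    expect_identical(gate_reliability(n, cfg), n > 6)
  expect_true(gate_reliability(7, cfg))
  expect_false(gate_reliability(6, cfg))
  expect_false(gate_reliability(0, cfg))
  cfg2 <- bcc_config(inlier_accept_threshold = 10L)
  expect_false(gate_reliability(10, cfg2))
  expect_true(gate_reliability(11, cfg2))
})

test_that("colocalize finds simulated frames and rejects foreign or blank ones", {
  ph <- test_phantom()
  ref <- test_reference()
  st <- test_stream()
  for (i in c(1, 4, 8)) {
    reg <- colocalize(st$frames[[i]], ref, ph$surface_calib, ph$calib,
                      seed = i)
    expect_true(reg$accepted)
    expect_identical(reg$source, "global")
    expect_lt(sqrt(sum((reg$pose$t - st$poses[[i]]$t)^2)), 0.5)
    expect_lt(abs(bccmap:::wrap_angle(reg$pose$theta - st$poses[[i]]$theta)),
              0.2 * pi / 180)
    # bit-identical on rerun with the same seed
    reg2 <- colocalize(st$frames[[i]], ref, ph$surface_calib, ph$calib,
                       seed = i)
    expect_identical(reg, reg2)
  }
  # a frame from an unrelated texture must be rejected, not error
  foreign <- generate_phantom(phantom_spec(seed = 99))
  path_f <- probe_path(foreign, 1, start_angle = 2, end_angle = 2, seed = 1)
  fr_f <- simulate_surface_stream(foreign, path_f, seed = 1)$frames[[1]]
  reg_f <- colocalize(fr_f, ref, ph$surface_calib, ph$calib, seed = 3)
  expect_false(reg_f$accepted)
  # blank frame: rejected result, never an exception
  blank <- array(0.5, c(ph$spec$surface_shape, ph$spec$surface_shape, 3))
  reg_b <- colocalize(blank, ref, ph$surface_calib, ph$calib)
  expect_false(reg_b$accepted)
  expect_identical(reg_b$source, "global")
  expect_identical(reg_b$inlier_count, 0L)
})
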