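# inter-frame motion and the LOCKED / COASTING / LOST state machine

test_that("inter-frame motion recovers identity and known shifts", {
  st <- test_stream()
  f1 <- st$frames[[1]]
  res <- interframe_motion(f1, f1, seed = 1)
  expect_gte(res$confidence, 7)
  expect_lt(sqrt(sum(res$delta$t^2)), 0.1)
  expect_lt(abs(res$delta$theta), 1e-3)
  # synthesize a pair with a known raw-pixel shift delta of (12, -5)
  ph <- test_phantom()
  s <- scale_factor(ph$surface_calib, ph$calib)
  d_true <- rigid_pose(0, 12, -5)
  d_ref <- rigid_pose(0, s * 12, s * -5)
  p1 <- st$path$poses[[1]]
  p2 <- pose_compose(p1, pose_invert(d_ref))
  shape <- ph$spec$surface_shape
  mk_frame <- function(pose) {
    fr <- bccmap:::sample_rigid(ph$image, shape, shape, pose, prescale = s)
    m <- bccmap:::circle_mask(shape, shape)
    for (c in 1:3) { ch <- fr[, , c]; ch[!m] <- 0; fr[, , c] <- ch }
    fr
  }
  res2 <- interframe_motion(mk_frame(p1), mk_frame(p2), seed = 2)
  expect_gte(res2$confidence, 7)
  expect_lt(sqrt(sum((res2$delta$t - d_true$t)^2)), 0.5)
  # blank pair: confidence 0
  blank <- array(0.2, c(shape, shape, 3))
  expect_identical(interframe_motion(blank, blank)$confidence, 0L)
  expect_error(interframe_motion(blank, array(0.2, c(64, 64, 3))),
               class = "bccmap_bad_input")
})

fake_reg <- function(accepted, pose = NULL, inliers = if (accepted) 20L else 0L) {
  bccmap:::registration_result(pose, inliers, seq_len(inliers), accepted)
}

test_that("tracker transitions: lock, coast, lose, re-lock", {
  cfg <- bcc_config()
  p <- rigid_pose(0.2, 100, 50)
  tr <- tracker_init()
  expect_identical(tr$status, "LOST")
  # accepted registration from any prior state -> LOCKED with that pose
  s1 <- step_tracker(tr, fake_reg(TRUE, p), NULL, cfg)
  expect_identical(s1$state$status, "LOCKED")
  expect_pose_equal(s1$pose, p)
  expect_identical(attr(s1$pose, "source"), "global")
  expect_pose_equal(s1$state$cumulative_delta, pose_identity())
  expect_identical(s1$state$frames_coasted, 0L)
  # rejected registration + confident delta -> COASTING
  d <- list(delta = rigid_pose(0, 2, 1), confidence = 15L)
  s2 <- step_tracker(s1$state, fake_reg(FALSE), d, cfg, scale = 1)
  expect_identical(s2$state$status, "COASTING")
  expect_identical(attr(s2$pose, "source"), "extrapolated")
  expect_pose_equal(s2$pose, pose_compose(p, pose_invert(rigid_pose(0, 2, 1))))
  # confidence at the threshold is NOT enough (strict gate)
  d_weak <- list(delta = rigid_pose(0, 1, 0), confidence = 6L)
  s3 <- step_tracker(s2$state, fake_reg(FALSE), d_weak, cfg, scale = 1)
  expect_identical(s3$state$status, "LOST")
  expect_null(s3$pose)
  expect_null(s3$state$last_reliable_pose)
  # once LOST, a confident delta alone cannot resurrect tracking
  s4 <- step_tracker(s3$state, fake_reg(FALSE), d, cfg, scale = 1)
  expect_identical(s4$state$status, "LOST")
  # but a fresh registration re-locks and discards drift exactly
  p2 <- rigid_pose(-0.1, 80, 60)
  s5 <- step_tracker(s4$state, fake_reg(TRUE, p2), d, cfg, scale = 1)
  expect_identical(s5$state$status, "LOCKED")
  expect_pose_equal(s5$pose, p2)
  expect_pose_equal(s5$state$cumulative_delta, pose_identity())
})

test_that("coasting accumulates deltas oldest-first and respects the cap", {
  cfg <- bcc_config(tracking_max_coast = 3L)
  p <- rigid_pose(0, 100, 100)
  st <- step_tracker(tracker_init(), fake_reg(TRUE, p), NULL, cfg)$state
  deltas <- list(rigid_pose(0.1, 3, 0), rigid_pose(-0.05, 0, 2),
                 rigid_pose(0.02, -1, 1))
  cum <- pose_identity()
  for (k in 1:3) {
    out <- step_tracker(st, fake_reg(FALSE),
                        list(delta = deltas[[k]], confidence = 10L),
                        cfg, scale = 1)
    st <- out$state
    cum <- pose_compose(deltas[[k]], cum)   # right-to-left accumulation
    expect_identical(st$status, "COASTING")
    expect_identical(st$frames_coasted, k)
    expect_pose_equal(out$pose, pose_compose(p, pose_invert(cum)), tol = 1e-9)
  }
  # 4th coasting step exceeds the cap -> forced LOST
  out4 <- step_tracker(st, fake_reg(FALSE),
                       list(delta = rigid_pose(0, 1, 1), confidence = 10L),
                       cfg, scale = 1)
  expect_identical(out4$state$status, "LOST")
})

test_that("coasting stays close to ground truth on a simulated sweep", {
  ph <- test_phantom()
  ref <- test_reference()
  st <- test_stream()
  s <- scale_factor(ph$surface_calib, ph$calib)
  cfg <- bcc_config()
  # lock on frame 1 with a real registration
  reg1 <- colocalize(st$frames[[1]], ref, ph$surface_calib, ph$calib, seed = 1)
  expect_true(reg1$accepted)
  tracker <- step_tracker(tracker_init(), reg1, NULL, cfg, scale = s)$state
  # frames 2..6: suppress global registration, coast on inter-frame motion
  errs <- c()
  for (i in 2:6) {
    d <- interframe_motion(st$frames[[i - 1]], st$frames[[i]], cfg, seed = i)
    out <- step_tracker(tracker, fake_reg(FALSE), d, cfg, scale = s)
    tracker <- out$state
    expect_identical(tracker$status, "COASTING")
    errs <- c(errs, sqrt(sum((out$pose$t - st$poses[[i]]$t)^2)))
  }
  expect_lt(max(errs), 3)
  # error growth is at most roughly linear in frames coasted
  expect_lt(errs[5], 5 * max(errs[1], 0.5))
  # re-lock: emitted pose equals the fresh registration exactly, no blending
  reg7 <- colocalize(st$frames[[7]], ref, ph$surface_calib, ph$calib, seed = 7)
  out7 <- step_tracker(tracker, reg7, NULL, cfg, scale = s)
  expect_identical(out7$state$status, "LOCKED")
  expect_identical(out7$pose$theta, reg7$pose$theta)
  expect_identical(out7$pose$t, reg7$pose$t)
})
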