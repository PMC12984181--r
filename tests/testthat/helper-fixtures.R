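# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default phantom used across test files
test_phantom <- function() cached("phantom7", generate_phantom(phantom_spec(seed = 7)))

# its reference keypoints (expensive: full-canvas detection)
test_reference <- function() cached("ref7", init_reference(test_phantom()$image))

# a short noise-free probe sweep with ground-truth poses
test_stream <- function() cached("stream7", {
  ph <- test_phantom()
  path <- probe_path(ph, 8, start_angle = 0.4, end_angle = 1.6, seed = 11)
  c(simulate_surface_stream(ph, path, seed = 12), list(path = path))
})

# random rigid pose for property-style loops
random_pose <- function() {
  rigid_pose(stats::runif(1, -pi, pi), stats::runif(1, -100, 100),
             stats::runif(1, -100, 100))
}

expect_pose_equal <- function(a, b, tol = 1e-9) {
  expect_lt(abs(bccmap:::wrap_angle(a$theta - b$theta)), tol)
  expect_lt(sqrt(sum((a$t - b$t)^2)), tol)
}

# independent closed-form rigid fit via SVD (oracle for Procrustes checks)
svd_rigid <- function(qpos, rpos) {
  qc <- colMeans(qpos); rc <- colMeans(rpos)
  H <- t(sweep(qpos, 2, qc)) %*% sweep(rpos, 2, rc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, d)) %*% t(s$u)
  t <- rc - as.numeric(R %*% qc)
  list(theta = atan2(R[2, 1], R[1, 1]), t = t)
}
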