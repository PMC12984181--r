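# incremental mosaicking

crop_tile <- function(img, x0, y0, w = 200, h = 200) {
  img[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), , drop = FALSE]
}

# snake-ordered 4 x 3 grid of 200 px tiles with 80 px linear overlap
tile_grid <- function() {
  xs <- c(80, 200, 320, 440); ys <- c(60, 180, 300)
  ord <- list()
  for (r in seq_along(ys)) {
    cols <- if (r %% 2 == 1) seq_along(xs) else rev(seq_along(xs))
    for (c in cols) ord[[length(ord) + 1]] <- c(xs[c], ys[r])
  }
  ord
}

test_that("a fresh mosaic holds one frame at identity with the input as canvas", {
  ph <- test_phantom()
  tile <- crop_tile(ph$image, 80, 60)
  m <- mosaic_start(tile)
  expect_identical(mosaic_count(m), 1L)
  expect_pose_equal(m$frames[[1]]$pose, pose_identity())
  expect_identical(m$canvas, tile)
  expect_identical(mosaic_render(m), tile)
  # composite features equal a direct reference initialization of the frame
  direct <- init_reference(tile)
  expect_identical(m$composite_features$keypoints, direct$keypoints)
})

test_that("grid tiles are stitched to within a pixel of ground truth", {
  ph <- test_phantom()
  grid <- tile_grid()
  m <- mosaic_start(crop_tile(ph$image, grid[[1]][1], grid[[1]][2]))
  for (k in 2:length(grid))
    m <- mosaic_add(m, crop_tile(ph$image, grid[[k]][1], grid[[k]][2]),
                    seed = k)
  expect_identical(mosaic_count(m), 12L)
  for (k in seq_along(grid)) {
    want_t <- grid[[k]] - grid[[1]]
    got <- m$frames[[k]]$pose
    expect_lt(sqrt(sum((got$t - want_t)^2)), 1)
    expect_lt(abs(got$theta), 0.01)
  }
  # every stored pose passed the gate at insertion
  for (k in 2:12) expect_gt(m$frames[[k]]$inlier_count, 6)
  # composite reproduces the phantom region: normalized cross-correlation
  # over the covered canvas (the bounding box includes a thin uncovered rim
  # from subpixel pose rounding)
  comp <- luminance(mosaic_render(m))
  x0 <- grid[[1]][1] - m$origin[1]; y0 <- grid[[1]][2] - m$origin[2]
  src <- luminance(ph$image)[(y0 + 1):(y0 + nrow(comp)),
                             (x0 + 1):(x0 + ncol(comp))]
  covered <- m$acc$w > 0
  expect_gt(mean(covered), 0.95)
  ncc <- stats::cor(comp[covered], src[covered])
  expect_gt(ncc, 0.98)
})

test_that("frame identical to the first stitches at the identity pose", {
  ph <- test_phantom()
  tile <- crop_tile(ph$image, 300, 200)
  m <- mosaic_start(tile)
  m <- mosaic_add(m, tile, seed = 5)
  expect_lt(sqrt(sum(m$frames[[2]]$pose$t^2)), 0.1)
  expect_lt(abs(m$frames[[2]]$pose$theta), 1e-3)
})

test_that("the frame cap triggers refusal exactly at cap + 1 and gates overlap", {
  ph <- test_phantom()
  cfg <- bcc_config(mosaic_max_frames = 3L)
  tiles <- tile_grid()
  m <- mosaic_start(crop_tile(ph$image, tiles[[1]][1], tiles[[1]][2]), cfg)
  m <- mosaic_add(m, crop_tile(ph$image, tiles[[2]][1], tiles[[2]][2]), seed = 2)
  m <- mosaic_add(m, crop_tile(ph$image, tiles[[3]][1], tiles[[3]][2]), seed = 3)
  expect_identical(mosaic_count(m), 3L)
  expect_error(
    mosaic_add(m, crop_tile(ph$image, tiles[[4]][1], tiles[[4]][2]), seed = 4),
    class = "bccmap_mosaic_full")
  # a frame with no true overlap is refused by the gate
  foreign <- generate_phantom(phantom_spec(seed = 31))
  m2 <- mosaic_start(crop_tile(ph$image, 80, 60), bcc_config())
  expect_error(mosaic_add(m2, crop_tile(foreign$image, 400, 300), seed = 9),
               class = "bccmap_insufficient_overlap")
})

test_that("canvas area never shrinks as frames are added", {
  ph <- test_phantom()
  grid <- tile_grid()[1:5]
  m <- mosaic_start(crop_tile(ph$image, grid[[1]][1], grid[[1]][2]))
  area <- prod(dim(m$canvas)[1:2])
  for (k in 2:5) {
    m <- mosaic_add(m, crop_tile(ph$image, grid[[k]][1], grid[[k]][2]),
                    seed = k)
    new_area <- prod(dim(mosaic_render(m))[1:2])
    expect_gte(new_area, area)
    area <- new_area
  }
})

test_that("rendering is deterministic and blends consistent content seamlessly", {
  ph <- test_phantom()
  tile_a <- crop_tile(ph$image, 200, 150)
  tile_b <- crop_tile(ph$image, 300, 150)   # half-overlapping, same content
  m <- mosaic_start(tile_a)
  m <- mosaic_add(m, tile_b, seed = 6)
  r1 <- mosaic_render(m)
  r2 <- mosaic_render(m)
  expect_identical(r1, r2)
  # interior of the overlap must match either source to within a gray level
  # (first-frame x in 105..195 lies inside both tiles)
  ox <- m$origin[1]; oy <- m$origin[2]
  ov <- r1[(6:195) + oy, (106:195) + ox, ]
  src <- tile_a[6:195, 106:195, ]
  expect_lt(max(abs(ov - src)), 1.5 / 255)
})

test_that("live position reports the FOV rectangle and canvas overlap", {
  ph <- test_phantom()
  tile <- crop_tile(ph$image, 200, 150)
  m <- mosaic_start(tile)
  # live frame equal to the first: identity rectangle, full overlap
  lp <- mosaic_live_position(m, tile, seed = 3)
  expect_false(is.null(lp))
  expect_lt(sqrt(sum(lp$pose$t^2)), 0.5)
  expect_equal(lp$overlap, 1.0, tolerance = 0.01)
  # shifted by half a FOV: overlap about one half
  lp2 <- mosaic_live_position(m, crop_tile(ph$image, 300, 150), seed = 4)
  expect_false(is.null(lp2))
  expect_equal(lp2$overlap, 0.5, tolerance = 0.05)
  expect_equal(lp2$pose$t[1], 100, tolerance = 1)
  # unrelated texture: absent
  foreign <- generate_phantom(phantom_spec(seed = 31))
  expect_null(mosaic_live_position(m, crop_tile(foreign$image, 400, 300),
                                   seed = 5))
})
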