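one_bottle_world <- function(x = 1.5, y = 0) {
  world(
    c(-2, 4, -2, 2),
    objects = neurochair:::world_object(
      1, "bottle",
      x = x, y = y, width = 0.08, depth = 0.08,
      height = 0.3, z_base = 0.7, shape = "cylinder", solid = FALSE
    )
  )
}

test_that("objects behind the wheelchair are not detected", {
  w <- one_bottle_world(x = -1.5)
  sensed <- simulate_sensing(w, c(0, 0, 0), seed = 1)
  expect_equal(nrow(sensed$detections), 0L)
})

test_that("a noise-free bottle is detected with its cloud centred on it", {
  w <- one_bottle_world()
  sensed <- simulate_sensing(w, c(0, 0, 0),
    miss_rate = 0, noise_sd = 0, seed = 2
  )
  expect_equal(nrow(sensed$detections), 1L)
  cl <- sensed$cloud
  expect_equal(mean(cl$x), 1.5, tolerance = 0.05)
  expect_equal(mean(cl$y), 0, tolerance = 0.05)
  expect_true(all(cl$z >= 0.7 & cl$z <= 1.0))
})

test_that("detection frequency follows the configured miss rate", {
  w <- one_bottle_world()
  hits <- withr::with_seed(77, {
    vapply(1:500, function(i) {
      nrow(simulate_sensing(w, c(0, 0, 0),
        miss_rate = 0.2,
        points_per_object = 20
      )$detections)
    }, numeric(1))
  })
  expect_equal(mean(hits), 0.8, tolerance = 0.05)
})

test_that("bbox shrink is linear about the centre", {
  # (100,100,200,100) has centre (200,150); 60% of each side leaves
  # 120 x 60 centred there, trimming 20% off every edge
  expect_equal(shrink_bbox(c(100, 100, 200, 100)), c(140, 120, 120, 60))
  b <- shrink_bbox(c(100, 100, 200, 100))
  expect_equal(b[1] + b[3] / 2, 200)
  expect_equal(b[2] + b[4] / 2, 150)
})

test_that("localization is the centroid of surviving shrunk-box points", {
  det <- tibble::tibble(x = 0, y = 0, w = 640, h = 480)
  cloud <- tibble::tibble(
    x = c(1, 1, 1), y = c(0, 0.2, -0.2), z = c(0.5, 0.5, 0.5),
    u = c(320, 330, 310), v = c(240, 240, 240)
  )
  expect_equal(localize_target(det, cloud), c(1, 0, 0.5))
})

test_that("points below 10 cm are dropped; all-floor clouds fail", {
  det <- tibble::tibble(x = 0, y = 0, w = 640, h = 480)
  cloud <- tibble::tibble(
    x = c(1, 1), y = c(0, 0), z = c(0.05, 0.05),
    u = c(320, 321), v = c(240, 241)
  )
  expect_error(
    localize_target(det, cloud),
    class = "neurochair_localization_failure"
  )
})

test_that("points outside the shrunk box are excluded from the centroid", {
  det <- tibble::tibble(x = 100, y = 100, w = 200, h = 100)
  # shrunk box is (140, 130, 120, 60): u in [140, 260], v in [130, 190]
  cloud <- tibble::tibble(
    x = c(1, 50), y = c(0, 0), z = c(0.5, 0.5),
    u = c(200, 110), v = c(150, 150)
  )
  expect_equal(localize_target(det, cloud), c(1, 0, 0.5))
})

# Orientation -------------------------------------------------------------

test_that("a wall-like cloud faces the wheelchair through the v/vn rule", {
  pts <- cbind(rep(2, 50), seq(-1, 1, length.out = 50))
  ori <- estimate_orientation(pts, wheelchair_position = c(0, 0))
  expect_equal(as.numeric(ori), c(-1, 0), tolerance = 1e-6)
  expect_false(attr(ori, "degenerate"))
})

test_that("the PCA axis matches a 1-degree brute-force variance search", {
  withr::local_seed(42)
  for (rep in 1:10) {
    ang <- stats::runif(1, 0, pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    pts <- t(R %*% rbind(rnorm(150, sd = 0.5), rnorm(150, sd = 0.05)))
    ori <- estimate_orientation(pts, wheelchair_position = c(-3, -3))
    major <- attr(ori, "major")
    expect_lt(axis_angle(major, oracle_principal_axis(pts)), 2 * pi / 180)
    # the returned orientation is one of the two principal axes
    minor <- c(-major[2], major[1])
    expect_lt(
      min(axis_angle(ori, major), axis_angle(ori, minor)), 1e-6
    )
  }
})

test_that("orientation output is unit length and points toward the chair", {
  withr::local_seed(7)
  for (rep in 1:10) {
    pts <- cbind(rnorm(80, 2, 0.6), rnorm(80, 1, 0.1))
    ori <- estimate_orientation(pts, wheelchair_position = c(0, 0))
    expect_equal(sqrt(sum(ori^2)), 1, tolerance = 1e-9)
    expect_lte(sum(ori * attr(ori, "f")), 0)
    # the chosen axis is within 45 degrees of f (orthogonal pair property)
    expect_lte(axis_angle(ori, attr(ori, "f")), pi / 4 + 1e-9)
  }
})

test_that("jointly rotating cloud and wheelchair rotates the output", {
  withr::local_seed(3)
  pts <- cbind(rnorm(100, 2, 0.5), rnorm(100, 0, 0.05))
  chair <- c(0, 0)
  ori0 <- estimate_orientation(pts, chair)
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  ori1 <- estimate_orientation(t(R %*% t(pts)), as.numeric(R %*% chair))
  expect_equal(as.numeric(ori1), as.numeric(R %*% as.numeric(ori0)),
    tolerance = 1e-6
  )
})

test_that("near-isotropic clouds fall back to facing the wheelchair", {
  withr::local_seed(10)
  pts <- cbind(rnorm(200, 3, 0.2), rnorm(200, 0, 0.2))
  ori <- estimate_orientation(pts, wheelchair_position = c(0, 0))
  expect_true(attr(ori, "degenerate"))
  expect_equal(as.numeric(ori), -attr(ori, "f"))
})

# Tracking ----------------------------------------------------------------

test_that("tracking a static object leaves the estimate in place", {
  w <- one_bottle_world()
  pose <- c(0, 0, 0)
  sensed <- simulate_sensing(w, pose, noise_sd = 0, seed = 5)
  est <- estimate_target(sensed$detections[1, ], sensed$cloud, pose)
  upd <- track_update(est, w, pose, noise_sd = 0, time_s = 1, seed = 6)
  expect_equal(upd$position[1:2], est$position[1:2], tolerance = 0.02)
})

test_that("a laterally moving object is followed within noise bounds", {
  w <- one_bottle_world()
  pose <- c(0, 0, 0)
  sensed <- simulate_sensing(w, pose, seed = 7)
  est <- estimate_target(sensed$detections[1, ], sensed$cloud, pose)
  for (k in 1:5) {
    w$objects$y[1] <- w$objects$y[1] + 0.01 # 0.1 m/s at 10 Hz
    est <- track_update(est, w, pose, time_s = k * 0.1, seed = 10 + k)
  }
  expect_equal(est$position[2], 0.05, tolerance = 0.03)
})

test_that("an object leaving the field of view raises tracking failure", {
  w <- one_bottle_world()
  pose <- c(0, 0, 0)
  sensed <- simulate_sensing(w, pose, seed = 8)
  est <- estimate_target(sensed$detections[1, ], sensed$cloud, pose)
  w$objects$y[1] <- 5 # way outside the 57-degree sector
  expect_error(
    track_update(est, w, pose, time_s = 1, seed = 9),
    class = "neurochair_tracking_failure"
  )
})
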