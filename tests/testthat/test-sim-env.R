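# Path planning -----------------------------------------------------------

door_world <- function(width) {
  gap <- c(-width / 2, width / 2)
  world(c(-2, 2, -2, 2), list(
    neurochair:::rect_poly(0, 0.1, -2, gap[1]),
    neurochair:::rect_poly(0, 0.1, gap[2], 2)
  ))
}

test_that("an empty world yields a straight path of the right length", {
  w <- world(c(-1, 4, -1, 1))
  p <- plan_path(w, c(0, 0, 0), c(3, 0, 0))
  expect_equal(p$status, "ok")
  expect_equal(p$length, 3.0, tolerance = 0.06)
})

test_that("the 70 cm footprint passes an 80 cm door but not a 60 cm one", {
  p80 <- plan_path(door_world(0.8), c(-1.5, 0, 0), c(1.5, 0, 0))
  expect_equal(p80$status, "ok")
  p60 <- plan_path(door_world(0.6), c(-1.5, 0, 0), c(1.5, 0, 0))
  expect_equal(p60$status, "no_path")
})

test_that("a goal inside an obstacle reports no path", {
  w <- world(c(-2, 2, -2, 2), list(neurochair:::rect_poly(0.5, 1.5, -1, 1)))
  p <- plan_path(w, c(-1.5, 0, 0), c(1, 0, 0))
  expect_equal(p$status, "no_path")
})

# Kinematics --------------------------------------------------------------

test_that("ten steps at 0.4 m/s displace exactly 0.40 m", {
  w <- world(c(-5, 5, -5, 5))
  st <- wheelchair_state(pose = c(0, 0, 0))
  for (i in 1:10) {
    out <- sim_step(w, st, c(0.4, 0, 0))
    st <- out$state
  }
  expect_equal(st$pose[1], 0.40, tolerance = 1e-9)
  expect_equal(st$pose[2], 0, tolerance = 1e-12)
})

test_that("commanded speeds are clamped into the 0.1-0.4 m/s band", {
  w <- world(c(-5, 5, -5, 5))
  st <- wheelchair_state(pose = c(0, 0, 0))
  slow <- sim_step(w, st, c(0.05, 0, 0))
  expect_equal(slow$state$velocity[1], 0.1)
  fast <- sim_step(w, st, c(2, 0, 0))
  expect_equal(fast$state$velocity[1], 0.4)
  stopped <- sim_step(w, st, c(0, 0, 0))
  expect_equal(stopped$state$velocity[1:2], c(0, 0))
})

test_that("driving into a wall emits a collision and halts at contact", {
  w <- world(c(-5, 5, -5, 5), list(neurochair:::rect_poly(1, 2, -2, 2)))
  st <- wheelchair_state(pose = c(0, 0, 0))
  events <- character(0)
  for (i in 1:40) {
    out <- sim_step(w, st, c(0.4, 0, 0))
    st <- out$state
    if ("collision" %in% out$events) {
      events <- out$events
      break
    }
  }
  expect_true("collision" %in% events)
  # front overhang is 0.15 m: the pose stops just short of x = 0.85
  expect_lte(st$pose[1], 0.85 + 1e-9)
  expect_gt(st$pose[1], 0.75)
})

test_that("in-place rotation spins about the chassis centre", {
  w <- world(c(-5, 5, -5, 5))
  st <- wheelchair_state(pose = c(0, 0, 0))
  centre0 <- st$pose[1:2] + c(-0.45, 0)
  for (i in 1:16) {
    out <- sim_step(w, st, c(0, 0, 0.5))
    st <- out$state
  }
  centre1 <- st$pose[1:2] +
    as.numeric(neurochair:::rot2(st$pose[3]) %*% c(-0.45, 0))
  expect_equal(centre1, centre0, tolerance = 1e-9)
})

test_that("dynamic agents advance by their velocities", {
  w <- world(c(-5, 5, -5, 5),
    objects = neurochair:::world_object(
      1, "person",
      x = 2, y = 0, width = 0.5, shape = "cylinder",
      vx = 0, vy = 0.5, dynamic = TRUE
    )
  )
  st <- wheelchair_state(pose = c(0, 0, 0))
  for (i in 1:10) {
    out <- sim_step(w, st, c(0, 0, 0))
    w <- out$world
    st <- out$state
  }
  expect_equal(w$objects$y[1], 0.5, tolerance = 1e-9)
})

# Scenario fixtures --------------------------------------------------------

test_that("scenario fixtures are well formed", {
  for (sc in list(scenario_a(), scenario_b())) {
    expect_equal(nrow(sc$tasks), 9L)
    expect_true(all(sc$tasks$mode %in% c("auto", "command", "none")))
    expect_gt(nrow(sc$world$objects), 2)
    expect_equal(sc$world$doorways$width, 0.8)
    # start pose must be collision-free
    expect_false(!isFALSE(neurochair:::footprint_collides(
      sc$world, sc$start_pose
    )))
  }
})

test_that("scenarios round-trip through YAML", {
  sc <- scenario_a()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$world$bounds, sc$world$bounds)
  expect_equal(length(back$world$obstacles), length(sc$world$obstacles))
  expect_equal(back$world$objects$class, sc$world$objects$class)
  expect_equal(back$tasks$action, sc$tasks$action)
  expect_equal(back$start_pose, sc$start_pose, tolerance = 1e-6)
})
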