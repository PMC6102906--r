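mk_est <- function(class, x, y, z = 0.8, ori = c(-1, 0), chair = c(0, 0)) {
  target_estimate(
    target_id = abs(round(x * 100 + y * 10)), class = class,
    position = c(x, y, z), orientation = ori,
    f_vector = (c(x, y) - chair) / sqrt(sum((c(x, y) - chair)^2))
  )
}

test_that("a person outranks a nearer chair", {
  out <- prioritize_targets(
    list(mk_est("person", 3, 0), mk_est("chair", 1, 0)),
    wheelchair_pose = c(0, 0, 0)
  )
  expect_equal(out$class, c("person", "chair"))
  expect_equal(out$display_index, c(0L, 1L))
})

test_that("within a class, closer targets rank higher", {
  out <- prioritize_targets(
    list(mk_est("chair", 2, 0), mk_est("chair", 1, 0)),
    wheelchair_pose = c(0, 0, 0)
  )
  expect_equal(out$distance, c(1, 2))
})

test_that("no more than six targets are displayed", {
  ests <- lapply(1:8, function(i) mk_est("cup", i, 0))
  out <- prioritize_targets(ests, c(0, 0, 0))
  expect_equal(nrow(out), 6L)
  expect_equal(out$display_index, 0:5)
})

test_that("an empty estimate list yields an empty display", {
  out <- prioritize_targets(list(), c(0, 0, 0))
  expect_equal(nrow(out), 0L)
})

test_that("the ten classes partition into exactly four solution groups", {
  rules <- solution_rules()
  expect_setequal(rules$class, target_classes())
  expect_equal(anyDuplicated(rules$class), 0L)
  expect_equal(length(unique(rules$group)), 4L)
})

test_that("conversation targets get an 80 cm facing goal", {
  sol <- plan_solution(mk_est("person", 2, 0), c(0, 0, 0))
  expect_equal(sol$goal_pose, c(1.2, 0, 0))
  expect_equal(sol$actions$primitive, "NAV_TO_POSE")
})

test_that("approach targets get a 20 cm facing goal", {
  sol <- plan_solution(mk_est("desk", 1, 0, z = 0.4), c(0, 0, 0))
  expect_equal(sol$goal_pose, c(0.8, 0, 0))
})

test_that("goal poses always face the target centre", {
  withr::local_seed(11)
  for (rep in 1:20) {
    xy <- stats::runif(2, -3, 3)
    ang <- stats::runif(1, 0, 2 * pi)
    cls <- sample(c("person", "chair", "sofa", "bed", "desk"), 1)
    est <- mk_est(cls, xy[1], xy[2], ori = c(cos(ang), sin(ang)))
    sol <- plan_solution(est, c(0, 0, 0))
    g <- sol$goal_pose
    expect_equal(
      g[3], atan2(xy[2] - g[2], xy[1] - g[1]),
      tolerance = 1e-6
    )
  }
})

test_that("an opened door plans a standoff then a pass-through beyond", {
  est <- mk_est("opened_door", 3, 0, z = 1, ori = c(-1, 0))
  sol <- plan_solution(est, c(0, 0, 0))
  expect_equal(sol$actions$primitive, c("NAV_TO_POSE", "PASS_THROUGH"))
  pre <- unlist(sol$actions[1, c("goal_x", "goal_y")])
  post <- unlist(sol$actions[2, c("goal_x", "goal_y")])
  expect_lt(pre[1], 3) # standoff before the doorway
  expect_gt(post[1], 3) # goal beyond it, along the normal
  expect_equal(pre[2], 0, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(post[2], 0, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("manipulation targets adjust then press or pick", {
  sw <- plan_solution(mk_est("electric_switch", 1, 0, z = 0.9), c(0, 0, 0))
  expect_equal(
    sw$actions$primitive, c("ADJUST_UNTIL_IN_WORKSPACE", "ARM_PRESS")
  )
  bt <- plan_solution(mk_est("bottle", 1, 0, z = 0.85), c(0, 0, 0))
  expect_equal(
    bt$actions$primitive,
    c("ADJUST_UNTIL_IN_WORKSPACE", "ARM_PICK", "ARM_TO_MOUTH")
  )
})

test_that("targets above the arm workspace ceiling are rejected", {
  # workspace z spans 0.55-1.00 m in the world (arm origin 0.70 m + box);
  # 0.35 m above the arm origin exceeds the 0.30 m ceiling
  est <- mk_est("bottle", 1, 0, z = 0.70 + 0.35)
  expect_error(
    plan_solution(est, c(0, 0, 0)),
    class = "neurochair_solution_rejected"
  )
  # and floor-level objects are below the reachable band
  expect_error(
    plan_solution(mk_est("cup", 1, 0, z = 0.1), c(0, 0, 0)),
    class = "neurochair_solution_rejected"
  )
})

test_that("unknown classes are rejected", {
  expect_error(plan_solution(mk_est("table", 1, 0), c(0, 0, 0)), "unknown")
})

test_that("the command menu exposes exactly the six motion commands", {
  menu <- command_menu()
  expect_equal(nrow(menu), 6L)
  expect_setequal(
    menu$command,
    c(
      "forward", "backward", "translate_left", "translate_right",
      "rotate_left", "rotate_right"
    )
  )
})
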