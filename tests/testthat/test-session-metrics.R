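# One ideal-stub scenario-A session shared by several blocks.
ideal_session_a <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_session(scenario_a(),
        user = ideal_user(),
        decoder = "ideal", seed = 7
      )
    }
    cache
  }
})

test_that("the ideal user completes scenario A with perfect metrics", {
  log <- ideal_session_a()
  expect_true(log$success)
  m <- compute_metrics(log)
  expect_equal(m$TrP3, 1)
  expect_equal(m$TiP3, 3.6)
  expect_equal(m$VT, 0)
  expect_equal(m$FV, 0L)
  expect_equal(m$SR, 1)
})

test_that("all nine task steps are logged in order", {
  log <- ideal_session_a()
  steps <- log$events$step[log$events$type == "task_step"]
  expect_equal(steps, 1:9)
})

test_that("each selection walks mode select, P300, validation, execution", {
  log <- ideal_session_a()
  ev <- log$events
  for (s in unique(ev$step[ev$type == "mode_selected"])) {
    sub <- ev[!is.na(ev$step) & ev$step == s, ]
    t_mode <- sub$t[sub$type == "mode_selected"][1]
    t_pred <- sub$t[sub$type == "p300_trial"][1]
    t_sel <- sub$t[sub$type == "selection_made"][1]
    t_exec <- sub$t[sub$type %in% c(
      "solution_planned", "action_start", "command_done"
    )][1]
    expect_true(t_mode <= t_pred)
    expect_true(t_pred <= t_sel)
    expect_true(t_sel <= t_exec)
  }
})

test_that("the footprint never crosses a wall along the whole trajectory", {
  log <- ideal_session_a()
  walls <- scenario_a()$world$obstacles
  tr <- log$trajectory
  idx <- seq(1, nrow(tr), by = 2)
  for (i in idx) {
    fp <- neurochair:::footprint_polygon(
      c(tr$x[i], tr$y[i], tr$theta[i])
    )
    for (poly in walls) {
      expect_false(neurochair:::polygons_intersect(fp, poly))
    }
  }
})

test_that("the guest walks off and is reached before conversation", {
  log <- ideal_session_a()
  types <- log$events$type
  expect_true("guest_walking" %in% types)
  expect_true("guest_stopped" %in% types)
  t_walk <- log$events$t[types == "guest_walking"][1]
  t_conv <- log$events$t[
    types == "passive_done" & log$events$note == "converse"
  ]
  expect_true(t_walk < t_conv)
  # final pose faces the stopped guest at conversation distance
  guest <- unlist(log$final_objects[
    log$final_objects$class == "person", c("x", "y")
  ])
  d <- sqrt(sum((log$final_pose[1:2] - guest)^2))
  expect_equal(d, 0.8, tolerance = 0.25)
})

test_that("scenario B also completes under the ideal stub", {
  log <- run_session(scenario_b(),
    user = ideal_user(),
    decoder = "ideal", seed = 101
  )
  expect_true(log$success)
  expect_equal(compute_metrics(log)$SR, 1)
})

test_that("session logs are reproducible under a fixed seed", {
  a <- run_session(scenario_a(), user = ideal_user(), seed = 3)
  b <- run_session(scenario_a(), user = ideal_user(), seed = 3)
  expect_equal(a$events$t, b$events$t)
  expect_equal(a$trajectory, b$trajectory)
})

# Metric arithmetic on handcrafted logs ------------------------------------

handcrafted_log <- function(extra = NULL) {
  ev <- dplyr::bind_rows(
    tibble::tibble(
      t = c(3.6, 7.2, 10.8, 14.4, 18.0, 21.6),
      type = "p300_trial",
      step = c(1L, 1L, 2L, 3L, 3L, 3L),
      trial = c(1L, 2L, 1L, 1L, 2L, 3L)
    ),
    tibble::tibble(
      t = c(9, 12, 24), type = "validation_delay",
      step = 1:3, delay = c(2, 1, 3)
    ),
    tibble::tibble(
      t = c(9, 12, 24), type = "validation",
      step = 1:3, necessary = TRUE
    ),
    extra
  )
  ev
}

test_that("TrP3 and TiP3 follow the trial counts arithmetic", {
  m <- compute_metrics(handcrafted_log(), trial_duration = 3.6)
  expect_equal(m$TrP3, 2.0) # mean of (2, 1, 3)
  expect_equal(m$TiP3, 7.2)
  expect_equal(m$VT, 2.0)
  expect_equal(m$FV, 0L)
})

test_that("a spurious validation counts as one false validation", {
  extra <- tibble::tibble(
    t = 15, type = "validation", step = NA_integer_, necessary = FALSE
  )
  m <- compute_metrics(handcrafted_log(extra))
  expect_equal(m$FV, 1L)
})

test_that("perception failures count as EP, not NV", {
  extra <- tibble::tibble(
    t = 16, type = "localization_failure", step = 2L
  )
  m <- compute_metrics(handcrafted_log(extra))
  expect_equal(m$EP, 1L)
  expect_equal(m$NV, 0L)
})

test_that("collisions and planning failures count as NV", {
  extra <- dplyr::bind_rows(
    tibble::tibble(t = 16, type = "collision", step = 2L),
    tibble::tibble(
      t = 17, type = "nav_failure", step = 2L, note = "planning_failure"
    )
  )
  m <- compute_metrics(handcrafted_log(extra))
  expect_equal(m$NV, 2L)
})

test_that("TiP3 / TrP3 equals the configured trial duration exactly", {
  for (dur in c(2.4, 3.6, 4.8)) {
    m <- compute_metrics(handcrafted_log(), trial_duration = dur)
    expect_equal(m$TiP3 / m$TrP3, dur)
  }
})

test_that("aggregate metrics recompute from per-session rows", {
  rows <- dplyr::bind_rows(
    tibble::tibble(TrP3 = 1, TiP3 = 3.6, VT = 2, FV = 0L, SR = 1,
      EP = 0L, NV = 0L, n_selections = 7L),
    tibble::tibble(TrP3 = 2, TiP3 = 7.2, VT = 4, FV = 1L, SR = 1,
      EP = 1L, NV = 0L, n_selections = 7L)
  )
  agg <- aggregate_metrics(rows)
  expect_equal(agg$TrP3_mean, 1.5)
  expect_equal(agg$TrP3_sd, sd(c(1, 2)))
  expect_equal(agg$VT_mean, 3)
  expect_equal(agg$FV, 1L)
  expect_equal(agg$SR, 1)
  expect_equal(agg$EP, 1L)
})

test_that("malformed logs are rejected", {
  expect_error(compute_metrics(tibble::tibble(a = 1)), "malformed")
})

test_that("tidy and glance work on session logs", {
  log <- ideal_session_a()
  expect_s3_class(tidy(log), "tbl_df")
  expect_equal(glance(log)$SR, 1)
})
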