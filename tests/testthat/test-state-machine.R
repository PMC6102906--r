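tick_until <- function(s, t_end, targets = TRUE, dt = 0.1) {
  t <- 0
  modes <- character(0)
  while (t < t_end) {
    t <- round(t + dt, 10)
    s <- sm_step(s, "tick", now = t, targets_present = targets)
    modes <- c(modes, s$preactivated_mode)
  }
  list(state = s, modes = modes, times = seq(dt, t_end, by = dt))
}

test_that("preactivated modes alternate every 3 s exactly", {
  out <- tick_until(control_state(0), 9.0)
  # auto for (0,3], command for (3,6], auto for (6,9]
  expect_equal(out$modes[out$times <= 3.0 - 1e-9][1], "auto")
  expect_true(all(out$modes[out$times < 3.0 - 1e-9] == "auto"))
  expect_true(all(
    out$modes[out$times >= 3.0 - 1e-9 & out$times < 6.0 - 1e-9] == "command"
  ))
  expect_true(all(
    out$modes[out$times >= 6.0 - 1e-9 & out$times < 9.0 - 1e-9] == "auto"
  ))
  # the switch happens on the tick at exactly 3.0 s
  i <- which(abs(out$times - 3.0) < 1e-9)
  expect_equal(out$modes[i], "command")
  expect_equal(out$modes[i - 1], "auto")
})

test_that("without targets the command mode stays preactivated", {
  out <- tick_until(control_state(0), 10, targets = FALSE)
  expect_true(all(out$modes[out$times > 3.01] == "command"))
})

test_that("the selection cycle walks the four states in order", {
  s <- control_state(0)
  expect_equal(s$state, "MODE_SELECT")
  s <- sm_step(s, "validation_fired")
  expect_equal(s$state, "P300_SELECT")
  expect_equal(s$active_mode, "auto")
  s <- sm_step(s, "p300_output", item = 3)
  expect_equal(s$state, "AWAIT_VALIDATION")
  expect_equal(s$selected_item, 3L)
  # the decoder may revise the prediction before validation
  s <- sm_step(s, "p300_output", item = 1)
  expect_equal(s$selected_item, 1L)
  s <- sm_step(s, "validation_fired")
  expect_equal(s$state, "EXECUTING")
  s <- sm_step(s, "task_done")
  expect_equal(s$state, "RESET")
  s <- sm_step(s, "tick", now = 10)
  expect_equal(s$state, "MODE_SELECT")
})

test_that("collisions and deadloops reset the system from any busy state", {
  for (ev in c("collision", "deadloop")) {
    s <- control_state(0)
    s <- sm_step(s, "validation_fired")
    s <- sm_step(s, "p300_output", item = 0)
    s <- sm_step(s, "validation_fired")
    s <- sm_step(s, ev)
    expect_equal(s$state, "RESET")
    s <- sm_step(s, "tick", now = 5)
    expect_equal(s$state, "MODE_SELECT")
  }
})

test_that("in command mode a second validation ceases execution", {
  s <- control_state(0)
  s <- sm_step(s, "tick", now = 3.0) # alternate to command
  expect_equal(s$preactivated_mode, "command")
  s <- sm_step(s, "validation_fired")
  s <- sm_step(s, "p300_output", item = 1)
  s <- sm_step(s, "validation_fired")
  expect_equal(s$state, "EXECUTING")
  s <- sm_step(s, "validation_fired") # cease
  expect_equal(s$state, "RESET")
})

test_that("a spurious validation during autocontrol execution is ignored", {
  s <- control_state(0)
  s <- sm_step(s, "validation_fired")
  s <- sm_step(s, "p300_output", item = 0)
  s <- sm_step(s, "validation_fired")
  s <- sm_step(s, "validation_fired") # auto mode: no cease semantics
  expect_equal(s$state, "EXECUTING")
})

test_that("illegal events name the state and event", {
  s <- control_state(0)
  expect_error(
    sm_step(s, "task_done"),
    "illegal event 'task_done' in state MODE_SELECT",
    class = "neurochair_illegal_transition"
  )
  s <- sm_step(s, "validation_fired")
  expect_error(
    sm_step(s, "task_done"),
    class = "neurochair_illegal_transition"
  )
})

test_that("every execution path returns to mode selection", {
  withr::local_seed(6)
  for (rep in 1:20) {
    s <- control_state(0)
    t <- 0
    # drive a random but legal scenario to completion
    s <- sm_step(s, "validation_fired")
    for (k in seq_len(sample(1:3, 1))) {
      s <- sm_step(s, "p300_output", item = sample(0:5, 1))
    }
    s <- sm_step(s, "validation_fired")
    s <- sm_step(s, sample(c("task_done", "collision", "deadloop"), 1))
    s <- sm_step(s, "tick", now = 99)
    expect_equal(s$state, "MODE_SELECT")
  }
})
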