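#' Shared-control state machine
#'
#' The interaction loop: the system starts in mode selection, where the
#' autocontrol and command-control modes are alternately preactivated for
#' 3 s each (staying on command control when no target is detected, since
#' target detection is the precondition of autocontrol). A validation
#' command during the window selects the preactivated mode and starts P300
#' selection; once the decoder's prediction is on display, a validation
#' confirms it and execution begins. Task completion, a collision, or a
#' planner deadloop resets the machine to mode selection. In command-control
#' mode a second validation ceases the running command.
#'
#' @param now Current time, seconds.
#' @param mode_window Preactivation window length, seconds.
#' @param start_mode Mode preactivated first (`"auto"` or `"command"`).
#' @return An object of class `control_state` with fields `state`
#'   (`MODE_SELECT`, `P300_SELECT`, `AWAIT_VALIDATION`, `EXECUTING`,
#'   `RESET`), `preactivated_mode`, `mode_window_deadline`, `active_mode`,
#'   `selected_item`.
#' @export
control_state <- function(now = 0, mode_window = 3,
                          start_mode = c("auto", "command")) {
  start_mode <- match.arg(start_mode)
  structure(
    list(
      state = "MODE_SELECT",
      preactivated_mode = start_mode,
      mode_window = mode_window,
      mode_window_deadline = now + mode_window,
      active_mode = NA_character_,
      selected_item = NA_integer_
    ),
    class = "control_state"
  )
}

#' @export
print.control_state <- function(x, ...) {
  cat(sprintf(
    "<control_state> %s (preactivated %s, active %s, item %s)\n",
    x$state, x$preactivated_mode, x$active_mode, x$selected_item
  ))
  invisible(x)
}

#' Advance the shared-control state machine by one event
#'
#' @param state A [control_state()].
#' @param event Event type, one of `"tick"`, `"p300_output"`,
#'   `"validation_fired"`, `"task_done"`, `"collision"`, `"deadloop"`.
#' @param now Event time, seconds (needed for `tick` and resets).
#' @param targets_present Whether any target is currently detected (used in
#'   mode selection: without targets the command mode stays preactivated).
#' @param item P300 prediction payload for `"p300_output"` (display index).
#' @return The updated `control_state`. Illegal state/event combinations
#'   raise an error naming both.
#' @export
sm_step <- function(state, event, now = NULL, targets_present = TRUE,
                    item = NULL) {
  illegal <- function() {
    abort(sprintf(
      "illegal event '%s' in state %s", event, state$state
    ), class = "neurochair_illegal_transition")
  }
  s <- state
  switch(state$state,
    MODE_SELECT = {
      if (event == "tick") {
        if (is.null(now)) abort("`now` required for tick events")
        if (now >= s$mode_window_deadline) {
          nxt <- if (s$preactivated_mode == "auto") "command" else "auto"
          if (!targets_present) nxt <- "command"
          s$preactivated_mode <- nxt
          s$mode_window_deadline <- s$mode_window_deadline + s$mode_window
        }
      } else if (event == "validation_fired") {
        if (s$preactivated_mode == "auto" && !targets_present) {
          # cannot enter autocontrol without targets; ignore the validation
          s$preactivated_mode <- "command"
        } else {
          s$active_mode <- s$preactivated_mode
          s$state <- "P300_SELECT"
          s$selected_item <- NA_integer_
        }
      } else {
        illegal()
      }
    },
    P300_SELECT = {
      if (event == "p300_output") {
        if (is.null(item)) abort("`item` required for p300_output")
        s$selected_item <- as.integer(item)
        s$state <- "AWAIT_VALIDATION"
      } else if (event == "tick") {
        # waiting for the decoder; nothing to do
      } else if (event %in% c("collision", "deadloop")) {
        s$state <- "RESET"
      } else {
        illegal()
      }
    },
    AWAIT_VALIDATION = {
      if (event == "validation_fired") {
        s$state <- "EXECUTING"
      } else if (event == "p300_output") {
        if (is.null(item)) abort("`item` required for p300_output")
        s$selected_item <- as.integer(item) # decoder keeps updating
      } else if (event == "tick") {
        # idle
      } else if (event %in% c("collision", "deadloop")) {
        s$state <- "RESET"
      } else {
        illegal()
      }
    },
    EXECUTING = {
      if (event %in% c("task_done", "collision", "deadloop")) {
        s$state <- "RESET"
      } else if (event == "validation_fired") {
        if (identical(s$active_mode, "command")) {
          s$state <- "RESET" # second validation ceases the command
        }
        # in autocontrol a validation during execution is spurious; ignored
      } else if (event == "tick") {
        # execution progress handled by the simulator
      } else {
        illegal()
      }
    },
    RESET = {
      if (event == "tick") {
        if (is.null(now)) abort("`now` required for tick events")
        ns <- control_state(now = now, mode_window = s$mode_window)
        ns$preactivated_mode <- if (targets_present) "auto" else "command"
        s <- ns
      } else {
        illegal()
      }
    },
    illegal()
  )
  s
}
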