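#' Simulated user model for closed-loop sessions
#'
#' Drives the closed loop: attends the task's assigned target, reacts to a
#' correct on-screen prediction by clenching the jaw after a lognormal-ish
#' (truncated normal) reaction time, and issues mode/cease validations the
#' same way. The ideal stub (`ideal_user()`) reacts instantly and never
#' errs; it isolates the control stack from decoder stochasticity.
#'
#' @param erp [erp_model()] used when a real decoder is in the loop.
#' @param reaction_mean,reaction_sd Reaction-time distribution, seconds.
#' @param reaction_min Lower truncation, seconds.
#' @param use_emg If `TRUE`, validations are issued by synthesizing a jaw
#'   clench and running the windowed-variance detector (adding its 0.4 s
#'   pattern latency); if `FALSE` validations fire instantly.
#' @param emg [emg_model()] for clench synthesis.
#' @return An object of class `simulated_user`.
#' @export
simulated_user <- function(erp = erp_model(), reaction_mean = 2.0,
                           reaction_sd = 0.7, reaction_min = 0.4,
                           use_emg = TRUE, emg = emg_model()) {
  structure(
    list(
      erp = erp, reaction_mean = reaction_mean, reaction_sd = reaction_sd,
      reaction_min = reaction_min, use_emg = use_emg, emg = emg
    ),
    class = "simulated_user"
  )
}

#' @rdname simulated_user
#' @export
ideal_user <- function() {
  simulated_user(
    reaction_mean = 0, reaction_sd = 0, reaction_min = 0, use_emg = FALSE
  )
}

draw_reaction <- function(user) {
  max(user$reaction_min,
    stats::rnorm(1, user$reaction_mean, user$reaction_sd))
}

# Validation latency: reaction time plus, when EMG is simulated, the
# detector's fire delay measured on an actual synthesized clench.
# Mode selection is anticipatory (the user follows the 3 s alternation
# rhythm and clenches as the desired box lights), so its reaction time is
# capped well below the window; target validation is reactive.
validation_delay <- function(user, cfg = validator_config(),
                             anticipatory = FALSE) {
  rt <- if (anticipatory) {
    max(0.2, stats::rnorm(1, min(user$reaction_mean, 0.7), 0.25))
  } else {
    draw_reaction(user)
  }
  if (!user$use_emg) {
    return(rt)
  }
  clench_start <- ceiling(rt / 0.2) * 0.2
  clench_end <- clench_start + 0.6
  trace <- synth_emg_trace(clench_end + 1.0,
    list(c(clench_start, clench_end)),
    model = user$emg
  )
  fires <- detect_validations(trace, cfg)
  if (nrow(fires) == 0) clench_end + 0.4 else fires$time_s[1]
}

#' Run one closed-loop session of a scenario task list
#'
#' Executes the full interaction loop for every task step: sensing and
#' target prioritization, mode selection (3 s alternating windows), P300
#' target selection (repeated trials until the decoder's prediction matches
#' the user's assigned target), validation, solution planning, navigation /
#' arm action, and logging. Dynamic "person" agents start walking away when
#' approached, exercising tracking-based replanning.
#'
#' @param scenario A [scenario_a()]-style scenario.
#' @param user A [simulated_user()].
#' @param decoder `"ideal"` (always-correct stub) or a [train_swlda()] model
#'   trained on the user's ERP statistics.
#' @param camera A [camera_model()].
#' @param seed Integer seed for all in-session randomness.
#' @param n_sequences Sequences per P300 trial.
#' @param max_trials Trial cap per selection before the session aborts.
#' @param dt Control period, seconds (the stack runs at 10 Hz).
#' @param replan_interval Seconds between tracking updates/replans for
#'   dynamic targets.
#' @param nav_tick_budget Tick budget per navigation before the deadloop
#'   rule resets the system.
#' @param converse_duration,drink_duration,arm_action_duration Durations of
#'   the passive/arm primitives, seconds (simulated time).
#' @return An object of class `session_log`: `events` tibble, `trajectory`
#'   tibble, `success` flag, `trial_duration` and the scenario name.
#'   [compute_metrics()] reduces it to the evaluation metrics.
#' @export
run_session <- function(scenario, user = ideal_user(), decoder = "ideal",
                        camera = camera_model(), seed = NULL,
                        n_sequences = 3, max_trials = 12, dt = 0.1,
                        replan_interval = 1.0, nav_tick_budget = 3000,
                        converse_duration = 2, drink_duration = 2,
                        arm_action_duration = 3) {
  with_seed(seed, run_session_impl(
    scenario, user, decoder, camera, n_sequences, max_trials, dt,
    replan_interval, nav_tick_budget, converse_duration, drink_duration,
    arm_action_duration
  ))
}

run_session_impl <- function(scenario, user, decoder, camera, n_sequences,
                             max_trials, dt, replan_interval,
                             nav_tick_budget, converse_duration,
                             drink_duration, arm_action_duration) {
  env <- new.env(parent = emptyenv())
  env$t <- 0
  env$world <- scenario$world
  env$world$cache <- new.env(parent = emptyenv())
  env$chair <- wheelchair_state(pose = scenario$start_pose)
  env$sm <- control_state(now = 0)
  env$events <- list()
  env$traj <- list()
  env$success <- TRUE
  env$abort <- FALSE
  env$walked <- FALSE
  env$approach_active <- FALSE # the guest walks once the approach begins
  trial_duration <- 6 * 0.2 * n_sequences

  ev <- function(type, ...) {
    env$events[[length(env$events) + 1]] <-
      tibble(t = env$t, type = type, ...)
  }
  log_pose <- function() {
    p <- env$chair$pose
    env$traj[[length(env$traj) + 1]] <- c(env$t, p)
  }
  advance <- function(command = c(0, 0, 0), exclude_ids = NULL) {
    res <- sim_step(env$world, env$chair, command, dt, exclude_ids)
    env$world <- res$world
    env$chair <- res$state
    env$t <- env$t + dt
    log_pose()
    update_walker()
    if ("collision" %in% res$events) {
      ev("collision_detail",
        note = sprintf("poly %s", attr(res$events, "poly") %||% NA)
      )
    }
    res$events
  }
  idle <- function(duration) {
    n <- max(0L, round(duration / dt))
    for (i in seq_len(n)) advance(c(0, 0, 0))
  }
  update_walker <- function() {
    objs <- env$world$objects
    i <- which(objs$class == "person" & objs$dynamic)
    if (length(i) == 0) return(invisible())
    i <- i[1]
    if (!env$walked) {
      d <- vnorm(c(objs$x[i], objs$y[i]) - env$chair$pose[1:2])
      if (env$approach_active && d < scenario$walk_trigger) {
        dir <- scenario$walk_to - c(objs$x[i], objs$y[i])
        if (vnorm(dir) > 0.05) {
          dir <- unitize(dir) * scenario$walk_speed
          env$world$objects$vx[i] <- dir[1]
          env$world$objects$vy[i] <- dir[2]
          env$walked <- TRUE
          ev("guest_walking")
        }
      }
    } else if (env$world$objects$vx[i] != 0 || env$world$objects$vy[i] != 0) {
      if (vnorm(c(objs$x[i], objs$y[i]) - scenario$walk_to) < 0.1) {
        env$world$objects$vx[i] <- 0
        env$world$objects$vy[i] <- 0
        ev("guest_stopped")
      }
    }
    invisible()
  }

  sense <- function(step) {
    sensed <- simulate_sensing(env$world, env$chair$pose, camera)
    ests <- list()
    for (i in seq_len(nrow(sensed$detections))) {
      est <- tryCatch(
        estimate_target(
          sensed$detections[i, ], sensed$cloud, env$chair$pose,
          time_s = env$t
        ),
        neurochair_localization_failure = function(e) {
          ev("localization_failure", step = step)
          NULL
        }
      )
      if (!is.null(est)) ests[[length(ests) + 1]] <- est
    }
    prioritize_targets(ests, env$chair$pose)
  }

  fire_validation <- function(necessary = TRUE, note = NA_character_) {
    delay <- validation_delay(user)
    delay <- ceiling(delay / dt) * dt
    idle(delay)
    ev("validation", necessary = necessary, note = note)
    delay
  }

  # --- mode selection: tick until the desired mode is validated ---
  select_mode <- function(desired, targets_present, step) {
    # SM may be in RESET from the previous step
    if (env$sm$state == "RESET") {
      env$sm <- sm_step(env$sm, "tick",
        now = env$t, targets_present = targets_present
      )
    }
    if (env$sm$state != "MODE_SELECT") {
      abort(sprintf("expected MODE_SELECT, found %s", env$sm$state))
    }
    ev("mode_select_enter", step = step, mode = desired)
    window_start <- env$t
    current <- env$sm$preactivated_mode
    fire_at <- NA_real_
    if (current == desired) {
      d <- validation_delay(user, anticipatory = TRUE)
      if (window_start + d < env$sm$mode_window_deadline) {
        fire_at <- ceiling((window_start + d) / dt) * dt
      }
    }
    budget <- 20000L
    repeat {
      budget <- budget - 1L
      if (budget <= 0L) abort("mode selection did not converge")
      if (!is.na(fire_at) && env$t >= fire_at) {
        env$sm <- sm_step(env$sm, "validation_fired",
          targets_present = targets_present
        )
        ev("validation", necessary = TRUE, note = "mode")
        ev("mode_selected", step = step, mode = desired)
        break
      }
      advance(c(0, 0, 0))
      prev <- env$sm$preactivated_mode
      env$sm <- sm_step(env$sm, "tick",
        now = env$t, targets_present = targets_present
      )
      if (env$sm$preactivated_mode != prev) {
        window_start <- env$t
        fire_at <- NA_real_
        if (env$sm$preactivated_mode == desired) {
          d <- validation_delay(user, anticipatory = TRUE)
          if (window_start + d < env$sm$mode_window_deadline) {
            fire_at <- ceiling((window_start + d) / dt) * dt
          }
        }
      }
    }
  }

  # --- P300 selection loop: trials until the prediction matches ---
  select_item <- function(attended_display, candidate_set, step) {
    trial <- 0L
    repeat {
      trial <- trial + 1L
      if (trial > max_trials) {
        ev("selection_failed", step = step)
        env$success <- FALSE
        env$abort <- TRUE
        return(invisible(NULL))
      }
      sched <- make_stimulus_schedule(0:5, n_sequences,
        trial_id = trial, start_time = env$t
      )
      predicted <- if (identical(decoder, "ideal")) {
        attended_display
      } else {
        rec <- synth_eeg_session(sched, attended_display, user$erp)
        rec <- bandpass_filter(rec, 2, 25)
        feats <- extract_epochs_and_featurize(rec, sched)
        score_and_classify(decoder, feats, candidate_set)$selected_index
      }
      idle(trial_duration)
      env$sm <- sm_step(env$sm, "p300_output", item = predicted)
      correct <- predicted == attended_display
      ev("p300_trial",
        step = step, trial = trial, predicted = predicted,
        attended = attended_display, correct = correct
      )
      if (correct) break
    }
    ev("selection_made", step = step, trial = trial)
    t_sel <- env$t
    fire_validation(necessary = TRUE, note = "selection")
    ev("validation_delay", step = step, delay = env$t - t_sel)
    env$sm <- sm_step(env$sm, "validation_fired")
    invisible(trial)
  }

  # --- navigation: plan + follow, tracking dynamic targets ---
  free_in_grid <- function(xy, exclude_ids = NULL) {
    grid <- occupancy_grid(env$world, exclude_ids = exclude_ids)
    cell <- grid_index(grid, xy)
    !grid$blocked[cell[1], cell[2]]
  }
  standoff_for <- function(goal_xy, ori, exclude_ids) {
    k <- 0
    while (k <= 30) {
      cand <- goal_xy + k * 0.05 * ori
      if (free_in_grid(cand, exclude_ids)) {
        return(cand)
      }
      k <- k + 1
    }
    NULL
  }
  # would an in-place rotation from the current heading to theta_goal keep
  # the footprint collision-free throughout the sweep?
  sweep_ok <- function(pose, theta_goal, exclude_ids = NULL) {
    err <- wrap_angle(theta_goal - pose[3])
    fp <- env$chair$footprint
    # margin absorbs the finite angular sampling of the sweep
    fp_m <- list(
      front = fp$front + 0.04, rear = fp$rear + 0.04,
      halfwidth = fp$halfwidth + 0.04
    )
    centre_off <- (fp$front - fp$rear) / 2
    centre <- pose[1:2] + as.numeric(rot2(pose[3]) %*% c(centre_off, 0))
    for (f in seq(0, 1, length.out = max(2, ceiling(abs(err) / 0.03)))) {
      th <- pose[3] + f * err
      p <- c(centre - as.numeric(rot2(th) %*% c(centre_off, 0)), th)
      if (footprint_collides(env$world, p, fp_m, exclude_ids)) {
        return(FALSE)
      }
    }
    TRUE
  }
  # is a straight-line translation at fixed heading collision-free?
  line_ok <- function(from_xy, to_xy, theta, exclude_ids = NULL,
                      margin = 0.01) {
    fp <- env$chair$footprint
    fp_m <- list(
      front = fp$front + margin, rear = fp$rear + margin,
      halfwidth = fp$halfwidth + margin
    )
    d <- vnorm(to_xy - from_xy)
    n <- max(2, ceiling(d / 0.025))
    for (f in seq(0, 1, length.out = n)) {
      p <- c(from_xy + f * (to_xy - from_xy), theta)
      if (footprint_collides(env$world, p, fp_m, exclude_ids)) {
        return(FALSE)
      }
    }
    TRUE
  }

  # string-pulling: reduce a grid waypoint list to the fewest straight
  # segments whose swept rectangle (at the segment's travel heading) is
  # collision-free; falls back to cell-by-cell where the corridor is tight
  simplify_waypoints <- function(wps, exclude_ids = NULL) {
    n <- nrow(wps)
    if (n <= 2) {
      return(wps[n, , drop = FALSE])
    }
    ends <- NULL
    i <- 1L
    while (i < n) {
      j <- n
      found <- FALSE
      while (j > i) {
        heading <- atan2(wps[j, 2] - wps[i, 2], wps[j, 1] - wps[i, 1])
        if (line_ok(wps[i, ], wps[j, ], heading, exclude_ids)) {
          found <- TRUE
          break
        }
        j_new <- i + floor((j - i) * 0.7)
        if (j_new >= j) j_new <- j - 1L
        j <- j_new
      }
      if (!found) j <- i + 1L
      ends <- rbind(ends, wps[j, ])
      i <- j
    }
    ends
  }

  rotate_to <- function(theta_goal, exclude_ids = NULL,
                        stop_before_contact = FALSE) {
    budget <- 600L
    fp <- env$chair$footprint
    fp_m <- list(
      front = fp$front + 0.02, rear = fp$rear + 0.02,
      halfwidth = fp$halfwidth + 0.02
    )
    centre_off <- (fp$front - fp$rear) / 2
    while (abs(wrap_angle(theta_goal - env$chair$pose[3])) > 0.02) {
      budget <- budget - 1L
      if (budget <= 0L) break
      err <- wrap_angle(theta_goal - env$chair$pose[3])
      omega <- sign(err) * min(0.6, abs(err) / dt)
      if (stop_before_contact) {
        # turn only as far as clearance allows
        pose <- env$chair$pose
        centre <- pose[1:2] + as.numeric(rot2(pose[3]) %*% c(centre_off, 0))
        th_next <- pose[3] + omega * dt
        cand <- c(
          centre - as.numeric(rot2(th_next) %*% c(centre_off, 0)), th_next
        )
        if (!isFALSE(footprint_collides(env$world, cand, fp_m,
          exclude_ids))) {
          break
        }
      }
      evs <- advance(c(0, 0, omega), exclude_ids)
      if ("collision" %in% evs) {
        return("collision")
      }
    }
    "ok"
  }

  # rotate in place if the sweep is clear; otherwise shift to a nearby
  # clear spot, rotate there, and translate back (holonomic maneuver)
  rotate_maneuver <- function(theta_goal, exclude_ids = NULL,
                              return_to_start = TRUE) {
    pose <- env$chair$pose
    if (abs(wrap_angle(theta_goal - pose[3])) < 0.02) {
      return("ok")
    }
    if (sweep_ok(pose, theta_goal, exclude_ids)) {
      return(rotate_to(theta_goal, exclude_ids))
    }
    dirs <- seq(0, 2 * pi, length.out = 9)[-9]
    for (r in c(0.4, 0.7, 1.0)) {
      for (a in dirs) {
        cand <- pose[1:2] + r * c(cos(a), sin(a))
        if (!line_ok(pose[1:2], cand, pose[3], exclude_ids)) next
        if (!sweep_ok(c(cand, pose[3]), theta_goal, exclude_ids)) next
        if (return_to_start &&
          !line_ok(cand, pose[1:2], theta_goal, exclude_ids)) {
          next
        }
        st <- translate_to(cand, exclude_ids)
        if (st != "ok") {
          return(st)
        }
        st <- rotate_to(theta_goal, exclude_ids)
        if (st != "ok") {
          return(st)
        }
        if (!return_to_start) {
          return("ok")
        }
        return(translate_to(pose[1:2], exclude_ids))
      }
    }
    # no clear maneuver: rotate only as far as the clearance allows
    rotate_to(theta_goal, exclude_ids, stop_before_contact = TRUE)
  }
  translate_to <- function(xy, exclude_ids = NULL, budget = 1000L) {
    # docking motion: drives to xy, but stops at contact margin with the
    # confirmed target (reaching the target is the goal semantics)
    while (vnorm(xy - env$chair$pose[1:2]) > 0.02) {
      budget <- budget - 1L
      if (budget <= 0L) {
        return("budget")
      }
      to <- xy - env$chair$pose[1:2]
      v_world <- unitize(to) * min(0.4, max(0.1, vnorm(to) / dt))
      cand <- env$chair$pose
      cand[1:2] <- cand[1:2] + v_world * dt
      if (!is.null(exclude_ids) &&
        footprint_hits_objects(env$world, cand, exclude_ids)) {
        return("contact") # arrived at contact margin with the target
      }
      v_body <- as.numeric(rot2(-env$chair$pose[3]) %*% v_world)
      evs <- advance(c(v_body[1], v_body[2], 0), exclude_ids)
      if ("collision" %in% evs) {
        return("collision")
      }
    }
    "ok"
  }

  navigate_to <- function(goal_pose, target, step, dynamic = FALSE,
                          exclude_ids = NULL, final_rotate = TRUE) {
    goal <- goal_pose
    next_track <- env$t + replan_interval
    path <- NULL
    replan <- function() {
      # the target stays an obstacle for planning; only the final docking
      # motion (translate_to) is allowed to close in on it
      ori <- target$orientation
      stand <- standoff_for(goal[1:2], ori, NULL)
      if (is.null(stand)) stand <- goal[1:2]
      p <- plan_path(env$world, env$chair$pose, c(stand, goal[3]))
      if (p$status != "ok") {
        # NV rule: distinguish "no path exists" from planner failure
        probe <- plan_path(env$world, env$chair$pose, c(stand, goal[3]),
          inflate = 0.25
        )
        kind <- if (probe$status == "ok") "planning_failure" else
          "unreachable"
        ev("nav_failure", step = step, note = kind)
        env$success <- FALSE
        env$abort <- TRUE
        return(NULL)
      }
      p
    }
    path <- replan()
    if (is.null(path)) return("failed")

    fail_nav <- function(kind) {
      ev(kind, step = step)
      env$sm <- sm_step(
        env$sm, if (kind == "deadloop") "deadloop" else "collision"
      )
      env$success <- FALSE
      env$abort <- TRUE
      "failed"
    }

    if (!dynamic) {
      # execute the simplified path: rotate to each segment's heading
      # (sweep-checked maneuver), then translate along the verified
      # corridor; a contact stop on the confirmed target ends the drive
      wps <- cbind(path$waypoints$x, path$waypoints$y)
      wps[1, ] <- env$chair$pose[1:2]
      if (!final_rotate && nrow(wps) > 1) {
        # keep the transit endpoint on its grid cell centre
        grid <- occupancy_grid(env$world)
        cell <- grid_index(grid, goal[1:2])
        wps[nrow(wps), ] <- c(grid$cx[cell[1]], grid$cy[cell[2]])
      }
      ends <- simplify_waypoints(wps, exclude_ids)
      contact <- FALSE
      for (k in seq_len(nrow(ends))) {
        to_xy <- ends[k, ]
        seg_len <- vnorm(to_xy - env$chair$pose[1:2])
        if (seg_len < 0.03) next
        # long traverses align the chassis with the travel direction so
        # the half-width corridor clearance applies; short moves stay at
        # the current heading when that corridor is clear (holonomic
        # translation), else they align too
        need_align <- seg_len >= 0.8 ||
          !line_ok(env$chair$pose[1:2], to_xy, env$chair$pose[3],
            exclude_ids,
            margin = 0.02
          )
        if (need_align) {
          heading <- atan2(
            to_xy[2] - env$chair$pose[2], to_xy[1] - env$chair$pose[1]
          )
          st <- rotate_maneuver(heading, exclude_ids)
          if (st == "contact") st <- "ok"
          if (st != "ok") {
            return(fail_nav(if (st == "budget") "deadloop" else
              "collision"))
          }
        }
        st <- translate_to(to_xy, exclude_ids)
        if (st == "contact") {
          contact <- TRUE
          break
        }
        if (st != "ok") {
          return(fail_nav(if (st == "budget") "deadloop" else "collision"))
        }
      }
      if (!contact && final_rotate) {
        # dock on the exact goal; a doorway transit (final_rotate FALSE)
        # instead ends on the grid path, whose channel clearance does not
        # depend on the target estimate
        st <- translate_to(goal[1:2], exclude_ids)
        if (!st %in% c("ok", "contact")) {
          return(fail_nav(if (st == "budget") "deadloop" else "collision"))
        }
      }
      if (final_rotate) {
        st <- rotate_maneuver(goal[3], exclude_ids)
        if (st == "contact") st <- "ok"
        if (st != "ok") {
          return(fail_nav(if (st == "budget") "deadloop" else "collision"))
        }
      }
    } else {
      # closed-loop chase of a moving target: disc-follow the waypoints,
      # keep the camera on the target, track and replan as it moves
      ticks <- 0L
      wp_i <- 1L
      repeat {
        ticks <- ticks + 1L
        if (ticks > nav_tick_budget) {
          return(fail_nav("deadloop"))
        }
        if (env$t >= next_track) {
          next_track <- env$t + replan_interval
          upd <- tryCatch(
            track_update(target, env$world, env$chair$pose, camera,
              time_s = env$t
            ),
            neurochair_tracking_failure = function(e) {
              ev("tracking_failure", step = step)
              env$sm <- sm_step(env$sm, "collision") # abort to reset
              env$success <- FALSE
              env$abort <- TRUE
              NULL
            }
          )
          if (is.null(upd)) {
            return("failed")
          }
          target <- upd
          new_xy <- target$position[1:2] + 0.8 * target$orientation
          moved <- vnorm(new_xy - goal[1:2]) > 0.3
          goal <- c(new_xy, atan2(
            target$position[2] - new_xy[2], target$position[1] - new_xy[1]
          ))
          if (moved) {
            path <- replan()
            if (is.null(path)) {
              return("failed")
            }
            wp_i <- 1L
          }
        }
        wps <- path$waypoints
        while (wp_i < nrow(wps) &&
          vnorm(c(wps$x[wp_i], wps$y[wp_i]) - env$chair$pose[1:2]) < 0.06) {
          wp_i <- wp_i + 1L
        }
        wp <- c(wps$x[wp_i], wps$y[wp_i])
        to <- wp - env$chair$pose[1:2]
        if (wp_i >= nrow(wps) && vnorm(to) < 0.05) {
          if (env$walked) {
            i <- which(env$world$objects$class == "person")[1]
            moving <- abs(env$world$objects$vx[i]) +
              abs(env$world$objects$vy[i]) > 0
            if (moving) {
              advance(c(0, 0, 0))
              next
            }
          }
          break
        }
        v_world <- unitize(to) * min(0.4, max(0.1, vnorm(to) / dt))
        v_body <- as.numeric(rot2(-env$chair$pose[3]) %*% v_world)
        bearing <- atan2(
          target$position[2] - env$chair$pose[2],
          target$position[1] - env$chair$pose[1]
        )
        err <- wrap_angle(bearing - env$chair$pose[3])
        omega <- sign(err) * min(0.6, 2 * abs(err))
        evs <- advance(c(v_body[1], v_body[2], omega), exclude_ids)
        if ("collision" %in% evs) {
          return(fail_nav("collision"))
        }
      }
      st <- translate_to(goal[1:2], exclude_ids)
      if (!st %in% c("ok", "contact")) {
        return(fail_nav(if (st == "budget") "deadloop" else "collision"))
      }
      st <- rotate_maneuver(goal[3], exclude_ids)
      if (st == "contact") st <- "ok"
      if (st != "ok") {
        return(fail_nav("collision"))
      }
    }
    ev("nav_done",
      step = step, x = env$chair$pose[1],
      y = env$chair$pose[2]
    )
    "ok"
  }

  execute_solution <- function(target, step) {
    sol <- tryCatch(
      plan_solution(target, env$chair$pose),
      neurochair_solution_rejected = function(e) {
        ev("solution_rejected", step = step, note = conditionMessage(e))
        env$success <- FALSE
        env$abort <- TRUE
        NULL
      }
    )
    if (is.null(sol)) {
      return(invisible())
    }
    ev("solution_planned",
      step = step, note = sol$group,
      x = sol$goal_pose[1], y = sol$goal_pose[2]
    )
    dynamic <- target$class == "person"
    if (dynamic) env$approach_active <- TRUE
    excl <- as.integer(target$target_id)

    # close-range targets: approach a coarse standoff first, refresh the
    # estimate from the head-on view (tracking update), and re-plan, so
    # the dock heading is square to the target face (and a doorway is
    # entered on its axis rather than from the first oblique sighting)
    if (sol$group %in% c("conversation", "approach") && !dynamic) {
      # far enough out that an in-place turn (front corner sweep ~0.4 m,
      # rear sweep ~1.1 m about the chassis centre) cannot clip the target;
      # search direction offsets for a standoff with full swing clearance
      d_pre <- max(1.0, 0.2 + solution_rules()$approach_distance[
        solution_rules()$class == target$class
      ])
      fpgeo <- env$chair$footprint
      # corner distance from the rotation (chassis) centre
      swing <- sqrt(((fpgeo$front + fpgeo$rear) / 2)^2 + fpgeo$halfwidth^2)
      centre_off <- (fpgeo$front - fpgeo$rear) / 2
      disc_clear <- function(xy, r) {
        for (poly in blocking_polygons(env$world)) {
          if (min(dist_points_polygon(matrix(xy, 1), poly)) < r) {
            return(FALSE)
          }
        }
        TRUE
      }
      pre_goal <- NULL
      for (off in c(0, -15, 15, -30, 30, -45, 45) * pi / 180) {
        for (extra in c(0, 0.2, 0.4)) {
          dir <- as.numeric(rot2(off) %*% target$orientation)
          pre <- target$position[1:2] + (d_pre + extra) * dir
          heading <- atan2(
            target$position[2] - pre[2], target$position[1] - pre[1]
          )
          ctr <- pre + as.numeric(rot2(heading) %*% c(centre_off, 0))
          if (free_in_grid(pre) && disc_clear(ctr, swing + 0.02)) {
            pre_goal <- c(pre, heading)
            break
          }
        }
        if (!is.null(pre_goal)) break
      }
      if (is.null(pre_goal)) {
        pre <- target$position[1:2] + d_pre * target$orientation
        pre_goal <- c(pre, atan2(
          target$position[2] - pre[2], target$position[1] - pre[1]
        ))
      }
      st <- navigate_to(pre_goal, target, step, exclude_ids = excl)
      if (st != "ok") {
        return(invisible())
      }
      upd <- tryCatch(
        track_update(target, env$world, env$chair$pose, camera,
          time_s = env$t
        ),
        neurochair_tracking_failure = function(e) {
          ev("tracking_failure", step = step)
          env$sm <- sm_step(env$sm, "collision")
          env$success <- FALSE
          env$abort <- TRUE
          NULL
        }
      )
      if (is.null(upd)) {
        return(invisible())
      }
      target <- upd
      sol <- plan_solution(target, env$chair$pose)
    }

    i <- 1L
    while (i <= nrow(sol$actions)) {
      act <- sol$actions[i, ]
      ev("action_start", step = step, note = act$primitive)
      if (sol$group == "pass_through" && act$primitive == "PASS_THROUGH") {
        # refresh the doorway estimate from the standoff before committing
        # to the transit (tracking updates the goal during navigation)
        upd <- tryCatch(
          track_update(target, env$world, env$chair$pose, camera,
            time_s = env$t
          ),
          neurochair_tracking_failure = function(e) NULL
        )
        if (!is.null(upd)) {
          target <- upd
          sol2 <- plan_solution(target, env$chair$pose)
          act <- sol2$actions[sol2$actions$primitive == "PASS_THROUGH", ]
        }
      }
      if (act$primitive %in% c(
        "NAV_TO_POSE", "PASS_THROUGH", "ADJUST_UNTIL_IN_WORKSPACE"
      )) {
        goal <- c(act$goal_x, act$goal_y, act$goal_theta)
        st <- navigate_to(goal, target, step,
          dynamic = dynamic, exclude_ids = excl,
          # a doorway transit keeps its travel heading: rotating in place
          # while straddling the frame has no clearance
          final_rotate = !identical(act$primitive, "PASS_THROUGH")
        )
        if (st != "ok") {
          return(invisible())
        }
        if (act$primitive == "ADJUST_UNTIL_IN_WORKSPACE") {
          box <- workspace_box_body(arm_workspace())
          in_ws <- FALSE
          for (try in 1:4) {
            body <- world_to_body(
              matrix(target$position[1:2], 1), env$chair$pose
            )
            in_ws <- body[1] >= box$x[1] && body[1] <= box$x[2] &&
              body[2] >= box$y[1] && body[2] <= box$y[2] &&
              target$position[3] >= box$z[1] &&
              target$position[3] <= box$z[2]
            if (in_ws) break
            # holonomic micro-adjustment: re-centre the target in the
            # workspace from the achieved pose and heading
            th <- env$chair$pose[3]
            want <- c(mean(box$x), mean(box$y))
            goal_xy <- target$position[1:2] -
              as.numeric(rot2(th) %*% want)
            st <- translate_to(goal_xy, excl)
            if (st != "ok") break
          }
          if (!in_ws) {
            ev("solution_rejected",
              step = step,
              note = "target not in workspace after adjustment"
            )
            env$success <- FALSE
            env$abort <- TRUE
            return(invisible())
          }
        }
      } else { # arm primitives
        idle(arm_action_duration)
        ev("arm_action", step = step, note = act$primitive)
      }
      i <- i + 1L
    }
    env$sm <- sm_step(env$sm, "task_done")
    ev("task_done", step = step)
    invisible()
  }

  execute_command <- function(command, amount, step,
                              target_heading = NA_real_) {
    menu <- command_menu()
    row <- menu[menu$command == command, ]
    speed <- 0.3
    omega <- 0.5
    start_pose <- env$chair$pose
    if (row$omega != 0 && !is.na(target_heading)) {
      # the user steers by sight toward the objective heading, shuffling
      # clear first when an in-place turn would not fit
      st <- rotate_maneuver(target_heading, return_to_start = FALSE)
      if (st != "ok") {
        ev("collision", step = step)
        env$sm <- sm_step(env$sm, "collision")
        env$success <- FALSE
        env$abort <- TRUE
        return(invisible())
      }
      fire_validation(necessary = TRUE, note = "cease")
      env$sm <- sm_step(env$sm, "validation_fired")
      ev("command_done", step = step, note = command)
      return(invisible())
    }
    budget <- 2000L
    repeat {
      budget <- budget - 1L
      if (budget <= 0L) break
      done <- if (row$omega != 0) {
        abs(wrap_angle(env$chair$pose[3] - start_pose[3])) >=
          amount - omega * dt / 2
      } else {
        vnorm(env$chair$pose[1:2] - start_pose[1:2]) >=
          amount - speed * dt / 2
      }
      if (done) break
      cmd <- c(row$vx * speed, row$vy * speed, row$omega * omega)
      evs <- advance(cmd)
      if ("collision" %in% evs) {
        ev("collision", step = step)
        env$sm <- sm_step(env$sm, "collision")
        env$success <- FALSE
        env$abort <- TRUE
        return(invisible())
      }
    }
    # second validation ceases the command
    fire_validation(necessary = TRUE, note = "cease")
    env$sm <- sm_step(env$sm, "validation_fired")
    ev("command_done", step = step, note = command)
    invisible()
  }

  log_pose()
  run_step <- function(task) {
    if (task$mode == "none") {
      if (task$action == "drink") idle(drink_duration)
      if (task$action == "converse") idle(converse_duration)
      ev("passive_done", step = task$step, note = task$action)
      return(invisible())
    }
    if (task$mode == "auto") {
      targets <- sense(task$step)
      retries <- 3L
      while (!task$target_class %in% targets$class && retries > 0L) {
        idle(0.5)
        targets <- sense(task$step)
        retries <- retries - 1L
      }
      # target class out of view: the user pans the chassis (command-mode
      # turning) until the camera picks it up
      scan <- 0L
      while (!task$target_class %in% targets$class && scan < 6L) {
        rotate_maneuver(
          wrap_angle(env$chair$pose[3] + pi / 3),
          return_to_start = FALSE
        )
        targets <- sense(task$step)
        scan <- scan + 1L
      }
      if (!task$target_class %in% targets$class) {
        ev("localization_failure", step = task$step)
        env$success <- FALSE
        env$abort <- TRUE
        return(invisible())
      }
      select_mode("auto", targets_present = nrow(targets) > 0,
        step = task$step)
      att_row <- which(targets$class == task$target_class)[1]
      attended <- targets$display_index[att_row]
      candidate_set <- targets$display_index
      select_item(attended, candidate_set, task$step)
      if (env$abort) return(invisible())
      execute_solution(targets$estimate[[att_row]], task$step)
    } else { # command mode
      targets <- sense(task$step)
      select_mode("command", targets_present = nrow(targets) > 0,
        step = task$step)
      menu <- command_menu()
      attended <- menu$display_index[menu$command == task$command]
      select_item(attended, 0:5, task$step)
      if (env$abort) return(invisible())
      execute_command(
        task$command, task$amount, task$step,
        task$target_heading %||% NA_real_
      )
    }
    invisible()
  }

  for (si in seq_len(nrow(scenario$tasks))) {
    if (env$abort) break
    task <- scenario$tasks[si, ]
    ev("task_step", step = task$step, mode = task$mode, note = task$action)
    # a collision / perception failure stops and resets the system; the
    # logged deduction stands, and the user re-attempts the step (the
    # evaluation counts deductions separately from session success)
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      run_step(task)
      if (!env$abort) break
      if (attempts >= 3L) break
      env$abort <- FALSE
      env$success <- TRUE
      ev("step_retry", step = task$step, note = sprintf("attempt %d",
        attempts + 1L))
      env$sm <- control_state(now = env$t) # full system reset
      idle(0.5)
    }
    if (env$abort) break
    # RESET -> MODE_SELECT on the next tick
    if (env$sm$state == "RESET") {
      advance(c(0, 0, 0))
      env$sm <- sm_step(env$sm, "tick", now = env$t)
    }
  }
  ev(if (env$success) "session_complete" else "session_failed")

  traj <- do.call(rbind, env$traj)
  structure(
    list(
      events = bind_rows(env$events),
      trajectory = tibble(
        t = traj[, 1], x = traj[, 2], y = traj[, 3], theta = traj[, 4]
      ),
      success = env$success,
      trial_duration = trial_duration,
      scenario_name = scenario$name,
      final_pose = env$chair$pose,
      final_objects = env$world$objects
    ),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf(
    "<session_log %s> %d events, %.1f s simulated, %s\n",
    x$scenario_name, nrow(x$events), max(x$trajectory$t),
    if (x$success) "completed" else "FAILED"
  ))
  invisible(x)
}

#' @describeIn run_session The session's event table.
#' @param x,object A `session_log`.
#' @param ... Unused.
#' @export
tidy.session_log <- function(x, ...) x$events

#' @describeIn run_session One-row metric summary (see [compute_metrics()]).
#' @export
glance.session_log <- function(x, ...) compute_metrics(x)

#' Plot a session trajectory over the scenario map
#'
#' @param log A `session_log`.
#' @param scenario The scenario it was run on.
#' @return A ggplot object.
#' @export
plot_session <- function(log, scenario) {
  plot_world(scenario$world, trajectory = log$trajectory,
    pose = log$final_pose)
}
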