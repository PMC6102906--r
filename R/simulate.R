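#' Wheelchair kinematic state
#'
#' Pose and body-frame velocity of the omnidirectional chassis. The chassis
#' is holonomic (mecanum wheels): it translates in any planar direction and
#' rotates with zero radius. Translation speed, when non-zero, is clamped to
#' the configured limits (0.1-0.4 m/s).
#'
#' @param pose `c(x, y, theta)` world frame.
#' @param velocity Body-frame `c(vx, vy, omega)`.
#' @param footprint List with `front`, `rear`, `halfwidth` extents, metres.
#' @param v_min,v_max Translation speed limits, m/s.
#' @return An object of class `wheelchair_state`.
#' @export
wheelchair_state <- function(pose = c(0, 0, 0), velocity = c(0, 0, 0),
                             footprint = default_footprint(),
                             v_min = 0.1, v_max = 0.4) {
  structure(
    list(
      pose = pose, velocity = velocity, footprint = footprint,
      v_min = v_min, v_max = v_max
    ),
    class = "wheelchair_state"
  )
}

# Clamp a commanded body-frame translation to the speed limits.
clamp_speed <- function(vx, vy, v_min, v_max) {
  sp <- sqrt(vx^2 + vy^2)
  if (sp == 0) {
    return(c(0, 0))
  }
  sp_c <- min(v_max, max(v_min, sp))
  c(vx, vy) * sp_c / sp
}

#' Advance the simulation by one control step
#'
#' Holonomic integration of the commanded body-frame velocity at the control
#' rate (10 Hz by default), with the speed clamp applied; dynamic agents
#' advance by their own velocities. If the motion would drive the footprint
#' into an obstacle, the wheelchair halts at its previous pose and a
#' collision event is emitted.
#'
#' @param world A [world()].
#' @param state A [wheelchair_state()].
#' @param command Body-frame `c(vx, vy, omega)` (m/s, m/s, rad/s).
#' @param dt Step length, seconds.
#' @param exclude_ids Object ids exempt from collision (docking target).
#' @return List `(world, state, events)`; `events` is a character vector
#'   (possibly empty, may contain `"collision"`).
#' @export
sim_step <- function(world, state, command, dt = 0.1, exclude_ids = NULL) {
  if (dt <= 0) abort("`dt` must be positive")
  v <- clamp_speed(command[1], command[2], state$v_min, state$v_max)
  omega <- command[3]
  pose <- state$pose
  # rigid-body motion: translation applies to the chassis, rotation is
  # about the chassis centre (the pose reference sits near the front)
  centre_off <- (state$footprint$front - state$footprint$rear) / 2
  centre <- pose[1:2] + as.numeric(rot2(pose[3]) %*% c(centre_off, 0))
  disp <- as.numeric(rot2(pose[3]) %*% v) * dt
  theta_new <- wrap_angle(pose[3] + omega * dt)
  centre_new <- centre + disp
  new_pose <- c(
    centre_new - as.numeric(rot2(theta_new) %*% c(centre_off, 0)),
    theta_new
  )

  # advance dynamic agents
  objs <- world$objects
  if (nrow(objs) > 0) {
    dyn <- objs$dynamic & (abs(objs$vx) + abs(objs$vy) > 0)
    if (any(dyn)) {
      objs$x[dyn] <- objs$x[dyn] + objs$vx[dyn] * dt
      objs$y[dyn] <- objs$y[dyn] + objs$vy[dyn] * dt
      world$objects <- objs
    }
  }

  events <- character(0)
  hit <- footprint_collides(world, new_pose, state$footprint, exclude_ids)
  if (!isFALSE(hit)) {
    events <- "collision"
    attr(events, "poly") <- hit
    new_pose <- pose # halt at contact
    state$velocity <- c(0, 0, 0)
  } else {
    state$velocity <- c(v, omega)
  }
  state$pose <- new_pose
  list(world = world, state = state, events = events)
}
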