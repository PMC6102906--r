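#' The ten recognized target classes
#'
#' @return Character vector of class names.
#' @export
target_classes <- function() {
  c(
    "chair", "opened_door", "closed_door", "bed", "sofa",
    "desk", "person", "bottle", "electric_switch", "cup"
  )
}

#' Default class priority ranking
#'
#' Smaller rank = higher priority. People outrank furniture (a person has a
#' higher priority than a chair); within a class, closer objects outrank
#' farther ones. The full ordering across the ten classes is a configurable
#' convention of this package.
#'
#' @return Named integer vector, rank per class.
#' @export
default_priority <- function() {
  c(
    person = 1L, opened_door = 2L, closed_door = 3L, bottle = 4L,
    cup = 5L, electric_switch = 6L, chair = 7L, sofa = 8L,
    desk = 9L, bed = 10L
  )
}

#' The four target-solution groups
#'
#' The ten classes partition into four solution rules: conversation targets
#' (stop at 80 cm, facing), approach targets (stop at 20 cm, facing),
#' pass-through (opened door), and arm manipulation (press or pick).
#'
#' @return A tibble with columns `class`, `group`, `approach_distance`.
#' @export
solution_rules <- function() {
  tibble(
    class = c(
      "person", "chair", "sofa",
      "bed", "closed_door", "desk",
      "opened_door",
      "electric_switch", "bottle", "cup"
    ),
    group = c(
      rep("conversation", 3), rep("approach", 3),
      "pass_through", rep("manipulate", 3)
    ),
    approach_distance = c(rep(0.80, 3), rep(0.20, 3), NA, NA, NA, NA)
  )
}

#' Robotic-arm workspace box
#'
#' Calibrated operating box of the end effector, in the arm frame (metres):
#' x in (-0.2, 0), y in (0, 0.35), z in (-0.15, 0.3). The body-to-arm
#' transform places the arm base over the left armrest; axes are aligned
#' with the body frame.
#'
#' @param x,y,z Numeric ranges `c(min, max)` per axis, metres.
#' @param origin_body Arm-base origin in the body frame, metres.
#' @return An object of class `arm_workspace`.
#' @export
arm_workspace <- function(x = c(-0.20, 0), y = c(0, 0.35),
                          z = c(-0.15, 0.30),
                          origin_body = c(0.65, -0.05, 0.70)) {
  for (rng in list(x, y, z)) {
    if (length(rng) != 2 || rng[1] >= rng[2]) {
      abort("workspace ranges must be c(min, max) with min < max")
    }
  }
  structure(
    list(x = x, y = y, z = z, origin_body = origin_body),
    class = "arm_workspace"
  )
}

# Body-frame coordinates of the workspace box (axes aligned).
workspace_box_body <- function(ws) {
  list(
    x = ws$x + ws$origin_body[1],
    y = ws$y + ws$origin_body[2],
    z = ws$z + ws$origin_body[3]
  )
}

#' Order detected targets by priority
#'
#' Sorts estimates by class rank (see [default_priority()]) then by distance
#' to the wheelchair (ascending) and keeps at most six, assigning display
#' indices 0-5 that map onto the six oddball stimuli. The first row is the
#' default selection.
#'
#' @param estimates List of [target_estimate()] objects (may be empty).
#' @param wheelchair_pose Pose `c(x, y, theta)`.
#' @param priority Named rank vector, as [default_priority()].
#' @return A tibble with columns `display_index` (0-5), `target_id`,
#'   `class`, `distance`, `rank` and a list-column `estimate`.
#' @export
prioritize_targets <- function(estimates, wheelchair_pose,
                               priority = default_priority()) {
  if (length(estimates) == 0) {
    return(tibble(
      display_index = integer(), target_id = integer(),
      class = character(), distance = double(), rank = integer(),
      estimate = list()
    ))
  }
  df <- tibble(
    target_id = map_dbl(estimates, ~ as.numeric(.x$target_id)),
    class = vapply(estimates, function(e) e$class, character(1)),
    distance = map_dbl(
      estimates,
      ~ vnorm(.x$position[1:2] - wheelchair_pose[1:2])
    ),
    estimate = estimates
  )
  df$rank <- unname(priority[df$class])
  df$rank[is.na(df$rank)] <- max(priority) + 1L
  df <- df %>%
    arrange(.data$rank, .data$distance) %>%
    slice_head(n = 6) %>%
    mutate(display_index = row_number() - 1L) %>%
    select(
      "display_index", "target_id", "class", "distance", "rank", "estimate"
    )
  df
}

#' Plan the solution for a confirmed target
#'
#' Maps the target's class to its solution group and emits the action
#' sequence with a goal pose:
#' * conversation targets (person/chair/sofa): navigate to a pose 0.80 m from
#'   the target centre along the target's orientation, heading facing the
#'   target;
#' * approach targets (bed/closed door/desk): the same at 0.20 m;
#' * opened door: navigate to a standoff pose before the doorway, then pass
#'   through to a goal beyond it along the door normal;
#' * electric switch / bottle / cup: check the target height against the arm
#'   workspace (the chassis cannot change z); if reachable, translate the
#'   wheelchair until the target enters the workspace, then press (switch)
#'   or pick and carry to the mouth (bottle/cup). An out-of-reach height
#'   signals a classed rejection error `neurochair_solution_rejected`.
#'
#' @param target A [target_estimate()].
#' @param wheelchair_pose Pose `c(x, y, theta)`.
#' @param workspace An [arm_workspace()].
#' @param pass_through_clearance Metres beyond the doorway centre for the
#'   pass-through goal; the default places the chassis centre past the
#'   door plane so an in-place turn is possible afterwards.
#' @param standoff Standoff distance before a doorway, metres.
#' @return A list of class `target_solution`: `class`, `group`, `actions`
#'   (tibble `step`, `primitive`, and parameter columns `goal_x`, `goal_y`,
#'   `goal_theta`), and `goal_pose` (final navigation pose).
#' @export
plan_solution <- function(target, wheelchair_pose,
                          workspace = arm_workspace(),
                          pass_through_clearance = 1.25,
                          standoff = 0.6) {
  rules <- solution_rules()
  if (!target$class %in% rules$class) {
    abort(sprintf("unknown target class '%s'", target$class))
  }
  rule <- rules[rules$class == target$class, ]
  centre <- target$position[1:2]
  ori <- target$orientation # unit vector, points toward the wheelchair

  face_pose <- function(stop_xy) {
    c(stop_xy, atan2(centre[2] - stop_xy[2], centre[1] - stop_xy[1]))
  }

  if (rule$group %in% c("conversation", "approach")) {
    d <- rule$approach_distance
    goal <- face_pose(centre + d * ori)
    actions <- tibble(
      step = 1L, primitive = "NAV_TO_POSE",
      goal_x = goal[1], goal_y = goal[2], goal_theta = goal[3]
    )
  } else if (rule$group == "pass_through") {
    # crossing direction: the doorway's elongation (first principal axis
    # of the frame cloud) runs along the wall, so its in-plane orthogonal
    # is the door normal; sign it away from the wheelchair. This stays
    # well-defined even when the door is sighted near 45 degrees, where
    # the v/vn orientation pick is ambiguous.
    f <- target$f_vector
    major <- target$major_axis %||% c(-ori[2], ori[1])
    through <- unitize(c(-major[2], major[1]))
    if (sum(through * f) < 0) through <- -through
    pre <- face_pose(centre - standoff * through)
    beyond <- centre + pass_through_clearance * through
    post <- c(beyond, pre[3])
    actions <- tibble(
      step = 1:2, primitive = c("NAV_TO_POSE", "PASS_THROUGH"),
      goal_x = c(pre[1], post[1]), goal_y = c(pre[2], post[2]),
      goal_theta = c(pre[3], post[3])
    )
    goal <- post
  } else { # manipulate
    box <- workspace_box_body(workspace)
    z <- target$position[3]
    if (z < box$z[1] || z > box$z[2]) {
      abort(
        sprintf(
          "target height %.2f m is outside the arm workspace (%.2f..%.2f m)",
          z, box$z[1], box$z[2]
        ),
        class = "neurochair_solution_rejected"
      )
    }
    # translate the chassis so the target lands at the workspace centre (xy)
    want_body <- c(mean(box$x), mean(box$y))
    theta <- wheelchair_pose[3]
    goal_xy <- centre - as.numeric(rot2(theta) %*% want_body)
    goal <- c(goal_xy, theta)
    op <- if (target$class == "electric_switch") "ARM_PRESS" else "ARM_PICK"
    prim <- c("ADJUST_UNTIL_IN_WORKSPACE", op)
    if (op == "ARM_PICK") prim <- c(prim, "ARM_TO_MOUTH")
    actions <- tibble(
      step = seq_along(prim), primitive = prim,
      goal_x = c(goal[1], rep(NA, length(prim) - 1)),
      goal_y = c(goal[2], rep(NA, length(prim) - 1)),
      goal_theta = c(goal[3], rep(NA, length(prim) - 1))
    )
  }
  structure(
    list(
      class = target$class, group = rule$group,
      actions = actions, goal_pose = goal
    ),
    class = "target_solution"
  )
}

#' @export
print.target_solution <- function(x, ...) {
  cat(sprintf(
    "<target_solution> %s (%s): %s\n", x$class, x$group,
    paste(x$actions$primitive, collapse = " -> ")
  ))
  invisible(x)
}

#' The six direct wheelchair commands of the command-control mode
#'
#' @return Tibble mapping display indices 0-5 to motion commands
#'   (body-frame velocities `vx`, `vy` and angular rate `omega`).
#' @export
command_menu <- function() {
  tibble(
    display_index = 0:5,
    command = c(
      "forward", "backward", "translate_left", "translate_right",
      "rotate_left", "rotate_right"
    ),
    vx = c(1, -1, 0, 0, 0, 0),
    vy = c(0, 0, 1, -1, 0, 0),
    omega = c(0, 0, 0, 0, 1, -1)
  )
}
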