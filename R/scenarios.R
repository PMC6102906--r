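#' Scenario fixtures
#'
#' Plausible reconstructions of the two evaluation environments: scenario A
#' is a sickroom with a desk (bottles on top) opening through an 80 cm door
#' onto a long gallery where a person stands (and walks off when
#' approached); scenario B is a laboratory flat with furniture (chairs,
#' desk, cabinet, boxes) across two rooms. Each scenario bundles a [world()],
#' a start pose and the predesigned task list.
#'
#' Task list columns: `step`, `mode` (`"auto"`, `"command"` or `"none"`),
#' `action` (`"goto"`, `"pick"`, `"pass_door"`, `"move"`, `"rotate"`,
#' `"drink"`, `"converse"`), `target_class` (for auto steps), `command`
#' (for command steps), `amount` (metres or radians) and `target_heading`
#' (for turns: the simulated user keeps rotating until this world-frame
#' heading is reached, emulating closed-loop visual steering).
#'
#' @param door_width Doorway width, metres (80 cm in the evaluation).
#' @return A list of class `scenario`: `name`, `world`, `start_pose`,
#'   `tasks`.
#' @export
scenario_a <- function(door_width = 0.8) {
  wt <- 0.1 # wall thickness
  gap <- c(1.4 - door_width / 2, 1.4 + door_width / 2)
  obstacles <- list(
    rect_poly(-wt, 0, -wt, 4 + wt), # west wall
    rect_poly(-wt, 5.6 + wt, 4, 4 + wt), # north wall (room + gallery)
    rect_poly(-wt, 4.1, -wt, 0), # room south wall
    rect_poly(4, 4.1, -wt, gap[1]), # room east wall below the door
    rect_poly(4, 4.1, gap[2], 4 + wt), # room east wall above the door
    rect_poly(4, 4.1, -6.1, -wt), # gallery west wall
    rect_poly(5.6, 5.6 + wt, -6.1, 4 + wt), # gallery east wall
    rect_poly(4, 5.6 + wt, -6.2, -6.1) # gallery south end
  )
  doorways <- tibble(
    x = 4.05, y = 1.4, width = door_width, normal_theta = 0
  )
  objects <- bind_rows(
    world_object(1, "desk",
      x = 2.0, y = 3.7, theta = -pi / 2,
      width = 1.2, depth = 0.6, height = 0.75, shape = "box"
    ),
    world_object(2, "bottle",
      x = 2.05, y = 3.5, width = 0.06, depth = 0.06,
      height = 0.25, z_base = 0.75, shape = "cylinder", solid = FALSE
    ),
    world_object(3, "opened_door",
      x = 4.05, y = 1.4, theta = 0,
      width = door_width, depth = 0.1, height = 2.0, shape = "door",
      solid = FALSE
    ),
    world_object(4, "person",
      x = 4.85, y = -1.5, width = 0.5, depth = 0.5,
      height = 1.7, shape = "cylinder", dynamic = TRUE
    )
  )
  tasks <- tibble(
    step = 1:9,
    mode = c(
      "auto", "auto", "none", "command", "command",
      "auto", "command", "auto", "none"
    ),
    action = c(
      "goto", "pick", "drink", "move", "rotate",
      "pass_door", "rotate", "goto", "converse"
    ),
    target_class = c(
      "desk", "bottle", NA, NA, NA, "opened_door", NA, "person", NA
    ),
    command = c(
      NA, NA, NA, "backward", "rotate_right", NA, "rotate_right", NA, NA
    ),
    amount = c(NA, NA, NA, 1.0, pi / 2, NA, pi / 2, NA, NA),
    target_heading = c(NA, NA, NA, NA, 0, NA, -pi / 2, NA, NA)
  )
  structure(
    list(
      name = "A",
      world = world(c(-0.2, 5.8, -6.3, 4.2), obstacles, doorways, objects),
      start_pose = c(2.0, 1.8, pi / 2),
      tasks = tasks,
      walk_to = c(4.85, -5.0), # where the walking guest heads and stops
      walk_speed = 0.5,
      walk_trigger = 2.5
    ),
    class = "scenario"
  )
}

#' @rdname scenario_a
#' @export
scenario_b <- function(door_width = 0.8) {
  wt <- 0.1
  gap <- c(2.0 - door_width / 2, 2.0 + door_width / 2)
  obstacles <- list(
    rect_poly(-wt, 0, -wt, 4.5 + wt), # west wall
    rect_poly(-wt, 8 + wt, 4.5, 4.5 + wt), # north wall
    rect_poly(-wt, 8 + wt, -wt, 0), # south wall
    rect_poly(8, 8 + wt, -wt, 4.5 + wt), # east wall
    rect_poly(4, 4.1, -wt, gap[1]), # partition below door
    rect_poly(4, 4.1, gap[2], 4.5 + wt), # partition above door
    rect_poly(0.1, 0.8, 3.7, 4.4), # cabinet (room 1, NW corner)
    rect_poly(6.6, 7.0, 0.2, 0.6) # paper boxes (room 2)
  )
  doorways <- tibble(
    x = 4.05, y = 2.0, width = door_width, normal_theta = 0
  )
  objects <- bind_rows(
    world_object(1, "person",
      x = 3.0, y = 1.4, width = 0.5, depth = 0.5,
      height = 1.7, shape = "cylinder", dynamic = TRUE
    ),
    world_object(2, "chair",
      x = 3.1, y = 4.1, theta = -pi / 2,
      width = 0.6, depth = 0.42, height = 0.9, shape = "box"
    ),
    world_object(3, "chair",
      x = 0.3, y = 2.0, theta = 0,
      width = 0.6, depth = 0.42, height = 0.9, shape = "box"
    ),
    world_object(4, "opened_door",
      x = 4.05, y = 2.0, theta = 0,
      width = door_width, depth = 0.1, height = 2.0, shape = "door",
      solid = FALSE
    ),
    world_object(5, "desk",
      x = 5.6, y = 3.7, theta = -pi / 2,
      width = 1.2, depth = 0.6, height = 0.75, shape = "box"
    ),
    world_object(6, "bottle",
      x = 5.55, y = 3.5, width = 0.06, depth = 0.06,
      height = 0.25, z_base = 0.75, shape = "cylinder", solid = FALSE
    )
  )
  tasks <- tibble(
    step = 1:9,
    mode = c(
      "auto", "none", "auto", "command", "auto",
      "command", "auto", "auto", "none"
    ),
    action = c(
      "goto", "converse", "goto", "rotate", "pass_door",
      "rotate", "goto", "pick", "drink"
    ),
    target_class = c(
      "person", NA, "chair", NA, "opened_door", NA, "desk", "bottle", NA
    ),
    command = c(
      NA, NA, NA, "rotate_right", NA, "rotate_left", NA, NA, NA
    ),
    amount = c(NA, NA, NA, pi / 2, NA, pi / 2, NA, NA, NA),
    target_heading = c(NA, NA, NA, -0.57, NA, pi / 3, NA, NA, NA)
  )
  structure(
    list(
      name = "B",
      world = world(c(-0.2, 8.2, -0.2, 4.7), obstacles, doorways, objects),
      start_pose = c(1.4, 1.3, 0),
      tasks = tasks,
      walk_to = c(2.0, 2.6),
      walk_speed = 0.5,
      walk_trigger = 2.5
    ),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario %s> %d task step(s), %d object(s)\n",
    x$name, nrow(x$tasks), nrow(x$world$objects)
  ))
  invisible(x)
}

#' Write / read a scenario description
#'
#' Scenarios serialize to YAML: bounds, obstacle polygons, doorways, objects,
#' start pose and the task table.
#'
#' @param scenario A `scenario` (see [scenario_a()]).
#' @param path File path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   the scenario.
#' @export
write_scenario <- function(scenario, path) {
  payload <- list(
    name = scenario$name,
    bounds = scenario$world$bounds,
    obstacles = lapply(scenario$world$obstacles, function(p) {
      list(x = p[, 1], y = p[, 2])
    }),
    doorways = as.list(scenario$world$doorways),
    objects = lapply(seq_len(nrow(scenario$world$objects)), function(i) {
      as.list(scenario$world$objects[i, ])
    }),
    start_pose = scenario$start_pose,
    tasks = lapply(seq_len(nrow(scenario$tasks)), function(i) {
      row <- as.list(scenario$tasks[i, ])
      row[!vapply(row, function(v) is.na(v) %||% FALSE, logical(1))]
    }),
    walk_to = scenario$walk_to,
    walk_speed = scenario$walk_speed,
    walk_trigger = scenario$walk_trigger
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  p <- yaml::read_yaml(path)
  obstacles <- lapply(p$obstacles, function(o) cbind(o$x, o$y))
  doorways <- as_tibble(p$doorways)
  objects <- bind_rows(lapply(p$objects, function(o) {
    do.call(world_object, o[intersect(names(o), names(formals(world_object)))])
  }))
  tasks <- bind_rows(lapply(p$tasks, function(tk) {
    tibble(
      step = tk$step, mode = tk$mode, action = tk$action,
      target_class = tk$target_class %||% NA_character_,
      command = tk$command %||% NA_character_,
      amount = tk$amount %||% NA_real_,
      target_heading = tk$target_heading %||% NA_real_
    )
  }))
  structure(
    list(
      name = p$name,
      world = world(unlist(p$bounds), obstacles, doorways, objects),
      start_pose = unlist(p$start_pose),
      tasks = tasks,
      walk_to = unlist(p$walk_to),
      walk_speed = p$walk_speed,
      walk_trigger = p$walk_trigger
    ),
    class = "scenario"
  )
}
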