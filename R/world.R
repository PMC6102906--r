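#' Construct a planar world
#'
#' The simulator's world is 2D: rectangular bounds, static polygonal
#' obstacles (walls, furniture), doorways (for the pass-through solution and
#' feasibility checks) and sensed objects. Objects live in a tibble with one
#' row per object; dynamic agents (walking people) carry velocities.
#'
#' Object columns: `id`, `class` (one of [target_classes()]), pose `x`, `y`,
#' `theta`, extents `width` (lateral), `depth` (facing axis), `height`,
#' `z_base`, `shape` (`"box"`, `"cylinder"` or `"door"`), velocities `vx`,
#' `vy`, `dynamic`, and `solid` (whether the object also blocks motion).
#'
#' @param bounds `c(xmin, xmax, ymin, ymax)`, metres.
#' @param obstacles List of polygon matrices (n x 2), world frame.
#' @param doorways Tibble with `x`, `y`, `width`, `normal_theta` per doorway.
#' @param objects Object tibble as described above (may be empty).
#' @return An object of class `world`.
#' @export
world <- function(bounds, obstacles = list(), doorways = NULL,
                  objects = NULL) {
  if (length(bounds) != 4 || bounds[2] <= bounds[1] || bounds[4] <= bounds[3]) {
    abort("`bounds` must be c(xmin, xmax, ymin, ymax)")
  }
  if (is.null(doorways)) {
    doorways <- tibble(
      x = double(), y = double(), width = double(), normal_theta = double()
    )
  }
  if (is.null(objects)) objects <- empty_objects()
  if (!is.null(doorways) && nrow(doorways) > 0 && any(doorways$width <= 0)) {
    abort("doorway widths must be positive")
  }
  structure(
    list(
      bounds = bounds, obstacles = obstacles, doorways = doorways,
      objects = objects, cache = new.env(parent = emptyenv())
    ),
    class = "world"
  )
}

empty_objects <- function() {
  tibble(
    id = integer(), class = character(), x = double(), y = double(),
    theta = double(), width = double(), depth = double(),
    height = double(), z_base = double(), shape = character(),
    vx = double(), vy = double(), dynamic = logical(), solid = logical()
  )
}

# One object row with defaults filled in.
world_object <- function(id, class, x, y, theta = 0, width = 0.5,
                         depth = 0.5, height = 1, z_base = 0,
                         shape = "box", vx = 0, vy = 0, dynamic = FALSE,
                         solid = TRUE) {
  tibble(
    id = as.integer(id), class = class, x = x, y = y, theta = theta,
    width = width, depth = depth, height = height, z_base = z_base,
    shape = shape, vx = vx, vy = vy, dynamic = dynamic, solid = solid
  )
}

#' @export
print.world <- function(x, ...) {
  cat(sprintf(
    "<world> bounds [%g, %g] x [%g, %g], %d obstacle(s), %d object(s)\n",
    x$bounds[1], x$bounds[2], x$bounds[3], x$bounds[4],
    length(x$obstacles), nrow(x$objects)
  ))
  invisible(x)
}

# Footprint polygon of the wheelchair at a pose. The pose reference sits
# near the front of the chassis (front overhang 0.15 m, rear 1.05 m, width
# 0.70 m) so approach distances measured pose-to-target stay collision-free.
default_footprint <- function() {
  list(front = 0.15, rear = 1.05, halfwidth = 0.35)
}

footprint_polygon <- function(pose, footprint = default_footprint()) {
  local <- cbind(
    c(footprint$front, footprint$front, -footprint$rear, -footprint$rear),
    c(-footprint$halfwidth, footprint$halfwidth,
      footprint$halfwidth, -footprint$halfwidth)
  )
  body_to_world(local, pose)
}

# Polygon for a solid object (box footprint or circle approximation).
object_polygon <- function(obj) {
  if (obj$shape == "cylinder") {
    ang <- seq(0, 2 * pi, length.out = 13)[-13]
    r <- obj$width / 2
    cbind(obj$x + r * cos(ang), obj$y + r * sin(ang))
  } else {
    hw <- obj$width / 2
    hd <- obj$depth / 2
    local <- cbind(c(hd, hd, -hd, -hd), c(-hw, hw, hw, -hw))
    pts <- t(rot2(obj$theta) %*% t(local))
    cbind(pts[, 1] + obj$x, pts[, 2] + obj$y)
  }
}

# All blocking polygons: static obstacles plus solid objects.
blocking_polygons <- function(world, exclude_ids = NULL) {
  polys <- world$obstacles
  objs <- world$objects
  if (nrow(objs) > 0) {
    keep <- objs$solid & !(objs$id %in% (exclude_ids %||% integer()))
    for (i in which(keep)) {
      polys[[length(polys) + 1]] <- object_polygon(as.list(objs[i, ]))
    }
  }
  polys
}

# Does the footprint touch the polygons of specific objects (used to stop
# a docking motion at contact with the confirmed target)?
footprint_hits_objects <- function(world, pose, ids,
                                   footprint = default_footprint(),
                                   margin = 0.05) {
  fp <- footprint_polygon(pose, footprint)
  objs <- world$objects
  for (i in which(objs$id %in% ids & objs$solid)) {
    poly <- object_polygon(as.list(objs[i, ]))
    # inflate the object polygon by `margin` via distance test on corners
    if (polygons_intersect(fp, poly) ||
      any(dist_points_polygon(fp, poly) <= margin)) {
      return(TRUE)
    }
  }
  FALSE
}

# Does the wheelchair footprint collide with any blocking polygon?
# Returns FALSE, or the index of the first colliding polygon (truthy).
footprint_collides <- function(world, pose, footprint = default_footprint(),
                               exclude_ids = NULL) {
  fp <- footprint_polygon(pose, footprint)
  polys <- blocking_polygons(world, exclude_ids)
  for (i in seq_along(polys)) {
    if (polygons_intersect(fp, polys[[i]])) {
      return(i)
    }
  }
  FALSE
}

#' Plot a world map
#'
#' Obstacles, doorways, objects and (optionally) a planned path and
#' trajectory, drawn to scale.
#'
#' @param world A [world()].
#' @param path Optional [plan_path()] result.
#' @param trajectory Optional tibble with `x`, `y` columns.
#' @param pose Optional wheelchair pose to draw as its footprint.
#' @return A ggplot object.
#' @export
plot_world <- function(world, path = NULL, trajectory = NULL, pose = NULL) {
  poly_df <- purrr::imap(blocking_polygons(world), function(p, i) {
    tibble(x = p[, 1], y = p[, 2], poly = i)
  }) %>% bind_rows()
  g <- ggplot() +
    geom_polygon(
      data = poly_df, aes(.data$x, .data$y, group = .data$poly),
      fill = "grey40"
    ) +
    coord_equal() +
    labs(x = "x (m)", y = "y (m)")
  if (nrow(world$objects) > 0) {
    g <- g + geom_point(
      data = world$objects,
      aes(.data$x, .data$y, colour = .data$class), size = 2
    )
  }
  if (!is.null(path) && path$status == "ok") {
    g <- g + geom_path(
      data = path$waypoints, aes(.data$x, .data$y),
      colour = "steelblue"
    )
  }
  if (!is.null(trajectory)) {
    g <- g + geom_path(
      data = trajectory, aes(.data$x, .data$y), colour = "firebrick"
    )
  }
  if (!is.null(pose)) {
    fp <- footprint_polygon(pose)
    g <- g + geom_polygon(
      data = tibble(x = fp[, 1], y = fp[, 2]),
      aes(.data$x, .data$y), fill = NA, colour = "firebrick"
    )
  }
  g
}
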