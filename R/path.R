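# Occupancy grid over the world bounds. Cells are `res` metres; a cell is
# blocked when its centre lies within `inflate` of a blocking polygon. The
# static layer (walls + solid objects) is cached on the world; dynamic
# agents are rasterized per call.
occupancy_grid <- function(world, res = 0.05, inflate = 0.35,
                           exclude_ids = NULL) {
  b <- world$bounds
  nx <- ceiling((b[2] - b[1]) / res)
  ny <- ceiling((b[4] - b[3]) / res)
  cx <- b[1] + (seq_len(nx) - 0.5) * res
  cy <- b[3] + (seq_len(ny) - 0.5) * res
  pts <- cbind(rep(cx, times = ny), rep(cy, each = nx))

  key <- sprintf(
    "static_%g_%g_%s", res, inflate,
    paste(sort(exclude_ids %||% integer()), collapse = ",")
  )
  blocked <- world$cache[[key]]
  if (is.null(blocked)) {
    blocked <- rep(FALSE, nx * ny)
    objs <- world$objects
    static_ids <- if (nrow(objs)) objs$id[!objs$dynamic] else integer()
    polys <- world$obstacles
    if (nrow(objs)) {
      keep <- objs$solid & !objs$dynamic &
        !(objs$id %in% (exclude_ids %||% integer()))
      for (i in which(keep)) {
        polys[[length(polys) + 1]] <- object_polygon(as.list(objs[i, ]))
      }
    }
    for (poly in polys) {
      # prefilter to the polygon's inflated bounding box
      in_bb <- pts[, 1] >= min(poly[, 1]) - inflate &
        pts[, 1] <= max(poly[, 1]) + inflate &
        pts[, 2] >= min(poly[, 2]) - inflate &
        pts[, 2] <= max(poly[, 2]) + inflate
      if (!any(in_bb)) next
      d <- dist_points_polygon(pts[in_bb, , drop = FALSE], poly)
      hit <- which(in_bb)[d <= inflate]
      blocked[hit] <- TRUE
    }
    world$cache[[key]] <- blocked
  }
  # dynamic agents as inflated discs
  objs <- world$objects
  if (nrow(objs)) {
    dyn <- objs$solid & objs$dynamic &
      !(objs$id %in% (exclude_ids %||% integer()))
    for (i in which(dyn)) {
      r <- objs$width[i] / 2 + inflate
      d2 <- (pts[, 1] - objs$x[i])^2 + (pts[, 2] - objs$y[i])^2
      blocked <- blocked | d2 <= r^2
    }
  }
  list(
    nx = nx, ny = ny, res = res, origin = c(b[1], b[3]),
    cx = cx, cy = cy, blocked = matrix(blocked, nx, ny)
  )
}

grid_index <- function(grid, xy) {
  ix <- pmin(grid$nx, pmax(1, floor((xy[1] - grid$origin[1]) / grid$res) + 1))
  iy <- pmin(grid$ny, pmax(1, floor((xy[2] - grid$origin[2]) / grid$res) + 1))
  c(ix, iy)
}

# Nearest free cell to xy within max_snap metres; NULL if none.
nearest_free_cell <- function(grid, xy, max_snap = 0.3) {
  c0 <- grid_index(grid, xy)
  if (!grid$blocked[c0[1], c0[2]]) {
    return(c0)
  }
  r_cells <- ceiling(max_snap / grid$res)
  best <- NULL
  best_d <- Inf
  for (dx in -r_cells:r_cells) {
    for (dy in -r_cells:r_cells) {
      ix <- c0[1] + dx
      iy <- c0[2] + dy
      if (ix < 1 || ix > grid$nx || iy < 1 || iy > grid$ny) next
      if (grid$blocked[ix, iy]) next
      d <- sqrt((grid$cx[ix] - xy[1])^2 + (grid$cy[iy] - xy[2])^2)
      if (d < best_d && d <= max_snap) {
        best <- c(ix, iy)
        best_d <- d
      }
    }
  }
  best
}

#' Plan a grid path for the footprint-inflated holonomic wheelchair
#'
#' Shortest 8-connected path on a 5 cm occupancy grid. Obstacles are
#' inflated by the chassis half-width (0.35 m for the 0.70 m footprint;
#' the holonomic base passes doorways aligned, so lateral clearance is the
#' binding constraint - an 80 cm doorway is feasible, a 60 cm one is not).
#'
#' @param world A [world()].
#' @param start_pose,goal_pose Poses `c(x, y, theta)` (theta unused for
#'   planning; the holonomic base rotates freely).
#' @param inflate Inflation radius, metres.
#' @param res Grid resolution, metres.
#' @param exclude_ids Object ids to ignore (e.g. the docking target).
#' @param max_snap How far start/goal may snap to the nearest free cell.
#' @return An object of class `nav_path`: list with `status` (`"ok"` or
#'   `"no_path"`), `waypoints` (tibble `x`, `y`), and `length` (metres;
#'   `NA` on failure).
#' @examples
#' w <- world(c(-1, 4, -1, 1))
#' p <- plan_path(w, c(0, 0, 0), c(3, 0, 0))
#' p$length # ~3 m
#' @export
plan_path <- function(world, start_pose, goal_pose, inflate = 0.35,
                      res = 0.05, exclude_ids = NULL, max_snap = 0.3) {
  grid <- occupancy_grid(world, res, inflate, exclude_ids)
  s <- nearest_free_cell(grid, start_pose[1:2], max_snap)
  g <- nearest_free_cell(grid, goal_pose[1:2], max_snap)
  if (is.null(s) || is.null(g)) {
    return(structure(
      list(status = "no_path", waypoints = NULL, length = NA_real_),
      class = "nav_path"
    ))
  }
  free <- which(!grid$blocked) # linear indices, column-major (ix fastest)
  id_of <- integer(grid$nx * grid$ny)
  id_of[free] <- seq_along(free)
  lin <- function(cell) (cell[2] - 1L) * grid$nx + cell[1]

  edges <- list()
  weights <- list()
  nbrs <- rbind(
    c(1, 0, 1), c(0, 1, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2))
  )
  ix <- ((free - 1L) %% grid$nx) + 1L
  iy <- ((free - 1L) %/% grid$nx) + 1L
  for (k in seq_len(nrow(nbrs))) {
    jx <- ix + nbrs[k, 1]
    jy <- iy + nbrs[k, 2]
    ok <- jx >= 1 & jx <= grid$nx & jy >= 1 & jy <= grid$ny
    tgt <- (jy - 1L) * grid$nx + jx
    ok[ok] <- !grid$blocked[cbind(jx[ok], jy[ok])]
    edges[[k]] <- cbind(id_of[free[ok]], id_of[tgt[ok]])
    weights[[k]] <- rep(nbrs[k, 3] * grid$res, sum(ok))
  }
  el <- do.call(rbind, edges)
  gr <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(gr)$weight <- unlist(weights)
  sv <- id_of[lin(s)]
  gv <- id_of[lin(g)]
  if (sv == 0 || gv == 0 || sv > igraph::vcount(gr) ||
    gv > igraph::vcount(gr)) {
    return(structure(
      list(status = "no_path", waypoints = NULL, length = NA_real_),
      class = "nav_path"
    ))
  }
  sp <- suppressWarnings(igraph::shortest_paths(
    gr, from = sv, to = gv,
    weights = igraph::E(gr)$weight, output = "vpath"
  ))
  vp <- sp$vpath[[1]]
  if (length(vp) == 0) {
    return(structure(
      list(status = "no_path", waypoints = NULL, length = NA_real_),
      class = "nav_path"
    ))
  }
  cells <- free[as.integer(vp)]
  wx <- grid$cx[((cells - 1L) %% grid$nx) + 1L]
  wy <- grid$cy[((cells - 1L) %/% grid$nx) + 1L]
  # replace snapped endpoints with the exact start/goal coordinates
  wx[1] <- start_pose[1]
  wy[1] <- start_pose[2]
  wx[length(wx)] <- goal_pose[1]
  wy[length(wy)] <- goal_pose[2]
  len <- sum(sqrt(diff(wx)^2 + diff(wy)^2))
  structure(
    list(
      status = "ok", waypoints = tibble(x = wx, y = wy), length = len
    ),
    class = "nav_path"
  )
}

#' @export
print.nav_path <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf(
      "<nav_path> %d waypoints, %.2f m\n", nrow(x$waypoints), x$length
    ))
  } else {
    cat("<nav_path> no path found\n")
  }
  invisible(x)
}
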