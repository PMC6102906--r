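#' Depth-camera model
#'
#' Pinhole camera mounted on the wheelchair's back support: 640 x 480 pixels,
#' a 57 degree horizontal field of view, mount height 1.5 m and a free
#' depression-angle parameter. Used both to decide object visibility (sector
#' test in the horizontal plane) and to give simulated cloud points their
#' pixel provenance.
#'
#' @param image_width,image_height Image size in pixels.
#' @param hfov_deg Horizontal field of view, degrees.
#' @param mount_height Camera height above the floor, metres.
#' @param mount_x Body-frame x of the camera (the back support sits behind
#'   the pose reference, hence negative), metres.
#' @param depression_deg Downward tilt of the optical axis, degrees.
#' @param max_range Maximum sensing range, metres.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(image_width = 640, image_height = 480,
                         hfov_deg = 57, mount_height = 1.5,
                         mount_x = -0.75, depression_deg = 10,
                         max_range = 4.5) {
  if (hfov_deg <= 0 || hfov_deg >= 180) abort("`hfov_deg` must be in (0, 180)")
  structure(
    list(
      image_width = image_width, image_height = image_height,
      hfov_deg = hfov_deg, mount_height = mount_height,
      mount_x = mount_x, depression_deg = depression_deg,
      max_range = max_range,
      focal_px = (image_width / 2) / tan(hfov_deg / 2 * pi / 180)
    ),
    class = "camera_model"
  )
}

# Project body-frame points (x forward, y left, z up, metres) to pixels.
# Returns a tibble(u, v, depth); points behind the camera get NA pixels.
project_to_pixels <- function(pts, camera) {
  d <- camera$depression_deg * pi / 180
  q <- cbind(pts[, 1] - camera$mount_x, pts[, 2],
    pts[, 3] - camera$mount_height)
  xc <- q[, 1] * cos(d) - q[, 3] * sin(d)
  yc <- q[, 2]
  zc <- q[, 1] * sin(d) + q[, 3] * cos(d)
  ok <- xc > 1e-6
  u <- ifelse(ok, camera$image_width / 2 - camera$focal_px * yc / xc, NA)
  v <- ifelse(ok, camera$image_height / 2 - camera$focal_px * zc / xc, NA)
  tibble(u = u, v = v, depth = xc)
}

# World-frame -> body-frame for 2D points given pose c(x, y, theta).
world_to_body <- function(xy, pose) {
  rel <- cbind(xy[, 1] - pose[1], xy[, 2] - pose[2])
  rel %*% rot2(pose[3]) # equivalent to R(-theta) %*% rel per row
}

body_to_world <- function(xy, pose) {
  out <- xy %*% t(rot2(pose[3]))
  cbind(out[, 1] + pose[1], out[, 2] + pose[2])
}

# Sample camera-facing surface points of one object (world frame, metres).
# Objects are upright boxes, cylinders or door frames (two jamb posts).
sample_object_surface <- function(obj, viewer_xy, n_points,
                                  viewer_z = 1.5) {
  shape <- obj$shape %||% "box"
  z <- stats::runif(n_points, obj$z_base, obj$z_base + obj$height)
  if (shape == "cylinder") {
    r <- obj$width / 2
    to_viewer <- atan2(viewer_xy[2] - obj$y, viewer_xy[1] - obj$x)
    ang <- to_viewer + stats::runif(n_points, -pi / 2, pi / 2)
    cbind(obj$x + r * cos(ang), obj$y + r * sin(ang), z)
  } else if (shape == "door") {
    # two jamb posts flanking the doorway, along the door's lateral axis;
    # sides are sampled in exact balance (a depth image covers both jambs
    # at comparable pixel density, so neither side dominates the centroid)
    lat <- c(-sin(obj$theta), cos(obj$theta))
    side <- rep(c(-1, 1), length.out = n_points)
    off <- side * (obj$width / 2 + 0.05) +
      stats::runif(n_points, -0.04, 0.04)
    cbind(obj$x + lat[1] * off, obj$y + lat[2] * off, z)
  } else {
    # box: sample side faces and the top surface in proportion to their
    # area, keep camera-facing points, and thin by the cosine of the
    # viewing incidence (grazing faces return few depth samples; the top
    # is visible when the camera sits above it)
    hw <- obj$width / 2
    hd <- obj$depth / 2
    z_top <- obj$z_base + obj$height
    areas <- c(
      obj$width * obj$height, obj$width * obj$height,
      obj$depth * obj$height, obj$depth * obj$height,
      obj$width * obj$depth
    )
    face <- sample(1:5, n_points, replace = TRUE, prob = areas)
    a <- stats::runif(n_points, -1, 1)
    b <- stats::runif(n_points, -1, 1)
    loc <- cbind(
      ifelse(face == 1, hd, ifelse(face == 2, -hd, a * hd)),
      ifelse(face == 3, hw, ifelse(face == 4, -hw,
        ifelse(face == 5, b * hw, a * hw)
      ))
    )
    nrm <- cbind(
      ifelse(face == 1, 1, ifelse(face == 2, -1, 0)),
      ifelse(face == 3, 1, ifelse(face == 4, -1, 0))
    )
    z[face == 5] <- z_top
    R <- rot2(obj$theta)
    w_loc <- t(R %*% t(loc))
    w_nrm <- t(R %*% t(nrm))
    pts <- cbind(obj$x + w_loc[, 1], obj$y + w_loc[, 2])
    view <- cbind(viewer_xy[1] - pts[, 1], viewer_xy[2] - pts[, 2])
    vn <- sqrt(view[, 1]^2 + view[, 2]^2)
    cosi <- rowSums(w_nrm * view) / pmax(vn, 1e-9)
    # top-face incidence uses the camera height above the surface
    top <- face == 5
    if (any(top)) {
      dz <- viewer_z - z_top
      cosi[top] <- dz / sqrt(vn[top]^2 + dz^2)
      if (dz <= 0) cosi[top] <- -1
    }
    keep <- cosi > 0 & stats::runif(n_points) < cosi
    if (sum(keep) < 3) keep <- cosi > 0
    if (sum(keep) < 3) keep <- rep(TRUE, n_points)
    cbind(pts[keep, 1], pts[keep, 2], z[keep])
  }
}

#' Simulate object detections and a depth point cloud
#'
#' Stand-in for the detector + depth-camera pair: every world object inside
#' the camera's sector (horizontal field of view and range) yields a
#' detection with probability `1 - miss_rate`, plus surface cloud points with
#' Gaussian position noise (default sigma 1 cm, the depth accuracy within a
#' 2 m working area). Cloud points carry their pixel provenance so the
#' bounding-box shrink of [localize_target()] can re-select them.
#'
#' @param world A [world()] (its `$objects` tibble is sensed).
#' @param pose Wheelchair pose `c(x, y, theta)` in the world frame.
#' @param camera A [camera_model()].
#' @param miss_rate Per-object probability of a missed detection.
#' @param noise_sd Cloud position noise, metres.
#' @param points_per_object Surface samples drawn per object.
#' @param bbox_pad Loose-box factor: detector boxes are the tight point
#'   bounding box scaled by this (with a little jitter), emulating the
#'   loose boxes real detectors draw - the reason the localizer shrinks
#'   boxes to 60% before extracting points.
#' @param seed Optional integer seed.
#' @return List with `detections` (tibble: `object_id`, `class`, pixel bbox
#'   `x`, `y`, `w`, `h`, `confidence`) and `cloud` (tibble: `object_id`,
#'   body-frame `x`, `y`, `z`, pixels `u`, `v`).
#' @export
simulate_sensing <- function(world, pose, camera = camera_model(),
                             miss_rate = 0, noise_sd = 0.01,
                             points_per_object = 200, bbox_pad = 1.8,
                             seed = NULL) {
  objs <- world$objects
  with_seed(seed, {
    det_rows <- list()
    cloud_rows <- list()
    for (i in seq_len(nrow(objs))) {
      obj <- as.list(objs[i, ])
      body <- world_to_body(cbind(obj$x, obj$y), pose)
      cam_rel <- c(body[1] - camera$mount_x, body[2])
      rng <- vnorm(cam_rel)
      bearing <- atan2(cam_rel[2], cam_rel[1])
      if (rng > camera$max_range || cam_rel[1] < 0.05 ||
        abs(bearing) > camera$hfov_deg / 2 * pi / 180) {
        next
      }
      if (stats::runif(1) < miss_rate) next
      pts_w <- sample_object_surface(obj, pose[1:2], points_per_object,
        viewer_z = camera$mount_height)
      pts_b <- cbind(world_to_body(pts_w[, 1:2, drop = FALSE], pose),
        pts_w[, 3]
      )
      if (noise_sd > 0) {
        pts_b <- pts_b + matrix(
          stats::rnorm(length(pts_b), sd = noise_sd),
          nrow(pts_b)
        )
      }
      px <- project_to_pixels(pts_b, camera)
      vis <- !is.na(px$u) & px$u >= 0 & px$u <= camera$image_width &
        px$v >= 0 & px$v <= camera$image_height
      if (sum(vis) < 3) next
      tight <- c(
        min(px$u[vis]), min(px$v[vis]),
        max(px$u[vis]) - min(px$u[vis]),
        max(px$v[vis]) - min(px$v[vis])
      )
      pad <- bbox_pad * stats::runif(1, 0.95, 1.05)
      bb <- c(
        tight[1] + tight[3] / 2 - tight[3] * pad / 2,
        tight[2] + tight[4] / 2 - tight[4] * pad / 2,
        tight[3] * pad, tight[4] * pad
      )
      det_rows[[length(det_rows) + 1]] <- tibble(
        object_id = obj$id, class = obj$class,
        x = bb[1], y = bb[2], w = max(bb[3], 1), h = max(bb[4], 1),
        confidence = stats::runif(1, 0.7, 1)
      )
      cloud_rows[[length(cloud_rows) + 1]] <- tibble(
        object_id = obj$id,
        x = pts_b[vis, 1], y = pts_b[vis, 2], z = pts_b[vis, 3],
        u = px$u[vis], v = px$v[vis]
      )
    }
    list(
      detections = if (length(det_rows)) bind_rows(det_rows) else
        tibble(
          object_id = integer(), class = character(), x = double(),
          y = double(), w = double(), h = double(), confidence = double()
        ),
      cloud = if (length(cloud_rows)) bind_rows(cloud_rows) else
        tibble(
          object_id = integer(), x = double(), y = double(), z = double(),
          u = double(), v = double()
        )
    )
  })
}

#' Localize a detected target from its point cloud
#'
#' Shrinks the detection bounding box to 60% of its width and height about
#' its centre, keeps the cloud points whose pixel provenance falls inside the
#' shrunk box, drops points below 10 cm from the floor, and returns the
#' arithmetic mean of the survivors as the target position.
#'
#' @param detection One detection row (pixel bbox `x`, `y`, `w`, `h`).
#' @param cloud Cloud tibble with body-frame `x`, `y`, `z` and pixels
#'   `u`, `v` (as produced by [simulate_sensing()]).
#' @param shrink Linear shrink factor per side.
#' @param floor_cutoff Height below which points are discarded, metres.
#' @return Numeric `c(x, y, z)` position in the cloud's frame. If no point
#'   survives, a classed error `neurochair_localization_failure` is signalled
#'   (downstream this counts as an environment-perception deduction).
#' @export
localize_target <- function(detection, cloud, shrink = 0.6,
                            floor_cutoff = 0.10) {
  box <- shrink_bbox(
    c(detection$x, detection$y, detection$w, detection$h), shrink
  )
  keep <- cloud$u >= box[1] & cloud$u <= box[1] + box[3] &
    cloud$v >= box[2] & cloud$v <= box[2] + box[4] &
    cloud$z >= floor_cutoff
  if (!any(keep)) {
    abort(
      "no cloud points survive the bounding-box shrink and floor filter",
      class = "neurochair_localization_failure"
    )
  }
  c(mean(cloud$x[keep]), mean(cloud$y[keep]), mean(cloud$z[keep]))
}

#' Shrink a pixel bounding box about its centre
#'
#' @param bbox `c(x, y, w, h)`, top-left origin.
#' @param shrink Linear factor applied to width and height.
#' @return The shrunk `c(x, y, w, h)`.
#' @export
shrink_bbox <- function(bbox, shrink = 0.6) {
  cx <- bbox[1] + bbox[3] / 2
  cy <- bbox[2] + bbox[4] / 2
  w <- bbox[3] * shrink
  h <- bbox[4] * shrink
  c(cx - w / 2, cy - h / 2, w, h)
}

#' Estimate a target's horizontal orientation from its point cloud
#'
#' Projects the cloud to the horizontal plane and takes the first principal
#' axis `v` (PCA); its in-plane orthogonal is `vn`. Whichever of `v`/`vn`
#' makes the smaller line angle with `f` (the unit vector from the wheelchair
#' to the target centre) is the orientation axis; the sign is chosen so the
#' orientation points back toward the wheelchair (face-to-face convention,
#' `dot(orientation, f) <= 0`). Near-isotropic clouds (singular-value ratio
#' below `degeneracy_ratio`) return `-f` with attribute `degenerate = TRUE`.
#'
#' @param points Matrix or tibble with columns `x`, `y` (any frame).
#' @param wheelchair_position `c(x, y)` in the same frame.
#' @param centre Optional target centre; defaults to the cloud mean.
#' @param degeneracy_ratio Minimum sd ratio for a well-defined axis.
#' @return Unit 2-vector with attributes `f` (unit wheelchair-to-target
#'   vector) and `degenerate`.
#' @export
estimate_orientation <- function(points, wheelchair_position, centre = NULL,
                                 degeneracy_ratio = 1.2) {
  xy <- if (is.matrix(points)) points[, 1:2, drop = FALSE] else
    cbind(points$x, points$y)
  if (nrow(xy) < 3) abort("need >= 3 points to estimate orientation")
  if (is.null(centre)) centre <- colMeans(xy)
  f <- unitize(centre[1:2] - wheelchair_position[1:2])
  pc <- stats::prcomp(xy, center = TRUE)
  ratio <- pc$sdev[1] / max(pc$sdev[2], 1e-12)
  if (!is.finite(ratio) || ratio < degeneracy_ratio) {
    out <- -f
    attr(out, "f") <- f
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  v <- unitize(pc$rotation[, 1])
  vn <- c(-v[2], v[1])
  axis <- if (line_angle(v, f) <= line_angle(vn, f)) v else vn
  if (sum(axis * f) > 0) axis <- -axis
  out <- axis
  attr(out, "f") <- f
  attr(out, "degenerate") <- FALSE
  attr(out, "major") <- v # first principal axis (elongation direction)
  out
}

#' Target estimate container
#'
#' @param target_id Object identifier.
#' @param class One of the ten recognized classes.
#' @param position `c(x, y, z)` target centre, metres.
#' @param orientation Unit 2-vector in the horizontal plane.
#' @param f_vector Unit 2-vector from wheelchair to target.
#' @param last_update Time of the last refresh, seconds.
#' @param degenerate Whether the orientation fell back to `-f`.
#' @param major_axis Unit 2-vector of the cloud's first principal axis
#'   (the elongation direction; defaults to the orientation's orthogonal).
#' @return An object of class `target_estimate`.
#' @export
target_estimate <- function(target_id, class, position, orientation,
                            f_vector, last_update = 0, degenerate = FALSE,
                            major_axis = NULL) {
  orientation <- unitize(orientation)
  if (is.null(major_axis)) {
    major_axis <- c(-orientation[2], orientation[1])
  }
  structure(
    list(
      target_id = target_id, class = class, position = position,
      orientation = orientation, f_vector = unitize(f_vector),
      last_update = last_update, degenerate = degenerate,
      major_axis = unitize(major_axis)
    ),
    class = "target_estimate"
  )
}

#' Build a target estimate from one sensing frame
#'
#' Convenience wrapper: localization + orientation for a given detection.
#' Positions are returned in the world frame.
#'
#' @param detection One detection row from [simulate_sensing()].
#' @param cloud The matching cloud (body frame).
#' @param pose Wheelchair pose `c(x, y, theta)`.
#' @param time_s Timestamp recorded on the estimate.
#' @inheritParams localize_target
#' @return A [target_estimate()].
#' @export
estimate_target <- function(detection, cloud, pose, time_s = 0,
                            shrink = 0.6, floor_cutoff = 0.10) {
  sub <- cloud[cloud$object_id == detection$object_id, , drop = FALSE]
  pos_b <- localize_target(detection, sub, shrink, floor_cutoff)
  pos_w <- body_to_world(matrix(pos_b[1:2], 1), pose)
  xy_w <- body_to_world(cbind(sub$x, sub$y), pose)
  ori <- estimate_orientation(
    xy_w, pose[1:2],
    centre = c(pos_w[1], pos_w[2])
  )
  target_estimate(
    target_id = detection$object_id, class = detection$class,
    position = c(pos_w[1], pos_w[2], pos_b[3]),
    orientation = as.numeric(ori), f_vector = attr(ori, "f"),
    last_update = time_s, degenerate = attr(ori, "degenerate"),
    major_axis = attr(ori, "major")
  )
}

#' Refresh a tracked target from a new sensing frame
#'
#' Emulates the image-tracker update contract: the confirmed target's
#' position and orientation are refreshed from the newest bounding box and
#' cloud. If the true object has left the camera's field of view a classed
#' error `neurochair_tracking_failure` is signalled (an environment-
#' perception deduction; the running task is aborted to the state-machine
#' reset).
#'
#' @param estimate The current [target_estimate()].
#' @param world The [world()] (ground truth for visibility).
#' @param pose Wheelchair pose `c(x, y, theta)`.
#' @param camera A [camera_model()].
#' @param time_s Current time, seconds.
#' @param seed Optional integer seed for the sensing draw.
#' @inheritParams simulate_sensing
#' @return The refreshed `target_estimate`.
#' @export
track_update <- function(estimate, world, pose, camera = camera_model(),
                         time_s = 0, noise_sd = 0.01,
                         points_per_object = 200, seed = NULL) {
  sensed <- simulate_sensing(world, pose, camera,
    miss_rate = 0, noise_sd = noise_sd,
    points_per_object = points_per_object, seed = seed
  )
  det <- sensed$detections[
    sensed$detections$object_id == estimate$target_id, ,
    drop = FALSE
  ]
  if (nrow(det) == 0) {
    abort(
      sprintf("target %s left the camera field of view", estimate$target_id),
      class = "neurochair_tracking_failure"
    )
  }
  estimate_target(det[1, ], sensed$cloud, pose, time_s = time_s)
}
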