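# 2D geometry primitives for the planar world: all polygons are simple,
# vertices counter-clockwise or clockwise (tests are orientation-free).

# Vectorized point-in-polygon (ray casting). pts: n x 2, poly: m x 2.
points_in_polygon <- function(pts, poly) {
  n <- nrow(pts)
  m <- nrow(poly)
  inside <- rep(FALSE, n)
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]
    yi <- poly[i, 2]
    xj <- poly[j, 1]
    yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Vectorized distance from points to a segment a-b.
dist_points_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-300) {
    return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  }
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
}

# Distance from points to a polygon boundary; 0 for interior points.
dist_points_polygon <- function(pts, poly) {
  m <- nrow(poly)
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    d <- pmin(d, dist_points_segment(pts, poly[i, ], poly[j, ]))
  }
  d[points_in_polygon(pts, poly)] <- 0
  d
}

# Do segments p1-p2 and q1-q2 intersect (including touching)?
segments_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(q1, q2, p1)
  d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1)
  d4 <- d(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  (d1 == 0 && on_seg(q1, q2, p1)) || (d2 == 0 && on_seg(q1, q2, p2)) ||
    (d3 == 0 && on_seg(p1, p2, q1)) || (d4 == 0 && on_seg(p1, p2, q2))
}

# Do two convex-or-simple polygons intersect (edge crossing or containment)?
polygons_intersect <- function(pa, pb) {
  na <- nrow(pa)
  nb <- nrow(pb)
  for (i in seq_len(na)) {
    i2 <- if (i == na) 1L else i + 1L
    for (j in seq_len(nb)) {
      j2 <- if (j == nb) 1L else j + 1L
      if (segments_intersect(pa[i, ], pa[i2, ], pb[j, ], pb[j2, ])) {
        return(TRUE)
      }
    }
  }
  any(points_in_polygon(pa, pb)) || any(points_in_polygon(pb, pa))
}

# Axis-aligned rectangle polygon from ranges.
rect_poly <- function(x1, x2, y1, y2) {
  cbind(c(x1, x2, x2, x1), c(y1, y1, y2, y2))
}
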