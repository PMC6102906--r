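# Small numeric helpers shared across modules.

# Euclidean norm of a 2- or 3-vector.
vnorm <- function(v) sqrt(sum(v^2))

# Unit vector; errors on (near-)zero input.
unitize <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (n < tol) abort("cannot normalize a zero-length vector")
  v / n
}

# Angle between two 2D *lines* (sign/direction-invariant), in radians [0, pi/2].
line_angle <- function(a, b) {
  ca <- abs(sum(unitize(a) * unitize(b)))
  acos(pmin(1, ca))
}

# 2D rotation matrix, counter-clockwise.
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# Wrap angle to (-pi, pi].
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  ifelse(a == -pi, pi, a)
}

# Run expr with a locally-seeded RNG, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive", name))
  invisible(x)
}
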