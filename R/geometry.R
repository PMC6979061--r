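# 3D vector / rotation primitives. All angles cross the API in degrees and are
# converted to radians internally; rotations are right-handed (counter-clockwise
# when looking down the axis direction towards the origin of the axis).

DEG2RAD <- pi / 180

# unit / orthogonality checks use this tolerance; directions within UNIT_SLACK
# of unit length are silently renormalised rather than rejected
UNIT_TOL <- 1e-9
UNIT_SLACK <- 1e-6

#' Elementary 3D vector operations
#'
#' Dot product, Euclidean norm, cross product and normalisation of length-3
#' numeric vectors.
#'
#' @param a,b Numeric length-3 vectors.
#' @return `v_dot` a scalar; `v_norm` a non-negative scalar; `v_cross` and
#'   `v_unit` length-3 vectors.
#' @name vec3-ops
NULL

#' @rdname vec3-ops
#' @export
v_dot <- function(a, b) sum(a * b)

#' @rdname vec3-ops
#' @export
v_norm <- function(a) sqrt(sum(a * a))

#' @rdname vec3-ops
#' @export
v_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @rdname vec3-ops
#' @export
v_unit <- function(a) {
  n <- v_norm(a)
  if (n < UNIT_TOL) stop("cannot normalise a (near-)zero vector", call. = FALSE)
  a / n
}

as_vec3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    stop(sprintf("%s must be a finite numeric vector of length 3", what),
         call. = FALSE)
  }
  p
}

# normalise a direction that should already be unit; reject if clearly non-unit
check_unit <- function(d, what = "direction") {
  d <- as_vec3(d, what)
  n <- v_norm(d)
  if (abs(n - 1) > UNIT_SLACK) {
    stop(sprintf("%s must be a unit vector (|%s| = %.9g)", what, what, n),
         call. = FALSE)
  }
  d / n
}

#' Construct an oriented line (axis) in 3D
#'
#' An axis is the rotation primitive used throughout: a point the line passes
#' through plus a unit direction. Directions within 1e-6 of unit length are
#' renormalised; anything else is rejected.
#'
#' @param point Numeric length-3, a point on the line (mm).
#' @param direction Numeric length-3 unit vector.
#' @return An object of class `axis3` with elements `point` and `direction`.
#' @export
axis3 <- function(point, direction) {
  structure(list(point = as_vec3(point),
                 direction = check_unit(direction)),
            class = "axis3")
}

#' Construct a plane from a point and a unit normal
#'
#' @param point Numeric length-3, a point on the plane (mm).
#' @param normal Numeric length-3 unit normal.
#' @return An object of class `plane3` with elements `point` and `normal`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = as_vec3(point),
                 normal = check_unit(normal, "normal")),
            class = "plane3")
}

#' Construct an orthonormal right-handed coordinate frame
#'
#' Validates pairwise orthogonality, unit length and right-handedness
#' (`x = y x z`) to 1e-9. Use [build_right_handed_frame()] to construct a frame
#' from a primary axis and a hint direction.
#'
#' @param origin Numeric length-3 origin (mm).
#' @param x,y,z Unit axis directions.
#' @return An object of class `frame3`.
#' @export
frame3 <- function(origin, x, y, z) {
  x <- check_unit(x, "x"); y <- check_unit(y, "y"); z <- check_unit(z, "z")
  if (abs(v_dot(x, y)) > UNIT_TOL || abs(v_dot(y, z)) > UNIT_TOL ||
      abs(v_dot(z, x)) > UNIT_TOL) {
    stop("frame axes must be pairwise orthogonal", call. = FALSE)
  }
  if (max(abs(x - v_cross(y, z))) > UNIT_TOL) {
    stop("frame must be right-handed with x = y x z", call. = FALSE)
  }
  structure(list(origin = as_vec3(origin), x = x, y = y, z = z),
            class = "frame3")
}

#' @export
print.frame3 <- function(x, ...) {
  cat("<frame3>\n")
  cat("  origin:", sprintf("% .3f", x$origin), "\n")
  cat("  x     :", sprintf("% .6f", x$x), "\n")
  cat("  y     :", sprintf("% .6f", x$y), "\n")
  cat("  z     :", sprintf("% .6f", x$z), "\n")
  invisible(x)
}

# Rodrigues rotation of a free vector about a unit direction (no translation)
rotate_direction <- function(v, direction, angle_deg) {
  k <- check_unit(direction)
  th <- angle_deg * DEG2RAD
  v * cos(th) + v_cross(k, v) * sin(th) + k * v_dot(k, v) * (1 - cos(th))
}

#' Rotate a point about an arbitrary axis
#'
#' Right-handed (counter-clockwise looking down the axis direction) rotation of
#' a point about the line defined by `axis`. The distance of the point to the
#' line is preserved exactly up to floating point.
#'
#' @param p Numeric length-3 point (mm).
#' @param axis An [axis3()] object.
#' @param angle_deg Signed rotation angle in degrees.
#' @return The rotated point, numeric length-3.
#' @examples
#' a <- axis3(c(0, 0, 0), c(0, 0, 1))
#' rotate_about_axis(c(1, 0, 0), a, 90) # ~ (0, 1, 0)
#' @export
rotate_about_axis <- function(p, axis, angle_deg) {
  stopifnot(inherits(axis, "axis3"))
  p <- as_vec3(p)
  axis$point + rotate_direction(p - axis$point, axis$direction, angle_deg)
}

#' Project a vector onto a plane
#'
#' Removes the component of `v` along the unit `normal`. Fails if `v` is
#' (numerically) parallel to the normal, i.e. the projection degenerates to a
#' zero vector.
#'
#' @param v Numeric length-3 vector.
#' @param normal Unit plane normal.
#' @return The in-plane component of `v`, orthogonal to `normal`.
#' @export
project_vector_onto_plane <- function(v, normal) {
  v <- as_vec3(v, "v")
  n <- check_unit(normal, "normal")
  w <- v - v_dot(v, n) * n
  if (v_norm(w) < UNIT_TOL) {
    stop("degenerate projection: vector is parallel to the plane normal",
         call. = FALSE)
  }
  w
}

#' Signed angle between two vectors measured in a plane
#'
#' Both vectors are projected onto the plane with unit normal `normal`; the
#' returned angle rotates the projection of `u` onto the projection of `v`,
#' positive right-handedly about `normal`. Range `(-180, 180]` degrees.
#'
#' @param u,v Numeric length-3 vectors with non-degenerate in-plane components.
#' @param normal Unit plane normal.
#' @return Signed angle in degrees.
#' @export
signed_angle_in_plane <- function(u, v, normal) {
  n <- check_unit(normal, "normal")
  pu <- project_vector_onto_plane(u, n)
  pv <- project_vector_onto_plane(v, n)
  ang <- atan2(v_dot(v_cross(pu, pv), n), v_dot(pu, pv)) / DEG2RAD
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Build a right-handed frame from a primary (y) direction and a z hint
#'
#' `y` is the normalised primary direction; `z` is the hint projected onto the
#' plane perpendicular to `y` and normalised; `x = y x z` completes the
#' right-handed triad. This mirrors how anatomical coordinate systems are
#' assembled from a segment axis plus a secondary reference direction.
#'
#' @param origin Frame origin (mm).
#' @param y_dir Primary direction (any non-zero length).
#' @param z_hint Secondary direction, must not be parallel to `y_dir`.
#' @return A [frame3()] object.
#' @export
build_right_handed_frame <- function(origin, y_dir, z_hint) {
  y <- v_unit(as_vec3(y_dir, "y_dir"))
  z_raw <- as_vec3(z_hint, "z_hint") - v_dot(as_vec3(z_hint, "z_hint"), y) * y
  if (v_norm(z_raw) < UNIT_SLACK) {
    stop("degenerate frame: z_hint is parallel to y_dir", call. = FALSE)
  }
  z <- z_raw / v_norm(z_raw)
  frame3(origin, v_cross(y, z), y, z)
}

#' Signed distance of a point from a plane
#'
#' Positive on the side the normal points towards.
#'
#' @param p Numeric length-3 point.
#' @param plane A [plane3()] object.
#' @return Signed distance in mm.
#' @export
point_plane_distance <- function(p, plane) {
  stopifnot(inherits(plane, "plane3"))
  v_dot(as_vec3(p) - plane$point, plane$normal)
}

# distance of a point to the line of an axis3
point_line_distance <- function(p, axis) {
  w <- as_vec3(p) - axis$point
  v_norm(w - v_dot(w, axis$direction) * axis$direction)
}
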