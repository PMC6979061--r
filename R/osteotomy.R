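# Osteotomy coordinate system, cutting planes and fragment rotation.
#
# The reference frame at the cut level follows ISB-style conventions: y along
# the femoral mechanical axis pointing proximal; z the projection onto the cut
# plane of the femoral neck axis (subtrochanteric site) or of the posterior
# condylar tangent (supracondylar site), pointing medial; x = y x z pointing
# anterior. Plane mal-angulation tilts the baseline normal about the frame's
# x axis (frontal tilt) or z axis (sagittal tilt).

#' Build the osteotomy reference frame at a cut level
#'
#' Origin is the shaft-slice centre at the requested level
#' ([shaft_point_at_level()]); y is the unit femoral mechanical axis pointing
#' proximal; z is the in-plane projection of the site's rotational reference
#' (femoral neck axis for subtrochanteric, posterior condylar tangent for
#' supracondylar), sign-fixed to point medially; x completes the right-handed
#' triad and points anteriorly.
#'
#' @param lm A `leg_landmarks` object (pre-operative).
#' @param site `"subtrochanteric"` or `"supracondylar"`.
#' @param level_offset_mm Cut level as arc-length offset from the site
#'   reference level, mm (e.g. 45 below the lesser trochanter, 60 above the
#'   condyles).
#' @return A [frame3()] object.
#' @export
build_osteotomy_frame <- function(lm,
                                  site = c("subtrochanteric", "supracondylar"),
                                  level_offset_mm) {
  site <- match.arg(site)
  origin <- shaft_point_at_level(lm, site, level_offset_mm)
  y <- femoral_mech_dir(lm)
  z_hint <- if (site == "subtrochanteric") lm$neck_axis else condylar_tangent_medial(lm)
  fr <- build_right_handed_frame(origin, y, z_hint)
  if (v_dot(fr$z, lm$medial0) < 0) {
    fr <- frame3(fr$origin, v_cross(fr$y, -fr$z), fr$y, -fr$z)
  }
  fr
}

#' Baseline osteotomy plane perpendicular to the mechanical femoral axis
#'
#' @param frame An osteotomy [frame3()].
#' @return A [plane3()] through the frame origin with normal along the frame's
#'   y axis (the mechanical femoral axis direction).
#' @export
make_baseline_plane <- function(frame) {
  stopifnot(inherits(frame, "frame3"))
  plane3(frame$origin, frame$y)
}

#' Specify a mal-angulation of the osteotomy plane
#'
#' Frontal mal-angulation tilts the baseline plane normal about the frame's
#' x axis; sagittal mal-angulation tilts it about the z axis. `direction`
#' selects the tilt sense: `"plus"` is the right-handed (counter-clockwise
#' looking down the frame axis) rotation, `"minus"` its opposite. Study grids
#' pool both directions, so summary cells do not depend on this mapping.
#'
#' @param plane `"frontal"` or `"sagittal"`.
#' @param magnitude_deg Tilt magnitude in degrees (study grid: 5, 10, 15, 20,
#'   30; 0 reproduces the baseline plane).
#' @param direction `"plus"` or `"minus"`.
#' @return An object of class `plane_angulation`.
#' @export
plane_angulation <- function(plane = c("frontal", "sagittal"),
                             magnitude_deg,
                             direction = c("plus", "minus")) {
  plane <- match.arg(plane)
  direction <- match.arg(direction)
  if (!is.numeric(magnitude_deg) || length(magnitude_deg) != 1L ||
      magnitude_deg < 0 || magnitude_deg >= 90) {
    stop("magnitude_deg must be a scalar in [0, 90)", call. = FALSE)
  }
  structure(list(plane = plane, magnitude_deg = magnitude_deg,
                 direction = direction),
            class = "plane_angulation")
}

#' Tilt the baseline osteotomy plane
#'
#' Rotates the baseline normal (the frame's y axis) about the frame's x axis
#' (frontal mal-angulation) or z axis (sagittal mal-angulation) by the signed
#' magnitude; the plane keeps passing through the frame origin. Magnitude 0
#' returns the baseline plane.
#'
#' @param frame An osteotomy [frame3()].
#' @param ang A [plane_angulation()].
#' @return A [plane3()].
#' @export
tilt_plane <- function(frame, ang) {
  stopifnot(inherits(frame, "frame3"), inherits(ang, "plane_angulation"))
  if (ang$magnitude_deg == 0) return(make_baseline_plane(frame))
  about <- if (ang$plane == "frontal") frame$x else frame$z
  sgn <- if (ang$direction == "plus") 1 else -1
  plane3(frame$origin, rotate_direction(frame$y, about, sgn * ang$magnitude_deg))
}

#' Specify the fragment rotation
#'
#' @param theta_deg Rotation magnitude in degrees, non-negative (study grid:
#'   5, 10, 15, 20, 30).
#' @param sense `"external"` or `"internal"` rotation of the distal fragment.
#' @return An object of class `rotation_spec`.
#' @export
rotation_spec <- function(theta_deg, sense = c("external", "internal")) {
  sense <- match.arg(sense)
  if (!is.numeric(theta_deg) || length(theta_deg) != 1L || theta_deg < 0) {
    stop("theta_deg must be a non-negative scalar", call. = FALSE)
  }
  structure(list(theta_deg = theta_deg, sense = sense), class = "rotation_spec")
}

# signed rotation angle about the proximally-oriented plane normal: for a
# right leg (x anterior, z medial, y proximal) a positive right-handed
# rotation about +y carries the anterior direction laterally, i.e. external
rotation_signed_angle <- function(rot) {
  if (rot$sense == "external") rot$theta_deg else -rot$theta_deg
}

#' Apply a rotational osteotomy to the distal fragment
#'
#' Cuts the leg at `plane`, then rigidly rotates every distal landmark (knee,
#' condyles, ankle, distal shaft points) about the rotation axis by the
#' requested angle; proximal landmarks are untouched. By default the rotation
#' axis is the normal of the (possibly mal-angulated) cutting plane through the
#' frame origin — the fragment turns on the cut surface; setting
#' `rotation_axis = "baseline_y"` rotates about the original mechanical-axis
#' direction instead, for sensitivity checks. The axis direction is oriented
#' proximally; external rotation is the positive right-handed sense about it
#' for a right leg.
#'
#' @param lm A `leg_landmarks` object.
#' @param plane The cutting [plane3()].
#' @param frame The osteotomy [frame3()] that generated the plane.
#' @param rot A [rotation_spec()].
#' @param rotation_axis `"plane_normal"` (default) or `"baseline_y"`.
#' @return A new `leg_landmarks` object with the distal fragment rotated; the
#'   applied axis and signed angle are stored in the `"transform"` attribute.
#' @export
apply_rotational_osteotomy <- function(lm, plane, frame, rot,
                                       rotation_axis = c("plane_normal", "baseline_y")) {
  stopifnot(inherits(lm, "leg_landmarks"), inherits(plane, "plane3"),
            inherits(frame, "frame3"), inherits(rot, "rotation_spec"))
  rotation_axis <- match.arg(rotation_axis)
  frag <- split_fragments(lm, plane)

  dir <- if (rotation_axis == "plane_normal") plane$normal else frame$y
  if (v_dot(dir, femoral_mech_dir(lm)) < 0) dir <- -dir  # orient proximally
  ax <- axis3(frame$origin, dir)
  theta <- rotation_signed_angle(rot)

  out <- lm
  for (nm in frag$distal) out[[nm]] <- rotate_about_axis(lm[[nm]], ax, theta)
  if (length(frag$shaft_distal) > 0) {
    out$shaft_polyline[frag$shaft_distal, ] <-
      t(apply(lm$shaft_polyline[frag$shaft_distal, , drop = FALSE], 1,
              function(p) rotate_about_axis(p, ax, theta)))
  }
  attr(out, "transform") <- list(axis = ax, angle_deg = theta,
                                 fragment = frag, rotation_axis = rotation_axis)
  out
}
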