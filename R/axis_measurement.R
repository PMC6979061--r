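# AP-projected mechanical leg axis (hip-knee-ankle angle) measurement.
#
# The HKA valgus angle is the signed frontal-plane angle from the distal
# femoral mechanical axis (hip -> knee) to the tibial mechanical axis
# (knee -> ankle), measured right-handedly about the anterior (AP) projection
# direction; valgus positive for a right leg. Two projection modes differ only
# in how the AP direction is chosen:
#   knee_anchored - rebuilt from the current posterior condylar tangent and the
#     global vertical, emulating a patella-forward standing radiograph that
#     follows the (possibly rotated) distal fragment;
#   global_fixed  - the model's pre-operative global anterior direction.

#' Measure the AP-projected mechanical leg axis (HKA)
#'
#' @param lm A `leg_landmarks` object.
#' @param mode Projection mode, `"knee_anchored"` (default) or
#'   `"global_fixed"`; see Details.
#' @details In `knee_anchored` mode the frontal-plane normal is
#'   `cross(vertical, condylar tangent)` with the tangent taken from the
#'   current (possibly rotated) posterior condyles and the vertical from the
#'   model's pre-operative proximal direction; in `global_fixed` mode it is the
#'   stored pre-operative anterior direction. The returned angle is positive
#'   for valgus on a right leg.
#' @return An object of class `alignment_result`: `hka_valgus_deg`,
#'   unit `femoral_axis` and `tibial_axis` (both pointing distally),
#'   `projection_normal`, and `mode`.
#' @export
measure_projected_hka <- function(lm, mode = c("knee_anchored", "global_fixed")) {
  mode <- match.arg(mode)
  f <- lm$knee_center - lm$hip_center    # femoral mechanical axis, distal
  t <- lm$ankle_center - lm$knee_center  # tibial mechanical axis, distal
  ap <- if (mode == "knee_anchored") {
    v_unit(v_cross(lm$proximal0, condylar_tangent_medial(lm)))
  } else {
    lm$anterior0
  }
  # keep the AP normal on the anterior side so the valgus sign convention is
  # stable under mirroring (left legs carry a lateral-pointing tangent)
  if (v_dot(ap, lm$anterior0) < 0) ap <- -ap
  hka <- signed_angle_in_plane(f, t, ap)
  structure(list(hka_valgus_deg = hka,
                 femoral_axis = v_unit(f),
                 tibial_axis = v_unit(t),
                 projection_normal = ap,
                 mode = mode),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  side <- if (x$hka_valgus_deg >= 0) "valgus" else "varus"
  cat(sprintf("<alignment_result> HKA %+.2f deg (%s), %s projection\n",
              x$hka_valgus_deg, side, x$mode))
  invisible(x)
}

#' Absolute deviation of the mechanical leg axis from the pre-operative state
#'
#' @param pre,post `alignment_result` objects measured in the same projection
#'   mode.
#' @return `abs(post - pre)` of the signed HKA angles, degrees.
#' @export
deviation_from_preop <- function(pre, post) {
  stopifnot(inherits(pre, "alignment_result"), inherits(post, "alignment_result"))
  if (!identical(pre$mode, post$mode)) {
    stop("pre and post alignment were measured in different projection modes",
         call. = FALSE)
  }
  abs(post$hka_valgus_deg - pre$hka_valgus_deg)
}

#' Hip-centre locus relative to the rotated distal fragment
#'
#' For each rotation angle, expresses the hip centre in the coordinate system
#' of the distal fragment (equivalently: rotates the hip by the negative
#' fragment rotation about the osteotomy axis) and reports its AP-projected
#' distance from the pre-operative hip position. All positions lie on one
#' circle about the rotation axis; tracing it reproduces how the projected hip
#' first moves away from and can fall back towards its pre-operative frontal
#' position as rotation grows.
#'
#' @param lm A pre-operative `leg_landmarks` object with the hip proximal to
#'   the plane.
#' @param plane The cutting [plane3()].
#' @param frame The osteotomy [frame3()].
#' @param thetas Numeric vector of signed rotation angles in degrees (positive
#'   = external for a right leg).
#' @return A [tibble::tibble()] with columns `theta_deg`, `hip_x`, `hip_y`,
#'   `hip_z` (fragment-frame coordinates, mm) and `ap_distance_mm` (frontal
#'   in-plane distance from the pre-operative hip).
#' @export
hip_center_locus <- function(lm, plane, frame, thetas) {
  stopifnot(inherits(plane, "plane3"), inherits(frame, "frame3"))
  frag <- split_fragments(lm, plane)
  if (!"hip_center" %in% frag$proximal) {
    stop("hip centre must lie proximal to the cutting plane", call. = FALSE)
  }
  dir <- plane$normal
  if (v_dot(dir, femoral_mech_dir(lm)) < 0) dir <- -dir
  ax <- axis3(frame$origin, dir)
  hip0 <- lm$hip_center
  ap <- lm$anterior0
  rows <- lapply(thetas, function(th) {
    hip <- rotate_about_axis(hip0, ax, -th)
    d <- hip - hip0
    d_frontal <- d - v_dot(d, ap) * ap
    tibble::tibble(theta_deg = th, hip_x = hip[1], hip_y = hip[2],
                   hip_z = hip[3], ap_distance_mm = v_norm(d_frontal))
  })
  dplyr::bind_rows(rows)
}
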