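# Parametric landmark-based model of a right lower limb.
#
# Global coordinate conventions (right leg): X anterior, Y proximal, Z medial,
# right-handed, knee centre at the origin, units mm. The femoral mechanical
# axis (hip centre -> knee centre) is built along +Y; the pre-operative
# hip-knee-ankle (HKA) angle is carried entirely by the tibial mechanical axis,
# and the distal femoral joint-line obliquity by the mLDFA.

#' Parameters of a synthetic lower-limb model
#'
#' Angular deformity parameters follow clinical sign conventions: femoral
#' torsion positive for antetorsion (neck anterior to the posterior condylar
#' plane), HKA positive for valgus. Segment dimensions default to adult norms
#' and are freely overridable.
#'
#' @param femoral_torsion_deg Femoral torsion in degrees (+ antetorsion,
#'   - retrotorsion); must lie in `[-30, 60]`.
#' @param antecurvatum_deg Anterior bowing angle of the femoral shaft, degrees,
#'   non-negative.
#' @param mldfa_deg Mechanical lateral distal femoral angle, degrees, in
#'   `[75, 95]`.
#' @param preop_hka_valgus_deg Pre-operative AP-projected mechanical leg axis,
#'   degrees (+ valgus, - varus).
#' @param femur_length_mm,tibia_length_mm Mechanical axis lengths, mm.
#' @param neck_length_mm Femoral neck length (head centre to shaft junction), mm.
#' @param neck_shaft_angle_deg Angle between neck axis and distal shaft
#'   direction, degrees.
#' @param head_to_lt_distance_mm Proximo-distal distance from the femoral head
#'   centre to the lesser trochanter level, mm.
#' @param condylar_halfwidth_mm Half the intercondylar width used to place the
#'   condylar landmarks, mm.
#' @param side Only `"right"` is supported; left legs mirror to right first.
#' @param model_id Optional label carried through simulation records.
#' @return An object of class `leg_parameters`.
#' @seealso [model_1_parameters()], [model_2_parameters()],
#'   [generate_synthetic_leg()]
#' @export
leg_parameters <- function(femoral_torsion_deg,
                           antecurvatum_deg,
                           mldfa_deg,
                           preop_hka_valgus_deg,
                           femur_length_mm = 420,
                           tibia_length_mm = 380,
                           neck_length_mm = 50,
                           neck_shaft_angle_deg = 127,
                           head_to_lt_distance_mm = 60,
                           condylar_halfwidth_mm = 40,
                           side = "right",
                           model_id = "model") {
  side <- match.arg(side, "right")
  p <- list(femoral_torsion_deg = femoral_torsion_deg,
            antecurvatum_deg = antecurvatum_deg,
            mldfa_deg = mldfa_deg,
            preop_hka_valgus_deg = preop_hka_valgus_deg,
            femur_length_mm = femur_length_mm,
            tibia_length_mm = tibia_length_mm,
            neck_length_mm = neck_length_mm,
            neck_shaft_angle_deg = neck_shaft_angle_deg,
            head_to_lt_distance_mm = head_to_lt_distance_mm,
            condylar_halfwidth_mm = condylar_halfwidth_mm,
            side = side, model_id = model_id)
  num <- vapply(p[1:10], function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), logical(1))
  if (!all(num)) stop("all leg parameters must be finite scalars", call. = FALSE)
  if (p$femoral_torsion_deg < -30 || p$femoral_torsion_deg > 60)
    stop("femoral_torsion_deg must lie in [-30, 60]", call. = FALSE)
  if (p$antecurvatum_deg < 0)
    stop("antecurvatum_deg must be non-negative", call. = FALSE)
  if (p$mldfa_deg < 75 || p$mldfa_deg > 95)
    stop("mldfa_deg must lie in [75, 95]", call. = FALSE)
  lens <- c(p$femur_length_mm, p$tibia_length_mm, p$neck_length_mm,
            p$head_to_lt_distance_mm, p$condylar_halfwidth_mm)
  if (any(lens <= 0)) stop("segment dimensions must be positive", call. = FALSE)
  structure(p, class = "leg_parameters")
}

#' Printed anatomy of the two study models
#'
#' `model_1_parameters()`: 42 degrees of femoral antetorsion, 8 degrees
#' antecurvatum, mLDFA 85 degrees, pre-operative mechanical leg axis 2.4
#' degrees valgus. `model_2_parameters()`: 6 degrees retrotorsion, 14 degrees
#' antecurvatum, mLDFA 86 degrees, 5.1 degrees valgus.
#'
#' @param ... Overrides forwarded to [leg_parameters()] (segment dimensions,
#'   for sensitivity checks).
#' @return A `leg_parameters` object.
#' @export
model_1_parameters <- function(...) {
  leg_parameters(femoral_torsion_deg = 42, antecurvatum_deg = 8,
                 mldfa_deg = 85, preop_hka_valgus_deg = 2.4,
                 model_id = "model_1", ...)
}

#' @rdname model_1_parameters
#' @export
model_2_parameters <- function(...) {
  leg_parameters(femoral_torsion_deg = -6, antecurvatum_deg = 14,
                 mldfa_deg = 86, preop_hka_valgus_deg = 5.1,
                 model_id = "model_2", ...)
}

# number of samples along the femoral shaft polyline
SHAFT_POINTS <- 81L

# circular arc from p0 to p1 bowing towards bow_dir with total tangent turning
# angle omega_deg; returns an n x 3 matrix of points ordered p0 -> p1
shaft_arc <- function(p0, p1, bow_dir, omega_deg, n = SHAFT_POINTS) {
  tt <- seq(0, 1, length.out = n)
  chord <- p1 - p0
  if (omega_deg < 1e-9) {
    return(t(vapply(tt, function(s) p0 + s * chord, numeric(3))))
  }
  c_hat <- v_unit(chord)
  b_hat <- v_unit(bow_dir - v_dot(bow_dir, c_hat) * c_hat)
  omega <- omega_deg * DEG2RAD
  r <- v_norm(chord) / (2 * sin(omega / 2))
  centre <- (p0 + p1) / 2 - b_hat * r * cos(omega / 2)
  n_hat <- v_cross(c_hat, b_hat)
  ax <- axis3(centre, n_hat)
  # choose the sweep sense that carries p0 onto p1
  sgn <- if (v_norm(rotate_about_axis(p0, ax, omega / DEG2RAD) - p1) <
             v_norm(rotate_about_axis(p0, ax, -omega / DEG2RAD) - p1)) 1 else -1
  t(vapply(tt, function(s) rotate_about_axis(p0, ax, sgn * s * omega / DEG2RAD),
           numeric(3)))
}

#' Generate a synthetic landmark-based leg model
#'
#' Deterministically constructs the named anatomical landmarks of a right lower
#' limb from its clinical parameters: knee centre at the origin, femoral
#' mechanical axis along global +Y (proximal), X anterior, Z medial. The
#' posterior condylar tangent lies in the transverse plane; the femoral neck
#' axis is placed at the requested torsion to the condylar tangent (projected
#' perpendicular to the mechanical axis) and at the neck-shaft angle to the
#' proximal direction; the shaft polyline is a circular anterior-bowing arc
#' from the neck-shaft junction to the knee centre whose proximal/distal third
#' chords subtend the antecurvatum angle; the tibial mechanical axis is tilted
#' in the frontal plane so the AP-projected HKA equals the requested
#' pre-operative value.
#'
#' @param params A [leg_parameters()] object.
#' @return An object of class `leg_landmarks`: named points (`hip_center`,
#'   `knee_center`, `ankle_center`, `lesser_trochanter`,
#'   `posterior_condyle_medial/lateral`, `distal_condyle_medial/lateral`), the
#'   unit `neck_axis`, a `shaft_polyline` matrix ordered proximal to distal,
#'   and metadata (`side`, global reference directions, the generating
#'   parameters).
#' @export
generate_synthetic_leg <- function(params) {
  stopifnot(inherits(params, "leg_parameters"))
  p <- params
  anterior <- c(1, 0, 0); proximal <- c(0, 1, 0); medial <- c(0, 0, 1)

  knee <- c(0, 0, 0)
  hip <- knee + p$femur_length_mm * proximal

  hw <- p$condylar_halfwidth_mm
  pc_med <- knee + c(-20, 0, hw)
  pc_lat <- knee + c(-20, 0, -hw)

  # distal joint line: lateral angle to the (proximal) mechanical axis = mLDFA
  m <- p$mldfa_deg * DEG2RAD
  j_lat <- c(0, cos(m), -sin(m))        # lateral end direction of joint line
  dc_lat <- knee + hw * j_lat
  dc_med <- knee - hw * j_lat

  # neck axis: torsion about the mechanical axis from the medial condylar
  # tangent, then lifted proximally by (neck-shaft angle - 90)
  tor <- p$femoral_torsion_deg * DEG2RAD
  neck_inplane <- cos(tor) * medial + sin(tor) * anterior
  psi <- (180 - p$neck_shaft_angle_deg) * DEG2RAD  # angle to proximal axis
  neck_axis <- cos(psi) * proximal + sin(psi) * neck_inplane

  junction <- hip - p$neck_length_mm * neck_axis
  # The proximal/distal third chords of a circular arc with tangent turning
  # angle omega subtend 2/3 omega, so omega = 1.5 x antecurvatum to first
  # order; the sagittal projection of the laterally leaning shaft inflates the
  # measured angle slightly, so omega is refined by root finding against the
  # measurement itself (deterministic, tolerance 1e-8 deg).
  shaft <- if (p$antecurvatum_deg < 1e-9) {
    shaft_arc(junction, knee, anterior, 0)
  } else {
    f <- function(om) {
      antecurvatum_of_polyline(shaft_arc(junction, knee, anterior, om), medial) -
        p$antecurvatum_deg
    }
    om <- stats::uniroot(f, c(0.5 * p$antecurvatum_deg, 2 * p$antecurvatum_deg),
                         tol = 1e-8)$root
    shaft_arc(junction, knee, anterior, om)
  }

  # lesser trochanter: shaft point at the stated distance below the head level
  lt_y <- hip[2] - p$head_to_lt_distance_mm
  if (lt_y > max(shaft[, 2]) || lt_y < min(shaft[, 2])) {
    stop("inconsistent parameters: lesser trochanter level off the shaft",
         call. = FALSE)
  }
  lt <- shaft_point_at_y(shaft, lt_y)

  h <- p$preop_hka_valgus_deg * DEG2RAD
  ankle <- knee + p$tibia_length_mm * c(0, -cos(h), -sin(h))  # lateral = -Z

  structure(list(
    hip_center = hip, knee_center = knee, ankle_center = ankle,
    lesser_trochanter = lt,
    posterior_condyle_medial = pc_med, posterior_condyle_lateral = pc_lat,
    distal_condyle_medial = dc_med, distal_condyle_lateral = dc_lat,
    neck_axis = neck_axis,
    shaft_polyline = shaft,
    side = p$side,
    anterior0 = anterior, proximal0 = proximal, medial0 = medial,
    params = p), class = "leg_landmarks")
}

#' @export
print.leg_landmarks <- function(x, ...) {
  id <- if (is.null(x$params)) "landmarks" else x$params$model_id
  cat(sprintf("<leg_landmarks> %s (%s leg)\n", id, x$side))
  cat(sprintf("  torsion %.1f deg, antecurvatum %.1f deg, mLDFA %.1f deg, pre-op HKA %+.1f deg\n",
              measure_femoral_torsion(x), measure_antecurvatum(x),
              measure_mldfa(x), measure_projected_hka(x)$hka_valgus_deg))
  invisible(x)
}

point_names <- function() {
  c("hip_center", "knee_center", "ankle_center", "lesser_trochanter",
    "posterior_condyle_medial", "posterior_condyle_lateral",
    "distal_condyle_medial", "distal_condyle_lateral")
}

femoral_mech_dir <- function(lm) v_unit(lm$hip_center - lm$knee_center)

condylar_tangent_medial <- function(lm) {
  v_unit(lm$posterior_condyle_medial - lm$posterior_condyle_lateral)
}

#' Measure femoral torsion of a leg model
#'
#' Signed angle between the femoral neck axis and the posterior condylar
#' tangent (medial direction), both projected onto the plane perpendicular to
#' the femoral mechanical axis; antetorsion (neck anterior to the condylar
#' plane) positive for a right leg.
#'
#' @param lm A `leg_landmarks` object.
#' @return Torsion in degrees.
#' @export
measure_femoral_torsion <- function(lm) {
  y <- femoral_mech_dir(lm)
  signed_angle_in_plane(condylar_tangent_medial(lm), lm$neck_axis, y)
}

#' Measure the mechanical lateral distal femoral angle (mLDFA)
#'
#' Frontal-projected angle on the lateral side between the femoral mechanical
#' axis (pointing proximal) and the distal condylar joint line, using the
#' model's pre-operative anterior direction as the frontal-plane normal.
#'
#' @param lm A `leg_landmarks` object.
#' @return mLDFA in degrees.
#' @export
measure_mldfa <- function(lm) {
  y <- femoral_mech_dir(lm)
  j_lat <- lm$distal_condyle_lateral - lm$distal_condyle_medial
  a <- signed_angle_in_plane(y, j_lat, lm$anterior0)
  abs(a)
}

#' Measure the antecurvatum (anterior bowing) angle of the femoral shaft
#'
#' Sagittal-plane angle between the chord of the proximal third and the chord
#' of the distal third of the shaft polyline, projected onto the plane
#' spanned by the anterior and proximal reference directions.
#'
#' @param lm A `leg_landmarks` object.
#' @return Antecurvatum angle in degrees (non-negative for anterior bow).
#' @export
measure_antecurvatum <- function(lm) {
  antecurvatum_of_polyline(lm$shaft_polyline, lm$medial0)
}

# sagittal-projected angle between proximal- and distal-third chords
antecurvatum_of_polyline <- function(s, sag_normal) {
  n <- nrow(s)
  if (n < 3L) stop("shaft polyline needs at least 3 points", call. = FALSE)
  k <- max(2L, floor(n / 3))
  chord_prox <- s[k, ] - s[1, ]
  chord_dist <- s[n, ] - s[n - k + 1L, ]
  abs(signed_angle_in_plane(chord_prox, chord_dist, sag_normal))
}

# cumulative arc length along a polyline matrix
polyline_arclength <- function(s) {
  seg <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# point at a given arc length (linear interpolation between samples)
polyline_point_at <- function(s, target) {
  cs <- polyline_arclength(s)
  if (target < -1e-9 || target > cs[length(cs)] + 1e-9) {
    stop("arc-length position outside the shaft span", call. = FALSE)
  }
  target <- min(max(target, 0), cs[length(cs)])
  i <- findInterval(target, cs, rightmost.closed = TRUE)
  i <- min(i, length(cs) - 1L)
  f <- (target - cs[i]) / (cs[i + 1L] - cs[i])
  s[i, ] + f * (s[i + 1L, ] - s[i, ])
}

# shaft point at a given proximo-distal (Y) level; polyline Y is monotone
shaft_point_at_y <- function(s, y_level) {
  ys <- s[, 2]
  i <- which(diff(sign(ys - y_level)) != 0)
  if (length(i) == 0L) {
    j <- which.min(abs(ys - y_level))
    return(s[j, ])
  }
  i <- i[1]
  f <- (y_level - ys[i]) / (ys[i + 1L] - ys[i])
  s[i, ] + f * (s[i + 1L, ] - s[i, ])
}

#' Shaft point at an osteotomy level
#'
#' Returns the point on the femoral shaft polyline at a given arc-length offset
#' from the site's reference level: distal to the lesser trochanter for
#' subtrochanteric cuts, proximal to the distal condylar level for
#' supracondylar cuts. This is the geometrical centre of a narrow shaft slice
#' at the cut level and becomes the origin of the osteotomy coordinate system.
#'
#' @param lm A `leg_landmarks` object.
#' @param site `"subtrochanteric"` or `"supracondylar"`.
#' @param offset_mm Arc-length offset in mm from the site reference level
#'   (below the lesser trochanter / above the condyles).
#' @return Numeric length-3 point on the shaft.
#' @export
shaft_point_at_level <- function(lm, site = c("subtrochanteric", "supracondylar"),
                                 offset_mm) {
  site <- match.arg(site)
  s <- lm$shaft_polyline
  cs <- polyline_arclength(s)
  if (site == "subtrochanteric") {
    lt <- lm$lesser_trochanter
    d2 <- rowSums(sweep(s, 2, lt)^2)
    i <- which.min(d2)
    s_lt <- cs[i]   # polyline contains the interpolated LT level closely
    # refine: project LT onto the neighbouring segment
    s_lt <- cs[i] + if (i < nrow(s)) v_dot(lt - s[i, ], v_unit(s[i + 1, ] - s[i, ])) else 0
    polyline_point_at(s, s_lt + offset_mm)
  } else {
    polyline_point_at(s, cs[length(cs)] - offset_mm)
  }
}

#' Assign landmarks to the proximal or distal osteotomy fragment
#'
#' Landmarks with signed plane distance towards the hip are proximal, all
#' others (knee, condyles, ankle) distal; shaft polyline points are split
#' individually by side. The plane must actually separate hip from ankle.
#'
#' @param lm A `leg_landmarks` object.
#' @param plane A [plane3()] cutting plane.
#' @return A list with character vectors `proximal` and `distal` (named
#'   landmarks) and an integer vector `shaft_distal` of distal polyline row
#'   indices.
#' @export
split_fragments <- function(lm, plane) {
  stopifnot(inherits(plane, "plane3"))
  # orient the normal towards the hip
  nrm <- plane$normal
  if (point_plane_distance(lm$hip_center, plane) < 0) nrm <- -nrm
  pl <- plane3(plane$point, nrm)
  d_hip <- point_plane_distance(lm$hip_center, pl)
  d_ankle <- point_plane_distance(lm$ankle_center, pl)
  if (d_hip <= 0 || d_ankle >= 0) {
    stop("invalid plane: hip and ankle are not on opposite sides", call. = FALSE)
  }
  dist <- vapply(point_names(), function(nm) point_plane_distance(lm[[nm]], pl),
                 numeric(1))
  if (any(abs(dist) <= 1e-6)) {
    stop("a landmark lies exactly on the cutting plane", call. = FALSE)
  }
  shaft_d <- apply(lm$shaft_polyline, 1, function(p) point_plane_distance(p, pl))
  list(proximal = names(dist)[dist > 0],
       distal = names(dist)[dist < 0],
       shaft_distal = which(shaft_d < 0))
}

#' Read leg landmarks from a JSON annotation file
#'
#' Schema: a JSON object with `side` (`"right"`), one `[x, y, z]` array in mm
#' for each named landmark point (see [generate_synthetic_leg()] for names),
#' a unit `neck_axis`, and `shaft_polyline` as an array of `[x, y, z]` points
#' ordered proximal to distal. Optional `anterior`, `proximal`, `medial`
#' reference directions default to the global axes.
#'
#' @param path Path to a JSON file.
#' @return A `leg_landmarks` object.
#' @export
read_leg_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c(point_names(), "neck_axis", "shaft_polyline")
  miss <- setdiff(need, names(j))
  if (length(miss) > 0) {
    stop("landmark file missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  lm <- list()
  for (nm in point_names()) lm[[nm]] <- as_vec3(j[[nm]], nm)
  lm$neck_axis <- check_unit(j$neck_axis, "neck_axis")
  sp <- j$shaft_polyline
  if (is.list(sp)) sp <- do.call(rbind, sp)
  lm$shaft_polyline <- matrix(as.numeric(sp), ncol = 3)
  lm$side <- if (is.null(j$side)) "right" else j$side
  lm$anterior0 <- if (is.null(j$anterior)) c(1, 0, 0) else check_unit(j$anterior)
  lm$proximal0 <- if (is.null(j$proximal)) c(0, 1, 0) else check_unit(j$proximal)
  lm$medial0 <- if (is.null(j$medial)) c(0, 0, 1) else check_unit(j$medial)
  lm$params <- NULL
  structure(lm, class = "leg_landmarks")
}
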