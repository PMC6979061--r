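# Osteotomy frames, plane mal-angulation and fragment rotation.

test_that("osteotomy frames align with the mechanical axis and rotational reference", {
  for (lm in list(leg_model_1(), leg_model_2())) {
    for (spec in list(list(site = "subtrochanteric", off = 45, ref = lm$neck_axis),
                      list(site = "supracondylar", off = 60,
                           ref = v_unit(lm$posterior_condyle_medial -
                                          lm$posterior_condyle_lateral)))) {
      fr <- build_osteotomy_frame(lm, spec$site, spec$off)
      y_mech <- v_unit(lm$hip_center - lm$knee_center)
      expect_equal(v_dot(fr$y, y_mech), 1, tolerance = 1e-9)
      # z equals the projection oracle of the site reference, pointing medial
      z_oracle <- spec$ref - v_dot(spec$ref, y_mech) * y_mech
      z_oracle <- z_oracle / v_norm(z_oracle)
      if (v_dot(z_oracle, lm$medial0) < 0) z_oracle <- -z_oracle
      expect_equal(fr$z, z_oracle, tolerance = 1e-9)
      expect_gt(v_dot(fr$z, lm$medial0), 0)
      expect_gt(v_dot(fr$x, lm$anterior0), 0)
      # orthonormal right-handed
      expect_equal(v_dot(fr$x, v_cross(fr$y, fr$z)), 1, tolerance = 1e-9)
      # origin on the shaft at the requested level
      expect_equal(fr$origin, shaft_point_at_level(lm, spec$site, spec$off))
    }
  }
})

test_that("the baseline plane is perpendicular to the mechanical axis", {
  lm <- leg_model_1()
  for (site in c("subtrochanteric", "supracondylar")) {
    fr <- build_osteotomy_frame(lm, site, if (site == "subtrochanteric") 45 else 60)
    pl <- make_baseline_plane(fr)
    expect_equal(v_dot(pl$normal, v_unit(lm$hip_center - lm$knee_center)), 1,
                 tolerance = 1e-9)
    expect_equal(pl$point, fr$origin)
    expect_lt(point_plane_distance(lm$ankle_center, pl) *
                point_plane_distance(lm$hip_center, pl), 0)
  }
})

test_that("plane tilting rotates the normal about the stated frame axis", {
  fr <- build_osteotomy_frame(leg_model_1(), "subtrochanteric", 45)
  expect_equal(tilt_plane(fr, plane_angulation("frontal", 0, "plus"))$normal,
               fr$y, tolerance = 1e-12)
  sag <- tilt_plane(fr, plane_angulation("sagittal", 30, "plus"))
  expect_equal(v_dot(sag$normal, fr$y), cos(30 * pi / 180), tolerance = 1e-9)
  expect_lt(abs(v_dot(sag$normal, fr$z)), 1e-9)  # stays in the x-y plane
  expect_gt(abs(v_dot(sag$normal, fr$x)), 0.1)
  fro <- tilt_plane(fr, plane_angulation("frontal", 15, "minus"))
  expect_equal(v_dot(fro$normal, fr$y), cos(15 * pi / 180), tolerance = 1e-9)
  expect_lt(abs(v_dot(fro$normal, fr$x)), 1e-9)  # stays in the y-z plane

  # +m then -m returns the baseline normal; tilt angle equals the magnitude
  for (pl_dir in c("frontal", "sagittal")) {
    for (m in c(5, 10, 15, 20, 30)) {
      about <- if (pl_dir == "frontal") fr$x else fr$z
      n1 <- tilt_plane(fr, plane_angulation(pl_dir, m, "plus"))$normal
      back <- osteoaxis:::rotate_direction(n1, about, -m)
      expect_equal(back, fr$y, tolerance = 1e-9)
      ang <- acos(min(1, v_dot(n1, fr$y))) * 180 / pi
      expect_equal(ang, m, tolerance = 1e-9)
    }
  }
})

test_that("fragment rotation is rigid, invertible and anchored on the plane normal", {
  lm <- leg_model_2()
  fr <- build_osteotomy_frame(lm, "subtrochanteric", 40)
  pl <- tilt_plane(fr, plane_angulation("sagittal", 20, "plus"))

  rot <- apply_rotational_osteotomy(lm, pl, fr, rotation_spec(25, "internal"))
  tr <- attr(rot, "transform")
  expect_equal(tr$axis$direction,
               pl$normal * sign(v_dot(pl$normal, c(0, 1, 0))), tolerance = 1e-12)
  expect_equal(tr$angle_deg, -25)  # internal = negative right-handed sense

  # proximal fragment untouched
  expect_identical(rot$hip_center, lm$hip_center)
  expect_identical(rot$lesser_trochanter, lm$lesser_trochanter)
  # rigidity within the distal fragment
  d_pre <- c(v_norm(lm$knee_center - lm$ankle_center),
             v_norm(lm$posterior_condyle_medial - lm$posterior_condyle_lateral),
             v_norm(lm$knee_center - lm$distal_condyle_medial))
  d_post <- c(v_norm(rot$knee_center - rot$ankle_center),
              v_norm(rot$posterior_condyle_medial - rot$posterior_condyle_lateral),
              v_norm(rot$knee_center - rot$distal_condyle_medial))
  expect_equal(d_post, d_pre, tolerance = 1e-9)

  # external theta then internal theta restores the landmarks
  ext <- apply_rotational_osteotomy(lm, pl, fr, rotation_spec(25, "external"))
  back <- apply_rotational_osteotomy(ext, pl, fr, rotation_spec(25, "internal"))
  for (nm in c("knee_center", "ankle_center", "posterior_condyle_medial")) {
    expect_equal(back[[nm]], lm[[nm]], tolerance = 1e-9)
  }
  expect_equal(back$shaft_polyline, lm$shaft_polyline, tolerance = 1e-9)

  # zero rotation is the identity
  id <- apply_rotational_osteotomy(lm, pl, fr, rotation_spec(0, "external"))
  expect_equal(id$ankle_center, lm$ankle_center, tolerance = 1e-12)

  # baseline plane: rotation axis equals the mechanical axis direction
  base <- make_baseline_plane(fr)
  tr_b <- attr(apply_rotational_osteotomy(lm, base, fr, rotation_spec(10, "internal")),
               "transform")
  expect_equal(tr_b$axis$direction, v_unit(lm$hip_center - lm$knee_center),
               tolerance = 1e-9)
})

test_that("external rotation carries the distal anterior direction laterally", {
  lm <- leg_model_1()
  fr <- build_osteotomy_frame(lm, "supracondylar", 60)
  rot <- apply_rotational_osteotomy(lm, make_baseline_plane(fr), fr,
                                    rotation_spec(20, "external"))
  ant_pre <- v_unit(v_cross(c(0, 1, 0), v_unit(
    lm$posterior_condyle_medial - lm$posterior_condyle_lateral)))
  ant_post <- v_unit(v_cross(c(0, 1, 0), v_unit(
    rot$posterior_condyle_medial - rot$posterior_condyle_lateral)))
  # anterior direction acquires a lateral (-z) component for a right leg
  expect_lt(v_dot(ant_post, lm$medial0), v_dot(ant_pre, lm$medial0))
})

test_that("baseline rotations obey the closed-form small-offset bound", {
  for (p in list(model_1_parameters(), model_2_parameters())) {
    lm <- generate_synthetic_leg(p)
    off <- if (p$model_id == "model_1") 60 else 65
    fr <- build_osteotomy_frame(lm, "supracondylar", off)
    base <- make_baseline_plane(fr)
    w <- lm$knee_center - fr$origin
    d <- v_norm(w - v_dot(w, fr$y) * fr$y)  # knee offset from the rotation axis
    pre <- measure_projected_hka(lm)
    for (th in c(5, 10, 15, 20, 30)) {
      post <- measure_projected_hka(
        apply_rotational_osteotomy(lm, base, fr, rotation_spec(th, "external")))
      dev <- deviation_from_preop(pre, post)
      bound <- atan(2 * d * sin(th / 2 * pi / 180) / p$tibia_length_mm) * 180 / pi
      expect_lte(dev, bound + 1e-6)
      if (p$model_id == "model_1") expect_lt(dev, 0.2)
    }
  }
})

test_that("supracondylar deviation approaches asin(sin a sin t) as the cut nears the condyles", {
  lm <- generate_synthetic_leg(leg_parameters(0, 0, 90, 0))
  fr <- build_osteotomy_frame(lm, "supracondylar", 0.01)
  pre <- measure_projected_hka(lm)
  for (a in c(10, 20, 30)) {
    pl <- tilt_plane(fr, plane_angulation("sagittal", a, "minus"))
    for (th in c(10, 20, 30)) {
      for (sense in c("external", "internal")) {
        post <- measure_projected_hka(
          apply_rotational_osteotomy(lm, pl, fr, rotation_spec(th, sense)))
        law <- asin(sin(a * pi / 180) * sin(th * pi / 180)) * 180 / pi
        expect_lt(abs(deviation_from_preop(pre, post) - law), 0.1)
      }
    }
  }
})
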