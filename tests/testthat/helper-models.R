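# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

leg_model_1 <- function() {
  if (is.null(.fixtures$lm1)) .fixtures$lm1 <- generate_synthetic_leg(model_1_parameters())
  .fixtures$lm1
}

leg_model_2 <- function() {
  if (is.null(.fixtures$lm2)) .fixtures$lm2 <- generate_synthetic_leg(model_2_parameters())
  .fixtures$lm2
}

# full default factorial grid (420 runs), cached across test files
default_records <- function() {
  if (is.null(.fixtures$records)) .fixtures$records <- run_grid(grid_config())
  .fixtures$records
}

default_table <- function() {
  if (is.null(.fixtures$table)) .fixtures$table <- summarize_table(default_records())
  .fixtures$table
}

# apply one rigid transform (rotation about an axis + translation) to every
# landmark, direction and stored reference direction of a leg model
rigid_transform_leg <- function(lm, axis, angle_deg, translation) {
  out <- lm
  for (nm in c("hip_center", "knee_center", "ankle_center", "lesser_trochanter",
               "posterior_condyle_medial", "posterior_condyle_lateral",
               "distal_condyle_medial", "distal_condyle_lateral")) {
    out[[nm]] <- rotate_about_axis(lm[[nm]], axis, angle_deg) + translation
  }
  out$shaft_polyline <- t(apply(lm$shaft_polyline, 1, function(p)
    rotate_about_axis(p, axis, angle_deg) + translation))
  rotdir <- function(v) rotate_about_axis(axis$point + v, axis, angle_deg) -
    rotate_about_axis(axis$point, axis, angle_deg)
  for (nm in c("neck_axis", "anterior0", "proximal0", "medial0")) {
    out[[nm]] <- rotdir(lm[[nm]])
  }
  out
}

# mirror a right leg across the sagittal midplane (flip the medial axis)
mirror_leg <- function(lm) {
  out <- lm
  flip <- function(p) p * c(1, 1, -1)
  for (nm in c("hip_center", "knee_center", "ankle_center", "lesser_trochanter",
               "posterior_condyle_medial", "posterior_condyle_lateral",
               "distal_condyle_medial", "distal_condyle_lateral",
               "neck_axis")) {
    out[[nm]] <- flip(lm[[nm]])
  }
  out$shaft_polyline <- lm$shaft_polyline %*% diag(c(1, 1, -1))
  out
}
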