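---
title: "Mal-angulated femoral rotational osteotomies and the mechanical leg axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mal-angulated femoral rotational osteotomies and the mechanical leg axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoaxis)
```

## The question

Subtrochanteric and supracondylar femoral rotational osteotomies correct
excessive femoral antetorsion or retrotorsion by cutting the femur and
rotating the distal fragment about the bone's long axis. If the cut is placed
exactly perpendicular to the *mechanical* femoral axis (the line from the
femoral head centre to the knee centre), pure rotation should leave the
frontal-plane mechanical leg axis — the hip–knee–ankle (HKA) angle — nearly
unchanged. Intra-operatively, however, the plane is aimed free-hand at an
imagined axis, so some mal-angulation in the frontal or sagittal direction is
likely. `osteoaxis` quantifies how much HKA deviation such mal-angulation
produces as a function of tilt direction, tilt magnitude and rotation angle,
and flags the combinations that exceed the ~2° accuracy achievable when an
axis correction is actually intended.

## The model

Every computation operates on a **landmark model** of one right lower limb:
hip, knee and ankle centres, the lesser trochanter, posterior and distal
condylar landmark pairs, the femoral neck axis, and a polyline along the
femoral shaft. Surfaces add nothing to the measured quantities — every angle
in the study is defined by axes and centres — so meshes are supported only as
an optional source of the same landmarks (JSON annotation files via
`read_leg_landmarks()`).

The synthetic generator `generate_synthetic_leg()` places, in a global frame
with X anterior, Y proximal and Z medial:

* the femoral mechanical axis along +Y with the knee centre at the origin;
* the posterior condylar tangent in the transverse plane;
* the distal joint line at the requested mLDFA to the mechanical axis;
* the neck axis at the requested torsion to the condylar tangent (both
  projected perpendicular to the mechanical axis) and at the neck–shaft angle
  to the proximal direction;
* the shaft as a circular anterior-bowing arc from the neck–shaft junction to
  the knee centre. The proximal-third and distal-third chords of an arc with
  tangent turning angle $\omega$ subtend $\tfrac{2}{3}\omega$, so
  $\omega \approx 1.5\times$ the antecurvatum angle; because the sagittal
  *projection* of the laterally leaning shaft slightly inflates the measured
  angle, $\omega$ is refined by deterministic root finding against the
  measurement itself (tolerance $10^{-8}$°);
* the tibial mechanical axis tilted in the frontal plane so that the
  AP-projected HKA equals the requested pre-operative value.

Measurement and generation therefore round-trip exactly; the test suite
asserts recovery of torsion, antecurvatum, mLDFA and HKA within 0.2°.

The two study models are available as presets:

```{r}
generate_synthetic_leg(model_1_parameters())  # 42 deg antetorsion
generate_synthetic_leg(model_2_parameters())  # 6 deg retrotorsion
```

### Parameters the study does not pin down

The published anatomy fixes torsion, antecurvatum, mLDFA and pre-operative
HKA, but not segment dimensions. Defaults are adult norms, all overridable
through `leg_parameters()`: femur 420 mm, tibia 380 mm, neck length 50 mm,
neck–shaft angle 127°, head-to-lesser-trochanter distance 60 mm, condylar
half-width 40 mm. These choices matter quantitatively: the neck geometry and
shaft bow set the lateral/anterior offset of the shaft from the mechanical
axis, which in turn controls how far the hip centre sits from the rotation
axis and hence the absolute size of the *subtrochanteric* deviations. The
supracondylar cells are dominated by the long lever arm between the cut and
the hip and are much less sensitive to these defaults.

## Osteotomy simulation

`build_osteotomy_frame()` erects the reference frame at the cut: origin at
the shaft-slice centre (45/40 mm below the lesser trochanter, 60/65 mm above
the condyles, per model), y along the mechanical axis pointing proximal, z
the in-plane projection of the neck axis (subtrochanteric) or posterior
condylar tangent (supracondylar) pointing medial, x = y × z pointing
anterior. The baseline plane is perpendicular to the mechanical axis;
`tilt_plane()` rotates its normal about the frame's x axis (frontal
mal-angulation) or z axis (sagittal mal-angulation).

`apply_rotational_osteotomy()` rotates the distal fragment rigidly about the
normal of the (possibly tilted) plane through the frame origin — the fragment
turns *on the cut surface*. Whether rotation after mal-angulation happens
about the tilted normal or the original mechanical axis is genuinely
ambiguous surgically; the tilted normal matches a fragment sliding on its
cut and is the default, with `rotation_axis = "baseline_y"` retained for
sensitivity analysis. External rotation is the positive right-handed sense
about the proximally oriented axis for a right leg (the distal anterior
direction moves laterally).

## Measuring the mechanical leg axis

`measure_projected_hka()` projects the femoral (hip→knee) and tibial
(knee→ankle) mechanical axes onto a frontal plane and returns their signed
angle, valgus positive. The exact AP direction of the original measurement
protocol is not fully specified, so two modes are provided:

* **knee_anchored** (default): the AP direction is rebuilt from the *current*
  posterior condylar tangent and the global vertical — a patella-forward
  standing radiograph that follows the rotated distal fragment. This mode
  reproduces the near-invariance of baseline rotations.
* **global_fixed**: the pre-operative global anterior direction, for
  comparison.

The AP normal is sign-anchored to the model's anterior reference so that the
valgus convention is stable (mirroring a leg flips the measured sign, as it
must). Deviation is the absolute difference of signed pre/post HKA values;
summary cells pool both tilt directions and both models, so they are
insensitive to the clockwise/counter-clockwise labelling of the tilts.

In the small-offset limit the simulation admits closed forms that the tests
use as oracles: with the cut approaching the condyles, the deviation for
sagittal tilt $\alpha$ and rotation $\theta$ converges to
$\arcsin(\sin\alpha\,\sin\theta)$; for baseline planes the deviation is
bounded by $\arctan\!\big(2 d \sin(\theta/2)/L_{tibia}\big)$ where $d$ is the
offset of the knee centre from the rotation axis. With the default geometry
$d$ is ~5 mm for the antetorsion model but ~12 mm for the retrotorsion model
(its 14° bow pushes the shaft anteriorly), so baseline changes stay below
0.2° for the former and below ~0.8° for the latter — pooled, the baseline
mean is ~0.3°, consistent with a perpendicular osteotomy being essentially
axis-neutral at clinical measurement precision.

## The factorial study

`run_grid(grid_config())` reproduces the full design: per model and site, the
baseline plane plus 2 tilt planes × 5 magnitudes (5–30°) × 2 directions, each
followed by 5 rotations (5–30°) in the model's rotation sense — 20 baseline
and 400 mal-angulated simulations, 80 distinct mal-angulated planes.
`summarize_table()` pools each (site, tilt plane, magnitude, rotation) cell
over 2 models × 2 directions (n = 4) with mean and sample SD;
`flag_relevant()` marks cells with mean + SD strictly above 2°. The 2°
threshold mirrors the accuracy of an intended axis correction in high tibial
osteotomy; it is configurable. The whole grid is deterministic and runs in a
couple of seconds; re-runs produce byte-identical CSVs.

```{r, eval = FALSE}
records <- run_grid(grid_config())
table <- summarize_table(records)
write_results_csv(records, table, "results")
```

The numbered scripts under `analysis/` drive exactly this sequence and write
their tables under `results/`.

## What the synthetic models can and cannot show

The generator reproduces the *printed* anatomy of the two patients — the
deformity parameters that enter every measured angle — but not their
individual bone shape: the real shaft is not a circular arc, the condylar
offsets are idiosyncratic, and segment lengths were not published. The
supracondylar sagittal cells, which depend almost only on tilt, rotation and
the cut-to-hip lever arm, reproduce the published values closely (12.4° at
±30°/30°). Subtrochanteric cells inherit the uncertainty of the unpublished
neck/shaft offsets and come out ~15 % low (3.4° vs 4.0° at ±30°/30°) — the
qualitative structure (sagittal ≫ frontal, supracondylar ≫ subtrochanteric,
monotone growth with tilt and rotation, and the frontal counter-clockwise
subtrochanteric exception that peaks before 30° of rotation) is reproduced
exactly. Passing tests therefore validate the geometry and the study design,
not patient-specific magnitudes at the subtrochanteric site.

## Numerical choices and degenerate inputs

Angles cross every interface in degrees. Unit/orthogonality checks use a
1e-9 tolerance; directions within 1e-6 of unit length are renormalised rather
than rejected. Degenerate projections (vector parallel to a plane normal),
frames with parallel axis hints, cutting planes that fail to separate hip
from ankle, and landmarks lying exactly on a cutting plane (within 1e-6 mm)
raise errors instead of propagating noise. The shaft polyline uses 81 samples;
arc-length queries interpolate linearly between samples, and cut levels
outside the shaft span are rejected. Sample (n−1) standard deviations are
used throughout, matching descriptive statistics at n = 4. An optional seeded
landmark jitter was considered and deliberately omitted: every published
quantity is deterministic, and robustness is exercised through parameter
overrides instead.

## Known limitations

* Only isolated frontal or sagittal mal-angulation is simulated; combined
  tilts may compound or compensate.
* Only the AP-projected axis is analysed; the change of the antecurvatum
  angle after rotation is out of scope.
* Left legs are handled by mirroring to a right leg first; `side = "left"`
  is not yet a generator option.
* Wedge or translational cut errors, bone contact of the rotated cut
  surfaces, and implant geometry are not modelled; the published plate-driven
  cut levels are taken as given offsets.
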