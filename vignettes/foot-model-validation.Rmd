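---
title: "Multi-segment foot kinematics and the simulated dummy-foot validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-segment foot kinematics and the simulated dummy-foot validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footkin)
```

## The problem and the models

The foot is a chain of small joints whose coordinated pronation and
supination alternately make it flexible (shock absorption) and stiff
(propulsion). Single-segment foot models average this motion away.
`footkin` implements a multi-segment alternative: a hallux, a forefoot
spanning the five metatarsals, a rearfoot spanning navicular, cuneiforms,
cuboid, calcaneus and talus, and the shank. Two rearfoot conventions are
provided — a transverse-plane frame (`new`, long axis C1 → MC) and a
sagittal-plane frame (`new_2`, long axis C2 → MC) — plus a Rizzoli-style
reference model (`rizzoli`) for comparison. All three are declarative
specifications (`register_model()`, serializable with `model_to_yaml()`),
so custom marker sets need no code changes.

Each segment frame is built the same way (`build_segment_pose()`):

1. unit long-axis vector `u` from the axis marker pair — kept **exact**,
   because a two-marker direction is the most reliably measured quantity;
2. plane normal `n0` from the ordered marker triple,
   `(m2 − m1) × (m3 − m1)`, oriented by a per-definition sign (below);
3. `n = u × (n0 × u)` normalized — the normal's component orthogonal to
   `u`, so orthogonalization error is pushed into the less reliable plane
   estimate;
4. anatomical mapping: the long axis becomes anterior X (foot segments) or
   superior Y (shank); the normal becomes the axis its plane label implies
   (transverse → superior Y, sagittal → right-lateral Z, frontal →
   anterior X); the cross product completes a right-handed triad.

Joint angles are the intrinsic z–x′–y″ Cardan decomposition of
`t(R_parent) %*% R_child`, i.e. flexion (Z) first, then eversion/inversion
(X), then abduction/adduction (Y). The axis order is fixed by the model's
definition; intrinsic versus extrinsic reading is a genuine ambiguity, so
the decomposition is intrinsic by default (the standard joint-coordinate-
system reading, flexion first) with `convention = "zxy_extrinsic"`
available for sensitivity checks.

### Design choices that were genuinely open

* **Axis assignment.** The published axis drawings are figures, not
  numbers. We map the long axis to anterior X and the transverse-plane
  normal to superior Y so that Z is the flexion axis and X the inversion
  axis, which makes the Z-X-Y sequence read Df/Pf, Ev/Inv, Abd/Add in
  that order.
* **Normal sign.** The ordered-triple cross product may point superior or
  inferior depending on marker order. A per-frame check against a lab
  direction would break rigid-motion equivariance (a rotated trial would
  flip frames), so each segment definition stores a constant `normal_sign`
  calibrated once from neutral right-foot anatomy. Left feet must be
  mirrored (negate lab Z) before analysis — documented, never silent.
* **Gimbal lock.** At `|Ev/Inv| = 90°` the first and third angles are not
  separable. We report the X angle as ±90°, set Abd/Add to 0, absorb the
  coupled rotation into Df/Pf and flag the frame (`gimbal` attribute /
  `gimbal_flag` column); NaN is never returned silently.
* **Filter target.** Whether smoothing is applied to marker displacements
  or to computed angles is ambiguous in common practice. Default is
  markers — filtering before frame construction avoids smoothing through
  angle discontinuities — with `filter_stage` exposed in `run_config()`.
* **Rizzoli frames.** The reference model is reconstructed from the
  landmark correspondence table (PM→P1, FMH→H1, …) using the same
  primary-axis + plane machinery (hallux FMH→PM; metatarsus SMB→SMH with
  the head/base triad; calcaneus CA→ID with the CA, ST, PT triad). It is a
  documented reconstruction-from-citation, not a verbatim restatement of
  the original definitions.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `cutoff_hz` | 6 | Hz | standard low-pass cutoff for human movement marker data |
| `order` | 4 | – | order of the *single-pass* Butterworth; the forward–backward pass squares the magnitude response (the conventional reading in movement analysis) |
| `collinear_tol` | 1e-6 | – | frames with plane-triangle area < tol × (longest side)² are degenerate |
| `gimbal_tol` | 1e-6 | deg | distance from ±90° of the middle angle below which a frame is flagged |
| `noise_sd` | 0 | mm | sweep marker noise; 0 is the validity oracle, ~0.2 mm approximates camera noise |
| `placement_offset_deg` | 0 | deg | rigid mounting misalignment of the moving segment |
| LoA multiplier | 1.96 | – | classical Bland–Altman limits, not a t quantile |

The zero-lag filter extends each series by odd reflection over 3 × order
samples and initializes both passes at the steady state of the first
sample, so a constant signal is preserved exactly and in-band sinusoids
pass without phase lag. The filter requires `rate > 2 × cutoff` and more
than 3 × order frames, and errors otherwise.

Baseline subtraction (`static_baseline()` / `subtract_baseline()`) uses
the whole static trial by default; a 15 s standing record at 100 Hz is
typical, but the duration is the protocol's choice, not a constraint. One
baseline per session is assumed (the static trial), not per trial.

## What the synthetic rig emulates

`dummy_geometry()` describes three rigid styrene-foam-style box segments
(toe 30 × 80 × 55 mm, forefoot 50 × 80 × 95 mm, rearfoot
50 × 65 × 75 mm) resting on reference plates A, B, C, each plate carrying
markers o, x, z (plate X from o to x, Y normal to the plate via
`(z − o) × X` chosen to point up at neutral, Z completing the triad — the
measured o→z direction is only trusted for the plane it spans, mirroring
the segment-frame convention). Landmarks shared by adjoining segments
(H1, H2, H5, B5, NV) exist once per segment, as on a physical rig built
from separate blocks: 12 unique + 5 duplicated = 17 physical markers.
Duplicates are labeled `"<name>:<box>"` and resolved per requesting
segment through the trajectory's segment→box table — exactly the
disambiguation a mocap labeling session would need.

`simulate_sweep()` rotates one end (toe + plate A, or rearfoot + plate C)
about one anatomical axis through a −90…90° grid in 5° steps, one frame
per position (quasi-static, so sweeps are not low-pass filtered — the
frames are not a time series; an interpolated continuous mode was
considered and rejected as unnecessary for validity analysis). The imposed
plate-relative rotation **is** the ground truth; noise perturbs markers
only, never the truth, and `plate_angles()` recovers the truth from the
noiseless plate markers as the physical protocol defines it. The marker
placements in the shipped YAML are *nominal synthetic coordinates*: the
physical rig's placements were never published, so simulated correlations
characterize the method under ideal rigid geometry, not any particular
apparatus — they should not be read as reproducing a physical experiment's
specific r values. With ideal placement the sweeps validate the pipeline
itself; with `placement_offset_deg` set, the moving segment is mounted
rotated about the sweep axis, which shifts the decomposed angle by exactly
that constant (rotations about a common axis commute), reproducing the
fixed-bias phenomenology of plate-validation studies in its cleanest form.
Mounting offsets about *other* axes produce only approximately constant
differences; the shipped demonstrations use the exact configuration.

What the rig does **not** emulate: skin artifact (soft-tissue motion of
several millimetres on the real foot), camera occlusion and merging,
non-rigid segments, or living-body task waveforms. Passing the simulated
validation therefore shows the mathematics and software are correct under
the rigid-body assumption — it does not bound in-vivo error.

## The agreement battery

`pearson_validity()` gives standard-related validity (r, two-sided p on
n − 2 df). `bland_altman()` reports bias = mean(measured − truth), SD of
differences, limits of agreement bias ± 1.96 SD, and two flags:
**fixed** bias when the 95% CI of the mean difference excludes zero (the
standard criterion; the underlying study only states outcomes), and
**proportional** bias when the OLS slope of differences on pairwise means
is significant at 5%. Differences whose mean or SD is below 1e-9° are
treated as exactly zero so floating-point residue never registers as bias.
`compare_peaks()` is a pooled-variance (Student) unpaired t-test at 5% —
Welch is available via `var_equal = FALSE` — and no multiple-testing
correction is applied, matching common practice in this literature (noted,
not endorsed). `dummy_foot_validity()` ties it together into one tidy
report per model × joint × plane.

## Problem sizes and runtime

The shipped analyses are sized for interactive use: 37-position sweeps per
plane (−90…90° in 5° steps), a 16,900-case Cardan round-trip grid (first
and third angles every 14° over the full circle, middle angle every 7°
inside ±90°), 100 random rigid motions for the equivariance properties,
n = 200 for Bland–Altman parameter recovery and 500 replicates for the
unbiasedness check. The full test suite runs in well under a minute on a
single core.

## Known limitations

* Right-foot convention throughout; left feet must be pre-mirrored.
* No marker gap handling: trajectories must be complete, by design.
* C3D is recognized but not parsed; TRC and wide CSV are the supported
  formats.
* The Met_Hal transverse cell degrades near gimbal positions when large
  frontal offsets combine with ±90° transverse sweeps; the decomposition
  flags those frames rather than hiding them.
* `Ev/Inv` is structurally confined to [−90°, 90°] by the arcsine in the
  decomposition; baseline-subtracted series may exceed it.
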