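# footkin

Marker-based rigid-body kinematics for **multi-segment foot models** in
optical motion capture, with a simulated dummy-foot rig for validity
studies.

Conventional gait models treat the foot as a single rigid segment and miss
the internal motion (pronation/supination, midfoot flexibility) that
matters for foot function. `footkin` implements a three-segment foot model
— hallux, forefoot, rearfoot, plus the shank — whose segment frames are
built from transverse-plane marker triads, together with a variant that
defines the rearfoot in the sagittal plane, and a Rizzoli-style reference
model. It is aimed at movement scientists processing marker trajectories
(TRC/CSV exports) and at anyone validating a marker set against a rigid
reference.

## The model

Each segment frame is constructed from a **long-axis marker pair** and a
**three-marker plane** (e.g. hallux: long axis H1 → P1, plane H1, P1, H5 in
the transverse plane). The long axis is kept exact as the anatomical
primary axis (anterior X for foot segments, superior Y for the shank); the
plane's unit normal, re-orthogonalized against it, supplies the second
axis; the cross product completes a right-handed triad. Joint angles are
the intrinsic **Z-X'-Y'' Cardan decomposition** of the distal segment's
rotation expressed in the proximal frame:

```
R_joint = Rz(Df/Pf) · Rx(Ev/Inv) · Ry(Abd/Add)
```

with dorsi-/plantarflexion about Z, eversion/inversion about X and
abduction/adduction about Y, in degrees. Marker trajectories can be
low-pass filtered with a zero-lag 4th-order Butterworth filter (6 Hz
default), angles are referenced to a static standing baseline, and task
windows are summarized by their peak values.

Validity is assessed the way a physical dummy-foot study does it: three
rigid box segments on reference plates (each carrying markers o, x, z) are
swept through known rotations from −90° to 90° in every plane; the
plate-relative angles are the ground truth, and agreement is quantified by
Pearson correlation plus Bland–Altman bias, limits of agreement and
fixed/proportional bias classification.

## Worked example

```r
library(footkin)

g  <- dummy_geometry()                       # shipped synthetic rig
sw <- simulate_sweep(g, moving_end = "toe", plane = "sagittal")
m  <- register_model("new")
ang <- joint_angles(sw$traj, m, joints = "Met_Hal")$Met_Hal

pearson_validity(ang$angles[, "dfpf"], sw$truth$dfpf)
#> <correlation_result> r = 1.000, p = 0, n = 37

rep <- dummy_foot_validity(models = c("new", "rizzoli"))
head(rep[, c("model", "joint", "plane", "r", "bias", "bias_class")])
#>     model   joint      plane         r          bias bias_class
#> 1     new Met_Hal    frontal 1.0000000  0.000000e+00       none
#> 2     new Met_Hal transverse 1.0000000 -1.992400e-15       none
#> 3     new Met_Hal   sagittal 1.0000000  3.600723e-16       none
#> 4     new Cal_Met    frontal 1.0000000  0.000000e+00       none
#> 5     new Cal_Met transverse 1.0000000  0.000000e+00       none
#> 6     new Cal_Met   sagittal 1.0000000  1.104222e-15       none
```

`r` is the correlation of the computed joint angle against the imposed
plate angle over the 37-position sweep; `bias` is the Bland–Altman mean
difference in degrees and `bias_class` its classification (the Rizzoli
rows of the same report show genuine `fixed` biases of a few degrees,
reflecting its differently aligned reconstructed segment frames). A
deliberate mounting misalignment (`placement_offset_deg`) reproduces the
classic fixed-bias pattern: a constant measured-minus-true offset across
the whole sweep.

For living-body trials, read a TRC/CSV export, then run the pipeline:

```r
cfg <- run_config(model = "new", out_dir = "out")
run_pipeline(cfg, list(
  trial_bundle("static.trc", "static"),
  trial_bundle("dropjump1.trc", "drop_jump")))
```

A thin CLI wraps the same functions
(`inst/exec/footkin simulate|angles|validate|peaks|report`).

## Limitations

Right feet only (mirror left-foot data by negating lab Z before analysis);
no C3D parsing (export TRC or CSV); no skin-artifact simulation, gap
filling or gait-cycle time normalization. The Rizzoli-style frames are
reconstructed from the landmark correspondence table, not taken verbatim
from the original description, and the rig's marker placements are nominal
synthetic coordinates — simulated correlations characterize the method,
not any particular physical rig.
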