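Package: footkin
Title: Multi-Segment Foot Model Kinematics from Optical Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-based rigid-body kinematics for multi-segment foot models.
    Provides a declarative registry of three foot models (a three-segment
    transverse-plane model, its sagittal-rearfoot variant, and a
    Rizzoli-style reference model), segment reference frame construction
    from marker triads, Z-X-Y Cardan angle decomposition of inter-segment
    rotations, zero-lag Butterworth trajectory filtering, static-baseline
    subtraction and task peak extraction. Includes a synthetic dummy-foot
    rig that sweeps rigid box segments on reference plates through known
    rotations to provide ground-truth angles, and the corresponding
    agreement statistics: standard-related validity (Pearson), Bland-Altman
    bias and limits of agreement with fixed/proportional bias
    classification, and unpaired t-tests for peak comparisons. Reads and
    writes TRC and CSV trajectory files and YAML model/geometry
    configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
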