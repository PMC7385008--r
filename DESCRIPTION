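Package: vesselwss
Title: Geometry Consistency and Wall Shear Stress Agreement for Tubular Vessel Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how reproducibly tubular blood-vessel
    geometry, and the wall shear stress quantities computed from it, are
    recovered from paired surface reconstructions of the same vessel.
    Provides a synthetic phantom generator (straight and curved tubes with
    controllable segmentation-like perturbations, flow-direction-dependent
    signal profiles, and pulsatile wall-shear series), centerline extraction
    by the maximal inscribed sphere principle, cross-sectional area profiling
    along the centerline, flow-direction metrics relative to the main field
    axis, time-averaged wall shear stress and oscillatory shear index
    post-processing, laminar pipe-flow oracles (Reynolds number,
    Darcy-Weisbach, Poiseuille), and paired-profile agreement statistics
    (Bland-Altman, normalized summed-difference error metric).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
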