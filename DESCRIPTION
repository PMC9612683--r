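Package: pcs3d
Title: Footprint-Seeded 3D Reconstruction of the Kidney Pelvicalyceal
    System from Non-Contrast CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Semi-autonomous three-dimensional reconstruction of the kidney
    pelvicalyceal system (PCS) from non-contrast computed tomography.
    User-placed circle footprints are refined with an edge-preserving smart
    brush, stone voxels are excluded from the seed density estimate, and the
    lumen is grown slice by slice inside an adaptive Hounsfield-unit band
    (expansion stops at a density increase above 15 HU) before the slices
    are fused into a polygonal surface model that is smoothed, measured and
    checked for 3D printability. Includes a classical global-threshold
    baseline for contrast-enhanced (excretory phase) scans, a synthetic CT
    phantom generator with ground truth for validation without patient
    data, virtual-endoscopy centerline and fly-through extraction, and a
    paired contrast versus non-contrast cohort experiment with
    normality-gated testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
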