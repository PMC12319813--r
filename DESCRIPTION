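Package: qmrinorm
Title: Normative Modelling of Quantitative MRI in Subcortical Grey Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for ROI-based normative
    modelling of quantitative MRI parameters (R1, R2*, magnetic
    susceptibility) in the basal ganglia. Provides MP2RAGE R1 estimation by
    B1-corrected dictionary matching and by lookup-table inversion,
    construction of R1-susceptibility hybrid images with polynomial contrast
    matching, per-ROI summary statistics (median, IQR, skewness), normalised
    volumes and first-order 3D spatial-gradient fits, general linear
    modelling of age, age-squared, sex and hemisphere effects with t-to-z
    conversion, Gaussian-process normative trajectories with cross-validated
    deviation z-scores, deviation-correlation networks, and patient-versus-
    control comparison with Benjamini-Hochberg false-discovery-rate control.
    A seeded synthetic cohort and voxel phantom generator emulating the
    statistical structure of a healthy-ageing qMRI study is included for
    testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    e1071,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
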