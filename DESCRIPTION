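Package: hubfc
Title: Voxel-Wise Hub Functional Connectivity and Long-Axis ROI Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for resting-state fMRI "hub" analysis: BOLD
    preprocessing (initial-volume dropping, linear detrending, zero-phase
    low-pass filtering, nine-parameter nuisance regression, Gaussian spatial
    smoothing, resampling to an isotropic analysis grid), per-subject
    voxel-wise weighted-degree connectivity maps with within-subject
    z-normalization, and group inference by two-sample, paired and
    covariate-regression statistic maps with cluster-forming thresholds and
    permutation max-cluster-size correction. Also provides principal-axis
    subdivision of labeled structures into thirds with group comparison of
    section volumes, a seeded synthetic-cohort generator (4D NIfTI scans,
    nuisance tables, label volumes, pain ratings) for end-to-end testing,
    and cohort bookkeeping with descriptive statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    igraph,
    Matrix,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
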