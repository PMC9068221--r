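Package: nasoplan
Title: Computer-Assisted Trans-Nasal Surgical Corridor Planning on Labeled CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive, discretized five-degree-of-freedom search for
    collision-free cylindrical surgical corridors from the nasal cavity to a
    marked skull-base target (the pre-chiasmatic optic canal) on a segmented
    CT label volume. Provides label-volume input/output (NIfTI and NRRD),
    isotropic resampling, capsule rasterization and exact voxel collision
    checks accelerated by a Euclidean distance-transform clearance map,
    automatic microdrill-size adaptation when no feasible path exists,
    clearance-based path ranking, JSON reporting, corridor overlay export,
    and a seeded synthetic skull-phantom generator for fully reproducible
    testing without CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
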