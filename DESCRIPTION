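Package: fsig
Title: Subgroup Identification from Multi-Subject fMRI via Constrained ICA
    and Gershgorin Discs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies homogeneous subgroups of subjects from multi-subject
    resting-state fMRI activation maps.  Each subject is decomposed separately
    with a constrained independent component analysis based on entropy bound
    minimization (c-EBM), in which spatial resting-state-network templates act
    as inequality constraints that align components across subjects.  The
    aligned components are stacked into source component vectors (SCVs), whose
    across-subject covariance matrices are clustered and aggregated; an
    eigenspectrum rule based on the Gershgorin disc theorem then counts and
    extracts homogeneous subject subgroups.  The package also provides group
    ICA-EBM template generation, model-order and run-consistency diagnostics
    (ISI and cross-ISI), voxelwise two-sample t-maps with false discovery rate
    correction, global difference maps, and a synthetic multi-subject data
    generator with planted subgroup structure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    RNifti,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
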