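Package: amypet
Title: Amyloid PET Centiloid Quantification and Z-Score Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standalone pipeline for quantitative analysis of brain amyloid
    PET. Computes the global Centiloid (CL) scale from PET and T1-weighted MRI
    volume pairs for the five amyloid tracers (11C-PiB, 18F-florbetapir,
    18F-flutemetamol, 18F-florbetaben, 18F-NAV4694) via reference-region SUVR
    and published tracer-specific linear conversions, and detects statistically
    significant local amyloid accumulation by voxelwise Z-score mapping against
    a normative database of amyloid-negative controls, with cluster-extent
    thresholding and five-region positivity calls. Includes rigid/affine
    NMI-based registration to template space, application of externally
    computed deformation fields, chi-square agreement testing between tracers,
    ROC derivation of CL cutoffs, and a synthetic phantom generator so the
    whole pipeline is testable without external image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    png,
    yaml,
    optparse,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
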