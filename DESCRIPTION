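Package: lymphopatch
Title: Hierarchical Patch-Based Classification of Lymphoma Histopathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based classification of H&E-stained non-Hodgkin lymphoma
    histopathology images into the CLL, FL and MCL subtypes. Images are
    transformed into blue-ratio gray space (emphasising nuclear signal) and
    CIE Lab color space; uniform local binary pattern texture histograms,
    gray-level statistics and Lab color histograms are extracted over a
    two-level parent-patch/subpatch hierarchy and classified with a random
    forest. Patch scores are aggregated to image-level predictions by
    majority voting, mean score, or distance-matrix weighting (DMW), in
    which each patch is weighted inversely to its mean feature-space
    distance from the other patches of the same image. Multiple feature
    paths (including a pluggable deep-embedding path) are fused at patch
    and image level. A seeded synthetic H&E-like image generator makes the
    whole pipeline testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    pROC,
    png,
    tiff,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
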