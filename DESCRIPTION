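Package: virtrater
Title: Virtual Raters for Reproducible Volumetric Assessment of Brain Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the virtual-rater protocol for reproducible volumetric
    assessment of brain tumors in multi-channel MRI: a multi-scale voxel
    feature bank, a sparse-scribble random-forest ensemble classifier with a
    fixed post-processing chain (probability smoothing, argmax, small-component
    removal), pooling of historical annotations from multiple human raters
    with the current rater's annotations, multi-category STAPLE consensus
    fusion, and a full agreement and response-assessment metric suite (Dice,
    Pearson, one-way ICC, Fisher's method, volumetry, longitudinal GTV change
    and RANO-style bidimensional measurement). A synthetic multi-channel MRI
    phantom generator with simulated imperfect raters makes the whole pipeline
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    randomForest,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
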