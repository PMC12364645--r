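Package: qontour
Title: Quantum and Quantum-Inspired Contouring Algorithms for Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classically simulated implementations of three quantum contouring
    approaches for grayscale medical images: a self-supervised quantum-inspired
    qutrit fuzzy segmentation network (QIS-Net), Grover amplitude amplification
    over an NAQSS-encoded image with externally marked states, and QCuts
    graph-energy segmentation solved by eigen-decomposition in place of a
    quantum annealer. Includes synthetic abdominal phantoms with ground-truth
    liver masks and corrupted marker masks, shared post-processing (largest
    connected component, hole filling, multi-level Otsu thresholding),
    Dice/Hausdorff evaluation, quantum-resource accounting, and a cohort
    comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    igraph,
    jsonlite,
    stats,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
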