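Package: mitoscale
Title: Mitotic Chromosome Loop-Layer Architecture from Hi-C and 3D Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies mitotic chromosome organization from Hi-C contact data
    and 3D fluorescence microscopy. Computes genome-wide contact probability
    decay curves P(s) with iterative matrix balancing, estimates average
    chromatin loop size and loop-layer size from the smoothed log-log
    derivative of P(s), and simulates contact maps with a three-regime
    rod-chromosome decay model with known ground truth. For imaging, provides
    Otsu segmentation, per-cluster immunofluorescence quantification, 3D
    surface-area measurement of chromosome masses, centromere (CENP-A) focus
    counting with an individualization classifier, a synthetic 3D stack
    generator with analytic ground truth, and the grouped two-tier statistics
    (replicate-median normalization, Mann-Whitney U, t-test on replicate
    medians) used to compare depletion conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
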