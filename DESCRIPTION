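Package: stenoselect
Title: Diversity-Controlled Hybrid Metaheuristic Feature Selection for
    Coronary Stenosis Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Wrapper feature selection for binary coronary-stenosis
    classification from X-ray angiogram patches, built around a hybrid
    metaheuristic that couples the Boltzmann Univariate Marginal
    Distribution Algorithm (BUMDA) with simulated annealing refinement and
    an explicit population-diversity control rule.  Includes the
    supporting angiographic feature bank (intensity statistics, gray-level
    co-occurrence Haralick textures, eight vessel-enhancement filters with
    segmentation and skeleton-based morphology), a support vector machine
    wrapper-fitness evaluator, confusion-matrix performance metrics,
    synthetic generators for feature tables and vessel-like image patches,
    PGM image input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
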