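Package: hydrophylo
Title: Leaf Hydraulic Traits from Optical and Drydown Assays with
    Phylogenetic Comparative Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts leaf hydraulic traits from raw measurement series and
    relates them to climate across species on a phylogeny. Implements the
    optical vulnerability method (time-lapse image differencing, cavitation
    event detection, vulnerability curves and the water potential at 50%
    embolism, P50), estimation of minimum shoot conductance (g_min) from
    branch drydown mass series via the Buck saturation vapour pressure
    equation, and segmented (breakpoint) regression of g_min against
    temperature to locate the cuticular phase-transition temperature (T_P).
    Comparative statistics include Blomberg's K with a permutation test,
    Pagel's lambda by maximum likelihood, phylogenetic generalized least
    squares with influence diagnostics, climate principal component
    analysis, and Loess smoothing. A synthetic-data generator produces
    image stacks, mass series, trees, traits and climate tables with known
    ground truth so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    picante,
    nlme,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
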