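Package: CCvoid
Title: Choriocapillaris Flow-Void Quantification from Averaged En Face OCTA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the choriocapillaris on en face optical coherence
    tomography angiography (OCTA). Repeated en face frames are quality-gated,
    registered by phase correlation driven by the superficial capillary plexus,
    and averaged; the averaged choriocapillaris image is binarized with the
    Phansalkar local adaptive threshold; flow voids are counted and measured
    (count, total area, mean size) and the vessel diameter index (total vessel
    area over skeleton length) is computed outside major retinal vessels and
    the foveal avascular zone. A synthetic-data module generates ground-truth
    capillary meshworks, degraded frame stacks, and statistical twin cohorts so
    that every stage is testable without proprietary device exports, and a
    cohort-statistics layer provides Pearson and age-adjusted partial
    correlations, Levene-gated t tests, age-group summaries, and per-year
    trend slopes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    igraph,
    car,
    withr,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
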