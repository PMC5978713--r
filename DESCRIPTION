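Package: jawsearch
Title: Automated Search for Optimal VMAT X-Jaw Settings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid search over X-jaw apertures for volumetric modulated arc
    therapy (VMAT) planning. Builds a candidate grid of jaw settings from a
    conformal baseline, obtains per-plan cumulative dose-volume histograms
    (DVHs) from a pluggable dose engine (a parametric synthetic surrogate is
    shipped), normalizes plans to prescription coverage, excludes plans with
    unacceptable hotspots, scores organ-at-risk sparing with a
    cohort-normalized mean/high dose-volume-product (MDVP/HDVP) score, and
    ranks and compares candidate plans. Includes DVH algebra (resampling,
    dose/volume queries, normalization), plain-text DVH and heat-map
    serialization, a knowledge-based-planning prediction stub, and paired
    dosimetric endpoint comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
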