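Package: psiplace
Title: Accuracy Assessment of Patient-Specific Surgical Guide Placement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric and statistical pipeline for assessing the placement
    accuracy of patient-specific instruments (PSIs) used to guide pelvic
    osteotomies. Provides rigid paired-point (Horn/Kabsch) registration with
    iterative closest point (ICP) surface refinement, estimation of the
    planned-to-actual guide transform from pinhole fiducials, plane-mesh
    cross-section extraction, the maximum osteotomy deviation (MOD) statistic,
    a synthetic hemipelvis phantom and placement-error simulator emulating
    freehand versus augmented-reality guided placement on conventional and
    soft-tissue-coated phantoms, and Kruskal-Wallis / Dunn post-hoc analysis
    of the resulting deviations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
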