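Package: habvuln
Title: Climate-Change Vulnerability Assessment of Species Habitat from
    Presence-Background Suitability Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for assessing the vulnerability of species
    habitat to climate change on a common equal-area raster grid: a
    presence-background maximum-entropy suitability model with linear,
    quadratic and hinge features fitted by L1-penalized coordinate descent;
    occurrence thinning and target-group background sampling; correlation and
    permutation-importance variable screening; replicated 75/25 evaluation with
    AUC and the maximum sensitivity-plus-specificity threshold; binary habitat
    mapping with minimum-area and isolation patch filtering; a four-category
    habitat-change classification with area-change and habitat-shift
    indicators; Mann-Whitney elevation contrasts; and protected-area gap
    analysis against reserve polygons. A seed-reproducible synthetic landscape
    generator provides spatially autocorrelated climate surfaces, future
    scenarios, occurrences drawn from a known true suitability surface and
    reserve polygons, so that the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    sp,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
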