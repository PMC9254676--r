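Package: underpassr
Title: Camera-Trap Analysis of Wildlife Road Underpass Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing camera-trap monitoring of wildlife road
    underpasses against forest reference sites. Collates raw camera records
    into independent passes (30-minute separation rule, paired-end
    deduplication), builds weekly detection histories with missing occasions,
    fits and ranks single-season detection-probability models (null,
    underpass-vs-forest, patchy, with an optional season covariate) by
    maximum likelihood and small-sample corrected AIC, and tests the
    prey-trap hypothesis with an exact one-tailed binomial test of nightly
    predator-prey co-detection independence. Includes a seeded synthetic
    camera-trap data generator with tunable nightly predator-prey dependence
    so every stage can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
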