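Package: pollendiet
Title: Pollen-Load Diet Analysis and Host-Range Classification for Wild Bees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies scopal pollen loads of wild bees into volume-weighted
    diet profiles, classifies each bee species' host range (lecty) under the
    dual volume-based and pure-load oligolecty criteria, standardises diet
    breadth across unequal sample sizes by integer-transform rarefaction
    without replacement, and relates diet breadth to frequency of occurrence
    across farms. Includes a synthetic foraging-data generator with known
    ground truth for parameter-recovery experiments, and reference fixtures
    from a published survey of farmland solitary bees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
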