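Package: rivermacro
Title: Bacterial Macroecology Along Continental River Transects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for bacterial macroecological dynamics along
    large rivers sampled as downstream-ordered transects. Converts bulk
    bacterial secondary production, total cell counts and mean cell volumes
    into per-cell production, division rates, doubling times, cumulative
    doubling events and whole-river cell production; partitions beta
    diversity into turnover (Simpson) and nestedness components along a
    water-travel-time axis; fits the associated trend models (ordinary least
    squares with adjusted R-squared, backward model selection, ordination
    with environmental vector fitting, discharge-ratio richness models); and
    estimates phylotype-level growth from penalized-spline smoothers and
    their derivatives. A synthetic river-transect generator with fully known
    ground truth exercises every stage without access to survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
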