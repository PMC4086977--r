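Package: grazefd
Title: Functional Traits, Productivity and Resilience of Grazed Grasslands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trait-based analysis of secondary (livestock)
    productivity in grazed grasslands. Computes community-weighted means,
    Rao's quadratic entropy and functional evenness (FEve) from mixed-type
    species trait tables via weighted Gower dissimilarities; fits
    hierarchical mixed models of productivity on an exponential-decay
    transform of community leaf dry matter content and growing-season
    weather, with ML/REML model simplification; tests whether functional
    diversity predicts the mean of productivity (forward selection) or its
    variability (absolute-residual regression with adjusted degrees of
    freedom); and generates seeded synthetic grazing-experiment datasets
    with known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    minpack.lm
Config/testthat/edition: 3
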