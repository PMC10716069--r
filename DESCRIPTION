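Package: confignav
Title: Psychometrics of Configural Spatial Knowledge Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-level scoring and psychometric analysis of the two standard
    measures of configural (survey) spatial knowledge: absolute pointing error
    from judgments of relative direction, and travel efficiency (traveled path
    length over shortest traversable path length) from route-based shortcutting.
    Provides metric maze graphs with shortest-path oracles and learned-route
    efficiency constants, exclusion and imputation rules for failed shortcutting
    trials, permutation-based split-half internal consistency with
    Spearman-Brown correction, correction for attenuation of between-measure
    correlations, comparison of independent correlations (Fisher z, Zou
    confidence interval), k-means ability clustering with silhouette-based model
    selection, group descriptives and one-sample inference against chance-level
    pointing (90 degrees) and learned-route efficiency, and a synthetic cohort
    generator with known ground truth (two latent ability clusters, a uniform
    guessing floor for pointing, and a ceiling at perfect efficiency) so every
    stage of the pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    e1071,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
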