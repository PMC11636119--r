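Package: sandstab
Title: Community Stability and Diversity Analysis for Sandy-Land Shrub Restoration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis of plant community recovery along a
    restoration chronosequence on alpine sandy land: species importance
    values, alpha-diversity indices (Margalef, Simpson, Shannon-Wiener,
    Pielou), and a coverage-based M. Godron community-stability
    measurement in which a cumulative rank-coverage curve is fitted with
    a smooth polynomial, intersected with the anti-diagonal, and scored
    by Euclidean distance to the 20/80 stability point. Includes
    stratified soil-nutrient summaries, percent-change-vs-control
    computations, and a seeded generator of synthetic quadrat and soil
    tables for testing every pipeline stage without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
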