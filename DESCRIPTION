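Package: novafopl
Title: Front-of-Package Traffic-Light Scoring and NOVA Processing-Group Analysis of Food Composition Databanks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores food-composition databanks against the UK front-of-package
    multiple-traffic-light (MTL) nutrient criteria for fat, saturated fat, total
    sugar and salt, classifies items as hyper-palatable from macronutrient energy
    fractions and sodium content, and compares outcomes across NOVA food-processing
    groups (minimally processed foods, processed culinary ingredients, processed
    foods, ultra-processed foods). Provides 2x2 odds ratios with Woolf intervals,
    binary and proportional-odds logistic regression, rank-based group tests with
    Bonferroni-corrected Dunn pairwise comparisons, a full study pipeline with
    healthy-subset stratification, and generators for synthetic databanks and
    deterministic contingency-count fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
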