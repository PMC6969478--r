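Package: gzmorph
Title: Growth-Zone Morphometrics and Cell-Cycle Dynamics for Sequentially
    Segmenting Arthropod Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of posterior elongation in anostracan
    crustacean larvae (Thamnocephalus-type anamorphic development): a
    synthetic staged-larva generator producing 2D ventral nucleus fields,
    morphometric measurement of the growth zone and trunk (linear, area and
    cell-count measures), mitosis and spindle-orientation statistics,
    EdU S-phase domain detection along the body axis, a growth-zone
    division-budget model, and cohort-level staging statistics
    (segment-addition rate, tagma grouping, PCA, permutation group tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
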