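Package: subchondral
Title: Quantitative Histomorphometry of Subchondral Bone in Osteoarthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies osteoarthritic changes in subchondral bone from 2D
    histology sections. Segments the bone-cartilage interface (BCI) from a
    thick hand-drawn band into a thin (about three pixel) interface mask,
    derives per-pixel local orientations with a local binary pattern (LBP)
    method, and summarises interface disorder with the Shannon entropy of
    local angles and the homogeneity of an angle-level co-occurrence matrix
    (ALCM). Also measures uncalcified cartilage, calcified cartilage and
    subchondral plate thickness at evenly distributed random points, and
    provides the grading statistics used to relate a four-stage subchondral
    bone grade to OARSI cartilage grade: intraclass correlation for rater
    consistency, one-way ANOVA with Tukey post hoc tests, Welch t-tests and
    linear regression. A synthetic-phantom generator produces layered
    osteochondral sections and study tables with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
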