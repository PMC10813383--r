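Package: nglycoda
Title: Compositional Analysis of Serum N-Glycome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the statistical analysis of serum N-glycome profiles
    measured as 46 chromatographic glycan peaks expressed as percentages of
    total integrated area.  Implements compositional data analysis on the
    simplex (closure, multiplicative zero replacement, clr and ilr pivot
    coordinates), derived glycosylation traits (galactosylation, sialylation,
    branching, fucosylation and oligomannose groups), permutation-calibrated
    global two-sample tests with per-coordinate follow-up and false discovery
    rate control, penalized-spline age-trend models per sex with
    back-transformation to the percentage scale, beta-response smooths for
    bounded traits, robust principal component analysis, K-means clustering
    with elbow selection, cluster phenotyping tables and covariate-adjusted
    outcome models.  A synthetic cohort generator with known ground truth
    supports method validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
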