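Package: frondsym
Title: Frond Outline Morphometrics and Continuous Symmetry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures size and bilateral symmetry of duckweed (Lemna) fronds
    from photographs and relates offspring morphology to parental age. Images
    are segmented by Otsu thresholding of the inverse blue channel, cleaned to
    a single hole-free component, contour-traced, and resampled to equally
    spaced outline reference points. From the outline the package computes
    area, perimeter, circularity, the Continuous Symmetry Measure (CSM) of
    bilateral symmetry, and a variant (CSM_forced) whose reflection axis is
    constrained through the outline point farthest from the centroid. A
    two-stage AICc model-selection workflow (random-effects structure first,
    then a dredge over parental-age polynomials crossed with a shelf effect)
    and a binomial exclusion analysis mirror the statistical protocol, and a
    synthetic frond/cohort generator makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    nlme,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
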