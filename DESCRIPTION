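Package: convexgsca
Title: Convex Generalized Structured Component Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimation of path-analytic models among components (weighted
    composites of observed indicators) where components may be convex
    combinations of unstandardized indicators, so that component scores,
    means and standard deviations stay on the indicators' original
    measurement scale. Fits the convex variant of generalized structured
    component analysis by alternating least squares under sum-to-one (and
    optionally non-negative) weight constraints, alongside the classic
    standardized variant, directly from raw data or from printed means and
    covariances. Provides weighted explained-variance fit indexes for
    unstandardized dependent variables, covariance-discrepancy indexes
    (GFI, SRMR), bootstrap standard errors and percentile confidence
    intervals, out-of-bag prediction error for model comparison, and a
    Monte-Carlo engine for parameter-recovery studies with normal or
    skewed/kurtotic indicators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
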