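Package: linetrend
Title: Summary-Measure, Multivariate, and Mixed-Model Analysis of Linear Trend Repeated Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing repeated-measures data whose subject profiles
    follow a linear trend. Implements the summary-measure approach (per-subject
    least-squares slopes and means with t, ANOVA, rank-based and permutation
    tests of time, group and group-by-time effects), the unstructured
    multivariate approach (profile-analysis parallelism via Wilks' lambda and a
    one-sample Hotelling T-squared time test on adjacent differences), and REML
    linear mixed models with independent, first-order autoregressive or
    unstructured within-subject error covariance, compared via AIC/BIC and
    Wald F tests with inner-outer denominator degrees of freedom. A Monte
    Carlo engine simulates linear-trend mixed-model data under the three error
    structures and estimates empirical type-I error rates and power for all
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nlme,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
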