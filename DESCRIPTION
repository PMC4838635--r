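Package: pmlfa
Title: Pairwise Maximum Likelihood Factor Analysis of Ordinal Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of confirmatory factor models for ordinal item
    responses under the underlying-multivariate-normal assumption by
    pairwise maximum likelihood (PML), a composite-likelihood method that
    maximizes the sum of all bivariate log-likelihoods instead of the
    intractable full-pattern likelihood.  Provides three likelihood-ratio
    goodness-of-fit statistics for PML-fitted models (a full-pattern
    statistic, a statistic against the unrestricted underlying-normality
    model, and a Bonferroni-protected maximum over pairwise statistics),
    a synthetic ordinal data generator that discretizes multivariate
    normal scores at fixed thresholds, and a Monte Carlo harness for
    calibration (type I error) and power studies of the fit statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mvtnorm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
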