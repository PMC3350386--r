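Package: psival
Title: Empirical Validation Toolkit for Hospital Patient Safety Indicators
Version: 0.1.0
Authors@R:
    person("Iris", "Salmeron", email = "iris.salmeron@example.org",
           role = c("aut", "cre"))
Description: Tools to assess the empirical properties of Patient Safety
    Indicators (PSI) computed from administrative hospital-discharge data.
    Implements indirect standardization of per-hospital incidence, percentile
    ratios of variation, the Empirical Bayes systematic-variation statistic
    from a hierarchical Poisson-lognormal model with cluster-bootstrap
    percentile intervals, two-level random-intercept logistic models with the
    latent-variable intraclass correlation (rho) and Median Odds Ratio, and
    empirical-Bayes shrunken residuals for flagging hospitals above or below
    the expected rate.  A synthetic discharge-data generator with recorded
    ground truth supports parameter-recovery and operating-characteristic
    studies, and a single run configuration drives the full pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
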