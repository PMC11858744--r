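Package: viscoweber
Title: Weber Fractions and Perceptual Bias from 2AFC Viscosity Discrimination
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for two-alternative forced-choice (2AFC)
    viscosity discrimination experiments run with the method of constant
    stimuli. Fits a log-domain error-function psychometric model
    parameterized directly by the Weber fraction via constrained maximum
    likelihood, extracts just-noticeable differences (JND) and points of
    subjective equality (PSE), and quantifies uncertainty with a
    participant-resampling percentile bootstrap including difference and
    bias tests with Bonferroni correction. Ships a synthetic 2AFC observer
    generator with appearance-dependent perceived-viscosity bias, lapse and
    subject heterogeneity, per-subject rank-based robustness checks
    (Mann-Whitney U, Wilcoxon signed-rank), and a reproducible
    simulate/fit/bootstrap/compare/report command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
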