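Package: emobias
Title: Psychometric Analysis of Perceptual Bias for Emotional Faces
Version: 0.1.0
Authors@R:
    person("emobias", "maintainers", email = "emobias@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing two-alternative forced-choice judgments of
    emotional face morphs in studies of social anxiety and state affect.
    Provides trial-level quality control with an auditable exclusion ledger,
    maximum-likelihood fitting of cumulative-normal psychometric functions
    yielding each participant's point of subjective equality (PSE) and slope,
    group comparisons (variance-screened t-tests, Cohen's d, normality
    screens), two-step moderation regression with heteroscedasticity-
    consistent standard errors and simple slopes, and a synthetic-observer
    cohort generator with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
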