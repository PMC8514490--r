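Package: lpchoice
Title: Learning-Progress-Driven Choice Modeling for Free-Choice Learning Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing how learners allocate effort among competing
    learning activities in free-choice experiments. Computes dynamic
    percent-correct (PC) and learning-progress (LP) signals from trial-level
    records, fits softmax intrinsic-utility choice models (bivariate PC+LP,
    univariate reductions, and a uniform-random baseline) by multi-start
    bounded maximum likelihood, compares models by AIC, derives behavioral
    indices (self-challenge, difficulty-weighted final performance, mastery
    counts), classifies PC-driven versus LP-driven choice strategies, and
    forward-simulates time allocation from fitted coefficients. A built-in
    synthetic-cohort generator produces trial data from known parameters for
    parameter-recovery and end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
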