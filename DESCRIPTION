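Package: symtraj
Title: Group-Based Trajectory Modeling of Longitudinal Symptom Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies latent subgroups of patients who share similar
    longitudinal patterns of patient-reported symptom burden, using a
    censored-normal (CNORM) finite mixture of polynomial trajectories
    fitted by maximum likelihood.  Provides preprocessing of Edmonton
    Symptom Assessment System (ESAS) assessments into a Box-Cox
    transformed total symptom distress score (TSDS), an iterative
    group-number and polynomial-order model-selection procedure based on
    the Bayesian information criterion and the log Bayes factor,
    posterior classification adequacy diagnostics (average posterior
    probability, odds of correct classification), time-varying covariate
    adjustment, multinomial membership regression, sensitivity analyses,
    and a synthetic-cohort generator that reproduces the data pathologies
    the preprocessing rules target.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
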