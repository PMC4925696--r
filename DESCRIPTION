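Package: valsplitrl
Title: Valence-Split Reinforcement Learning Models for Probabilistic
    Feedback Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a probabilistic category-learning task that dissociates
    learning from positive and negative feedback (four stimuli, 80/20 category
    contingencies, four blocks of forty trials, +25/0/-25 point feedback by
    stimulus valence, with a post-task point top-up rule), and fits
    trial-by-trial choice data with a family of reinforcement-learning models:
    Q-learning, a valence-split actor-only learner, and actor-critic variants
    with separate learning rates for positive and negative prediction errors
    and a softmax choice rule with noise and perseveration parameters. Provides
    per-subject maximum-likelihood estimation with multi-restart bounded
    optimization, model comparison by negative log-likelihood and BIC, random-
    effects Bayesian model selection with expected posterior and exceedance
    probabilities, synthetic clinical cohorts (generalized anxiety, social
    anxiety, panic disorder, healthy controls) with group-specific parameter
    distributions, parameter-recovery diagnostics, and descriptive behavioral
    metrics (optimal-response proportions by block and valence, chance tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
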