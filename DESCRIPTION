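Package: norminfer
Title: Bayesian Models of Group-Norm Inference from Observed Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ideal-observer models of how people infer latent group norms
    from the behavior of group members: a single-step Bayes update, three
    causal Bayesian networks over norms, desires and actions (independent
    effects, fully connected, desire mediation), and a frequency-tracking
    baseline. Belief updating is indexed by the Kullback-Leibler divergence
    between two-point prior and posterior belief distributions. The package
    links model-derived posteriors to judgmental posteriors with Bayesian
    hierarchical linear regression (random intercepts and slopes per
    participant, optionally per condition), compares candidate models with
    Pareto-smoothed importance-sampling leave-one-out cross-validation
    (LOOIC), and provides the descriptive layer of repeated-measures ANOVA
    with Greenhouse-Geisser correction, Bonferroni-corrected t tests and
    Cohen's d. A synthetic-observer generator emulates the three slider
    experiment designs so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
RoxygenNote: 7.3.3
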