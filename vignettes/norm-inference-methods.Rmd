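---
title: "Methods: Bayesian inference of group norms from observed behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian inference of group norms from observed behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(norminfer)
```

## The scientific question

When people watch members of a group behave, how do they decide whether the
group has a shared (injunctive) norm? `norminfer` implements a family of
ideal-observer accounts of this inference and the full statistical pipeline
used to compare them against human-style slider judgments: a synthetic
observer generator, exact probabilistic inference for each candidate model,
Bayesian hierarchical regression of judgments on model predictions,
leave-one-out model comparison, and a classical repeated-measures
descriptive layer.

## The cognitive models

### Single-step Bayes update

The core model treats norm existence as a binary hypothesis $N$ and an
observed action $A$ (norm-consistent or deviant). Given a judgmental prior
$P(N)$ and elicited likelihoods $P(A \mid N)$ and $P(A \mid \neg N)$, the
posterior is

$$
P(N \mid A) \;=\;
\frac{P(N)\,P(A \mid N)}
     {P(N)\,P(A \mid N) + P(\neg N)\,P(A \mid \neg N)},
$$

implemented by `bayes_posterior()`. Belief updating is indexed by the
Kullback–Leibler divergence between the two-point posterior and prior
distributions,

$$
D_{\mathrm{KL}} \;=\;
p \log\frac{p}{q} + (1-p)\log\frac{1-p}{1-q},
$$

in nats (`kl_update()`), with $p$ the posterior and $q$ the prior
probability of $N$.

### Causal Bayesian networks

When the actor's desire $D$ is also in play, three causal structures over
$(N, D, A)$ are candidate explanations of the same action:

* **IE** (independent effects): $N \rightarrow A \leftarrow D$, with $D$
  marginally independent of $N$;
* **FC** (fully connected): $N \rightarrow D$, $N \rightarrow A$,
  $D \rightarrow A$;
* **DM** (desire mediation): $N \rightarrow D \rightarrow A$, so the norm
  influences the action only through the desire.

`network_spec()` validates a conditional-probability-table (CPT)
parameterization for a given structure, and `network_posterior()` /
`desire_posterior()` return $P(N \mid A)$ and $P(D \mid A)$ by exact
inference. Because the networks are tiny, inference is done in closed form
by collapsing over the unobserved variable; the test suite checks this
algebra against an independent brute-force enumeration of the full joint
table at $10^{-12}$ on a thousand random CPTs.

### Frequency tracking

The non-Bayesian baseline (`frequency_estimate()`) predicts judgments from
the observed proportion of norm-consistent actors alone, $k/n$, with no
integration of the prior.

## Synthetic observers

`experiment_design()` encodes the three slider-experiment layouts:

* Experiment 1: 32 participants, 8 trials per condition, conditions are the
  number of norm-consistent agents among 4 (1–4);
* Experiments 2 and 3: 12 trials per condition, conditions are
  norm-consistent proportions 0.25, 0.5, 0.75, 1; Experiment 3 additionally
  elicits desire judgments and the full set of network conditionals.

`generate_experiment()` simulates observers who hold one *generating joint
distribution* over $(N, D, A)$ — built from a documented default CPT
(`default_true_cpt()`) or a user-supplied one — and report probabilities on
a 0–1 slider with step 0.01. All elicited quantities, including the
conditionals used to parameterize every candidate network, are conditionals
of that single joint. This matters: it makes model recovery well-posed,
because the models differ only in structure, not in which underlying
observer produced the numbers.

Response noise is truncated-normal on $[0,1]$ (inverse-CDF construction,
`sigma_response = 0.05` by default) followed by rounding to the slider
grid. Two deliberate simplifications relative to human data: when
`sigma_response = 0` responses are reported *exactly* (no grid rounding),
so noise-free ideal observers are recoverable to machine precision; and
observers have no sequential or memory effects — each trial is an
independent draw. The generator therefore emulates the designs' structure
and noise scale, not response biases such as slider anchoring.

## Hierarchical regression

Judgmental posteriors are regressed on model-derived posteriors with a
Gaussian hierarchical linear model: fixed intercept and slope, plus random
intercepts and slopes per participant, and optionally per condition
(`fit_hierarchical(..., condition_random = TRUE)`, the stricter variant
that absorbs condition-level structure). Priors are weakly informative —
Normal(0, 2.5) on the fixed effects (both variables live on $[0,1]$) and
half-Normal(0, 1) on every standard deviation. Sampling is Gibbs via JAGS.

Three numerical choices matter for mixing and are worth stating:

* **Predictor centering.** $x$ is centered internally before sampling and
  draws are transformed back afterwards; with $x$ confined to a narrow
  band, the raw intercept and slope are nearly collinear and unmixed.
* **Hierarchical centering.** Participant coefficients are drawn around the
  population coefficients in the participant-only model. In the condition
  variant the *condition* effects are the ones centered on the fixed
  effects: with only four condition levels and potentially large
  between-condition variance, a zero-mean parameterization leaves the
  fixed effects and the condition means strongly anticorrelated and the
  sampler mixes an order of magnitude more slowly.
* **Uncorrelated random effects.** Random intercepts and slopes are given
  independent priors rather than a correlated multivariate prior. This is
  a simplification (a full LKJ-style covariance prior is not convenient in
  JAGS); for the recovery regimes exercised here the correlation is not
  identified strongly enough to change the slope inference.

Convergence is monitored with a hand-computed split-half $\widehat{R}$
(`split_rhat()`: each chain is split in half and the classic
between/within-variance formula applied); fits warn above 1.05 rather than
erroring, so test-scale runs surface their own diagnostics. Defaults are 2
chains × 2000 iterations (500 warmup) for test-scale work; full-scale
analyses should use more (e.g. 2 × 10⁴ with 2000 warmup).

The standardized effect size $\delta_t$ (`delta_t()`) is the slope divided
by the square root of the sum of all variance components; by default the
ratio is computed per posterior draw and averaged, with a `"means"` method
forming the ratio of posterior means instead.

## Model comparison

`psis_loo()` implements Pareto-smoothed importance-sampling leave-one-out
cross-validation from a draws × observations pointwise log-likelihood
matrix: the importance ratios' upper tail (of size
$\lceil \min(0.2S, 3\sqrt{S}) \rceil$ for $S$ draws) is replaced by
quantiles of a generalized Pareto distribution fitted by the
Zhang–Stephens profile-likelihood method with the standard shrinkage
regularization, and smoothed weights are capped at the raw maximum. The
tail-shape diagnostic $k$ is reported per observation. `compare_loo()`
ranks models by LOOIC $= -2 \cdot \widehat{\mathrm{elpd}}$, with
differences from the best model; ties preserve input order. The suite
validates the estimator against exact refit LOO on a conjugate Gaussian
problem.

## Frequentist descriptive layer

`rm_anova()` computes the one-way within-subject ANOVA from first-principles
sums of squares, with Greenhouse–Geisser correction applied when Mauchly's
test rejects sphericity (the `"auto"` policy), and partial $\eta^2$ as
$SS_{\text{effect}} / (SS_{\text{effect}} + SS_{\text{error}})$. A caution
established during development: the GG-corrected $p$ is only guaranteed to
exceed the uncorrected $p$ when $F$ is clearly above 1; for pure-noise data
the correction can lower $p$. `paired_posthoc()` runs Bonferroni-corrected
paired $t$ tests (Cohen's $d$ uses the average-sd denominator), and
`one_sample_t()` tests priors against 0.5 and updating scores against 0.

## Belief-updating index

$D_{\mathrm{KL}}$ is computed *per trial* from that trial's prior and
posterior report and then averaged within participant × condition
(`add_kl_rows()`, `aggregate_by_condition()`), rather than from averaged
beliefs; the divergence is convex, so the two orders differ, and the
per-trial order is the one that treats each judgment as a belief state.
Probabilities are clipped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-6}$ before logarithms, so slider endpoints (0 and 1)
produce large but finite divergences.

## The pipeline

`run_config()` + `run_experiment()` chain the stages — simulate (or ingest
via `read_trials()`), per-trial updating, aggregation, ANOVA and post-hoc
layer, per-model hierarchical regressions in both variants, and the LOO
comparison table — writing a CSV bundle and run log when an output
directory is given. `read_run_config()` reads the same configuration from
YAML, and `inst/scripts/norminfer-cli.R` exposes `simulate` and `run-exp`
subcommands.

## Limitations

* Synthetic observers are idealized: no anchoring, drift, lapses, or
  individual differences in the generating joint beyond response noise.
* The regression assumes Gaussian residuals on the probability scale;
  judgments near the slider bounds mildly violate this.
* Random-effect correlations are not modeled (see above).
* Exact network inference covers binary $(N, D, A)$ only; larger state
  spaces would need a general inference engine.
* MCMC defaults are sized for test-scale runs; production analyses should
  increase iterations and chains and check $\widehat{R}$.
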