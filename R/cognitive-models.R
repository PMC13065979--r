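#' Single-step Bayes update for the existence of a group norm
#'
#' Computes the posterior probability that a latent group norm N exists after
#' observing the group's behavior A, from a prior P(N) and the two elicited
#' likelihoods:
#' \deqn{P(N|A) = \frac{P(N)\,P(A|N)}{P(N)\,P(A|N) + P(\neg N)\,P(A|\neg N)}}
#' with \eqn{P(\neg N) = 1 - P(N)} (never stored separately).
#'
#' @param p_n prior probability that the norm exists.
#' @param p_a_given_n probability of the observed behaviors given the norm
#'   exists.
#' @param p_a_given_notn probability of the observed behaviors given the norm
#'   does not exist.
#' @param eps clipping bound applied before forming the ratio (sliders permit
#'   0 and 1).
#' @return posterior probability `P(N|A)`, vectorized over the inputs.
#' @examples
#' bayes_posterior(0.5, 0.9, 0.3)  # 0.75
#' @export
bayes_posterior <- function(p_n, p_a_given_n, p_a_given_notn, eps = 1e-6) {
  assert_prob(p_n); assert_prob(p_a_given_n); assert_prob(p_a_given_notn)
  p_n <- clip_prob(p_n, eps)
  num <- p_n * p_a_given_n
  den <- num + (1 - p_n) * p_a_given_notn
  if (any(den <= 0))
    stop("degenerate evidence: P(N)P(A|N) + P(not N)P(A|not N) is zero",
         call. = FALSE)
  num / den
}

#' Kullback-Leibler divergence of a two-point belief update
#'
#' Belief about the existence of a norm is a two-point distribution
#' \{P, 1 - P\}. The degree of belief updating from prior q to posterior p is
#' \deqn{D_{KL}(p \| q) = \sum_i p(x_i)\,(\log p(x_i) - \log q(x_i))}
#' in nats (natural logarithm). Both probabilities are clipped to
#' `[eps, 1 - eps]` before taking logs, so a slider response of exactly 0 or
#' 1 yields a large finite divergence rather than infinity.
#'
#' @param prior,posterior probabilities of norm existence before and after
#'   observation; vectorized.
#' @param eps clipping bound.
#' @return divergence in nats, `>= 0`, `0` iff prior equals posterior after
#'   clipping.
#' @examples
#' kl_update(0.5, 0.75)  # 0.75*log(1.5) + 0.25*log(0.5) = 0.13081...
#' @export
kl_update <- function(prior, posterior, eps = 1e-6) {
  assert_prob(prior); assert_prob(posterior)
  q <- clip_prob(prior, eps)
  p <- clip_prob(posterior, eps)
  p * (log(p) - log(q)) + (1 - p) * (log(1 - p) - log(1 - q))
}

# CPT entries each causal structure requires (beyond the prior p_N).
.network_entries <- list(
  BAYES = c("p_N", "p_A_given_N", "p_A_given_notN"),
  IE = c("p_N", "p_D", "p_A_given_N_D", "p_A_given_N_notD",
         "p_A_given_notN_D", "p_A_given_notN_notD"),
  FC = c("p_N", "p_D_given_N", "p_D_given_notN", "p_A_given_N_D",
         "p_A_given_N_notD", "p_A_given_notN_D", "p_A_given_notN_notD"),
  DM = c("p_N", "p_D_given_N", "p_D_given_notN", "p_A_given_D",
         "p_A_given_notD")
)

#' Specify a causal model of norm inference
#'
#' The candidate models are three discrete Bayesian networks over norm N,
#' desire D and action A — IE (independent effects, N -> A <- D), FC (fully
#' connected: N -> D, N -> A, D -> A) and DM (desire mediation,
#' N -> D -> A) — plus the single-variable Bayes update (`BAYES`) and the
#' frequency-tracking baseline (`FREQ`, which takes no probabilities).
#'
#' @param model one of `"IE"`, `"FC"`, `"DM"`, `"BAYES"`, `"FREQ"`.
#' @param cpt named list of conditional-probability entries; exactly the
#'   entries the structure requires must be present (see
#'   [required_cpt_entries()]). Entries may be equal-length numeric vectors,
#'   in which case all computations vectorize elementwise.
#' @return an object of class `"network_spec"`.
#' @export
network_spec <- function(model = c("IE", "FC", "DM", "BAYES", "FREQ"),
                         cpt = list()) {
  model <- match.arg(model)
  if (model == "FREQ") {
    if (length(cpt)) stop("FREQ takes no CPT entries", call. = FALSE)
    return(structure(list(model = model, cpt = list()),
                     class = "network_spec"))
  }
  req <- .network_entries[[model]]
  missing <- setdiff(req, names(cpt))
  if (length(missing))
    stop(sprintf("missing CPT entries for %s model: %s", model,
                 paste(missing, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(cpt), req)
  if (length(extra))
    stop(sprintf("unknown CPT entries for %s model: %s", model,
                 paste(extra, collapse = ", ")), call. = FALSE)
  lens <- vapply(cpt[req], length, 1L)
  if (length(unique(lens)) != 1)
    stop("all CPT entries must have the same length", call. = FALSE)
  for (nm in req) assert_prob(cpt[[nm]], nm)
  structure(list(model = model, cpt = cpt[req]), class = "network_spec")
}

#' @rdname network_spec
#' @export
required_cpt_entries <- function(model) {
  .network_entries[[match.arg(model, names(.network_entries))]]
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>", x$model, "model\n")
  if (length(x$cpt))
    cat("  entries:", paste(names(x$cpt), collapse = ", "), "\n")
  invisible(x)
}

# Collapse the desire variable: returns list(p_A_given_N, p_A_given_notN)
# by marginalizing D under the model's own factorization. This is the
# model-specific algebra route; tests check it against generic joint-table
# enumeration.
.collapsed_likelihood <- function(spec) {
  cpt <- spec$cpt
  switch(spec$model,
    BAYES = list(n = cpt$p_A_given_N, notn = cpt$p_A_given_notN),
    IE = list(
      n    = cpt$p_D * cpt$p_A_given_N_D + (1 - cpt$p_D) * cpt$p_A_given_N_notD,
      notn = cpt$p_D * cpt$p_A_given_notN_D +
             (1 - cpt$p_D) * cpt$p_A_given_notN_notD),
    FC = list(
      n    = cpt$p_D_given_N * cpt$p_A_given_N_D +
             (1 - cpt$p_D_given_N) * cpt$p_A_given_N_notD,
      notn = cpt$p_D_given_notN * cpt$p_A_given_notN_D +
             (1 - cpt$p_D_given_notN) * cpt$p_A_given_notN_notD),
    DM = list(
      n    = cpt$p_D_given_N * cpt$p_A_given_D +
             (1 - cpt$p_D_given_N) * cpt$p_A_given_notD,
      notn = cpt$p_D_given_notN * cpt$p_A_given_D +
             (1 - cpt$p_D_given_notN) * cpt$p_A_given_notD),
    stop("no likelihood for model ", spec$model, call. = FALSE))
}

#' Posterior probability of a norm under a causal model
#'
#' Exact inference of `P(N | A = action_observed)` in the model's
#' factorization, by marginalizing the desire variable into collapsed
#' likelihoods `P(A|N)`, `P(A|not N)` and applying the Bayes update.
#'
#' @param spec a [network_spec()] (IE, FC, DM or BAYES).
#' @param action_observed logical; `TRUE` (default) conditions on observing
#'   the norm-consistent action, `FALSE` on its absence.
#' @param eps clipping bound passed to the Bayes update.
#' @return posterior probability `P(N|A)`, vectorized over CPT entries.
#' @examples
#' ie <- network_spec("IE", list(p_N = 0.5, p_D = 0.5,
#'   p_A_given_N_D = 0.9, p_A_given_N_notD = 0.7,
#'   p_A_given_notN_D = 0.6, p_A_given_notN_notD = 0.1))
#' network_posterior(ie)  # 0.8/1.15
#' @export
network_posterior <- function(spec, action_observed = TRUE, eps = 1e-6) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$model == "FREQ")
    stop("FREQ has no probabilistic posterior; use frequency_estimate()",
         call. = FALSE)
  lik <- .collapsed_likelihood(spec)
  if (action_observed)
    bayes_posterior(spec$cpt$p_N, lik$n, lik$notn, eps)
  else
    bayes_posterior(spec$cpt$p_N, 1 - lik$n, 1 - lik$notn, eps)
}

#' Posterior probability of the agent's desire under a causal model
#'
#' Exact `P(D | A = action_observed)` for the IE, FC and DM networks, via the
#' desire marginal `P(D)` and the collapsed likelihoods `P(A|D)`,
#' `P(A|not D)` implied by the factorization.
#'
#' @inheritParams network_posterior
#' @return posterior probability `P(D|A)`.
#' @export
desire_posterior <- function(spec, action_observed = TRUE, eps = 1e-6) {
  stopifnot(inherits(spec, "network_spec"))
  cpt <- spec$cpt
  lik <- switch(spec$model,
    IE = {
      p_d <- cpt$p_D
      list(p_d = p_d,
           d    = cpt$p_N * cpt$p_A_given_N_D +
                  (1 - cpt$p_N) * cpt$p_A_given_notN_D,
           notd = cpt$p_N * cpt$p_A_given_N_notD +
                  (1 - cpt$p_N) * cpt$p_A_given_notN_notD)
    },
    FC = {
      p_d <- cpt$p_N * cpt$p_D_given_N + (1 - cpt$p_N) * cpt$p_D_given_notN
      p_d_c <- clip_prob(p_d, eps)
      # P(N|D) and P(N|not D) by Bayes on the N -> D edge
      p_n_d <- cpt$p_N * cpt$p_D_given_N / p_d_c
      p_n_notd <- cpt$p_N * (1 - cpt$p_D_given_N) / (1 - p_d_c)
      list(p_d = p_d,
           d    = p_n_d * cpt$p_A_given_N_D +
                  (1 - p_n_d) * cpt$p_A_given_notN_D,
           notd = p_n_notd * cpt$p_A_given_N_notD +
                  (1 - p_n_notd) * cpt$p_A_given_notN_notD)
    },
    DM = {
      p_d <- cpt$p_N * cpt$p_D_given_N + (1 - cpt$p_N) * cpt$p_D_given_notN
      list(p_d = p_d, d = cpt$p_A_given_D, notd = cpt$p_A_given_notD)
    },
    stop(spec$model, " has no desire variable", call. = FALSE))
  if (action_observed)
    bayes_posterior(lik$p_d, pmin(pmax(lik$d, 0), 1),
                    pmin(pmax(lik$notd, 0), 1), eps)
  else
    bayes_posterior(lik$p_d, pmin(pmax(1 - lik$d, 0), 1),
                    pmin(pmax(1 - lik$notd, 0), 1), eps)
}

#' Frequency-tracking baseline
#'
#' Predicts the norm judgment from the observed tally alone: the proportion
#' `k/n` of sample agents whose behavior was norm-consistent, with no prior
#' integration. Over a four-agent group this yields only the fixed estimates
#' \{0.25, 0.5, 0.75, 1\}.
#'
#' @param k_consistent number of norm-consistent behaviors observed.
#' @param n_agents number of sample agents (4 in all designs).
#' @return `k_consistent / n_agents`, vectorized.
#' @export
frequency_estimate <- function(k_consistent, n_agents) {
  if (any(n_agents <= 0)) stop("n_agents must be positive", call. = FALSE)
  if (any(k_consistent < 0) || any(k_consistent > n_agents))
    stop("k_consistent must lie in [0, n_agents]", call. = FALSE)
  k_consistent / n_agents
}
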