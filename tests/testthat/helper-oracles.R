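# Independent oracles, deliberately implemented by brute force and kept
# free of the package's own inference code paths.

# Generic joint-table enumeration over binary (N, D, A): build all 8 cells
# explicitly from the model's factorization, then condition by summation.
oracle_joint <- function(model, cpt, states = expand.grid(n = c(1, 0),
                                                          d = c(1, 0),
                                                          a = c(1, 0))) {
  probs <- apply(states, 1, function(s) {
    n <- s[["n"]]; d <- s[["d"]]; a <- s[["a"]]
    p_n <- if (n == 1) cpt$p_N else 1 - cpt$p_N
    p_d <- switch(model,
      IE = if (d == 1) cpt$p_D else 1 - cpt$p_D,
      FC = ,
      DM = {
        pd <- if (n == 1) cpt$p_D_given_N else cpt$p_D_given_notN
        if (d == 1) pd else 1 - pd
      })
    p_a <- switch(model,
      IE = ,
      FC = {
        key <- paste0("p_A_given_", if (n == 1) "N" else "notN",
                      "_", if (d == 1) "D" else "notD")
        if (a == 1) cpt[[key]] else 1 - cpt[[key]]
      },
      DM = {
        pa <- if (d == 1) cpt$p_A_given_D else cpt$p_A_given_notD
        if (a == 1) pa else 1 - pa
      })
    p_n * p_d * p_a
  })
  cbind(states, p = probs)
}

oracle_conditional <- function(model, cpt, target = c("n", "d"), a_obs = 1) {
  target <- match.arg(target)
  j <- oracle_joint(model, cpt)
  given <- j[j$a == a_obs, ]
  sum(given$p[given[[target]] == 1]) / sum(given$p)
}

random_cpt <- function(model) {
  entries <- norminfer::required_cpt_entries(model)
  # keep entries interior so conditioning is well-defined
  vals <- stats::runif(length(entries), 0.05, 0.95)
  as.list(stats::setNames(vals, entries))
}

# Exact leave-one-out for the conjugate normal-mean model
# y_i ~ N(mu, s2) with known s2, prior mu ~ N(0, tau2): refit without i and
# evaluate the posterior predictive density of y_i in closed form.
oracle_exact_loo <- function(y, s2, tau2) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    yi <- y[-i]
    post_var <- 1 / ((n - 1) / s2 + 1 / tau2)
    post_mean <- post_var * sum(yi) / s2
    stats::dnorm(y[i], post_mean, sqrt(post_var + s2), log = TRUE)
  }, numeric(1))
}

# First-principles within-subject decomposition for the one-way
# repeated-measures ANOVA, via explicit cell loops.
oracle_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- 0; ss_subj <- 0; ss_tot <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(m[, j]) - grand)^2
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(m[i, ]) - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_tot <- ss_tot + (m[i, j] - grand)^2
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  # GG epsilon straight from its eigenvalue definition on the
  # double-centered covariance
  S <- cov(m)
  B <- diag(k) - matrix(1 / k, k, k)
  Sc <- B %*% S %*% B
  lam <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  list(f = f, eps = eps, pes = ss_cond / (ss_cond + ss_err))
}

# Small helper: quick Exp-design fixtures at reduced size for speed
small_design <- function(experiment, n = 8, seed = 1,
                         trials_per_condition = 4)
  experiment_design(experiment, n_participants = n,
                    trials_per_condition = trials_per_condition,
                    seed = seed)
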