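# Bayesian hierarchical linear regression of judgmental posteriors on
# model-derived posteriors, with random intercepts and slopes per
# participant and optionally per condition. Sampled with JAGS (rjags).

# Random effects use the hierarchically centered parametrization
# (group coefficients drawn around the population coefficients), which
# mixes far better under Gibbs sampling; the monitored a[i], b[i] are the
# usual zero-mean deviations.
.jags_model_participant <- "
model {
  for (j in 1:J) {
    mu[j] <- aa[pid[j]] + bb[pid[j]] * x[j]
    y[j] ~ dnorm(mu[j], tau_res)
  }
  for (i in 1:P) {
    aa[i] ~ dnorm(alpha, tau_a)
    bb[i] ~ dnorm(beta, tau_b)
    a[i] <- aa[i] - alpha
    b[i] <- bb[i] - beta
  }
  alpha ~ dnorm(0, prec_fixed)
  beta ~ dnorm(0, prec_fixed)
  sigma_a ~ dnorm(0, prec_sd) T(0,)
  sigma_b ~ dnorm(0, prec_sd) T(0,)
  sigma_res ~ dnorm(0, prec_sd) T(0,)
  tau_a <- 1 / (sigma_a * sigma_a)
  tau_b <- 1 / (sigma_b * sigma_b)
  tau_res <- 1 / (sigma_res * sigma_res)
}"

# In the condition variant the *condition* effects are the ones centered on
# the fixed effects: with few condition levels and potentially large
# between-condition variance, a zero-mean parametrization leaves the fixed
# effects and the condition means strongly anticorrelated and the Gibbs
# sampler mixes very slowly. Participant effects (many levels, small
# variance) stay zero-mean.
.jags_model_condition <- "
model {
  for (j in 1:J) {
    mu[j] <- a[pid[j]] + gg[cid[j]] + (b[pid[j]] + dd[cid[j]]) * x[j]
    y[j] ~ dnorm(mu[j], tau_res)
  }
  for (i in 1:P) {
    a[i] ~ dnorm(0, tau_a)
    b[i] ~ dnorm(0, tau_b)
  }
  for (k in 1:C) {
    gg[k] ~ dnorm(alpha, tau_c)
    dd[k] ~ dnorm(beta, tau_d)
    cc[k] <- gg[k] - alpha
    d[k] <- dd[k] - beta
  }
  alpha ~ dnorm(0, prec_fixed)
  beta ~ dnorm(0, prec_fixed)
  sigma_a ~ dnorm(0, prec_sd) T(0,)
  sigma_b ~ dnorm(0, prec_sd) T(0,)
  sigma_c ~ dnorm(0, prec_sd) T(0,)
  sigma_d ~ dnorm(0, prec_sd) T(0,)
  sigma_res ~ dnorm(0, prec_sd) T(0,)
  tau_a <- 1 / (sigma_a * sigma_a)
  tau_b <- 1 / (sigma_b * sigma_b)
  tau_c <- 1 / (sigma_c * sigma_c)
  tau_d <- 1 / (sigma_d * sigma_d)
  tau_res <- 1 / (sigma_res * sigma_res)
}"

#' Fit the hierarchical regression of judgments on model posteriors
#'
#' Gaussian hierarchical linear model `y ~ x` with a random intercept and
#' random slope for each participant, and optionally an additional random
#' intercept and slope for each condition (the more stringent variant that
#' absorbs condition-level structure). Priors are weakly informative:
#' Normal(0, 2.5) on the intercept and slope (predictor and response both
#' live on [0,1]) and half-Normal(0, 1) on every standard deviation.
#' Sampling is Markov chain Monte Carlo via JAGS.
#'
#' @param x model-derived posterior per participant x condition cell.
#' @param y judgmental posterior per cell.
#' @param participant grouping identifier per cell.
#' @param condition condition identifier per cell; required when
#'   `condition_random = TRUE`.
#' @param condition_random add condition as a second random grouping
#'   (intercept + slope)?
#' @param chains number of MCMC chains (default 2).
#' @param iter total iterations per chain including warmup (default 2000;
#'   full-scale runs use 10000).
#' @param warmup adaptation/burn-in iterations per chain (default 500;
#'   full-scale runs use 2000).
#' @param seed integer seed for the samplers.
#' @param jitter sd of Gaussian noise added to `y` before fitting; breaks
#'   the degenerate zero-residual case when `y` equals `x` exactly
#'   (default 0).
#' @param prior_sd_fixed,prior_sd_scale prior scales for fixed effects and
#'   standard deviations.
#' @return an object of class `"norm_hfit"`: draw matrices per chain, merged
#'   draws, `rhat` per parameter, variance components, pointwise
#'   log-likelihood (draws x observations) and the data used.
#' @export
fit_hierarchical <- function(x, y, participant, condition = NULL,
                             condition_random = FALSE, chains = 2,
                             iter = 2000, warmup = 500, seed = 1L,
                             jitter = 0, prior_sd_fixed = 2.5,
                             prior_sd_scale = 1) {
  stopifnot(length(x) == length(y), length(x) == length(participant),
            iter > warmup, chains >= 2)
  pid <- as.integer(factor(participant))
  if (length(unique(pid)) < 2) stop("need >= 2 participants", call. = FALSE)
  if (jitter > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, jitter)
  }
  # Center the predictor for sampling: with x on [0,1] and judgments far
  # from 0, intercept and slope are strongly correlated and Gibbs mixing
  # suffers; draws are transformed back to the raw-x parametrization below.
  xbar <- mean(x)
  dat <- list(y = y, x = x - xbar, pid = pid, J = length(y),
              P = max(pid), prec_fixed = 1 / prior_sd_fixed^2,
              prec_sd = 1 / prior_sd_scale^2)
  monitors <- c("alpha", "beta", "sigma_a", "sigma_b", "sigma_res", "a", "b")
  model_str <- .jags_model_participant
  if (condition_random) {
    if (is.null(condition)) stop("condition required", call. = FALSE)
    cid <- as.integer(factor(condition))
    dat$cid <- cid; dat$C <- max(cid)
    monitors <- c(monitors, "sigma_c", "sigma_d", "cc", "d")
    model_str <- .jags_model_condition
  }
  inits <- lapply(seq_len(chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) %% 100000L) * 100L + i)
  })
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          inits = inits, n.chains = chains,
                          n.adapt = max(100, warmup %/% 2), quiet = TRUE)
  stats::update(jm, n.iter = warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = iter - warmup,
                              progress.bar = "none")
  # back-transform to the raw-x parametrization:
  # alpha_raw = alpha_c - beta * xbar, a_raw = a_c - b * xbar (same for the
  # condition intercepts); slopes and variance components are unchanged.
  uncenter <- function(m) {
    m[, "alpha"] <- m[, "alpha"] - m[, "beta"] * xbar
    for (i in seq_len(dat$P))
      m[, paste0("a[", i, "]")] <- m[, paste0("a[", i, "]")] -
        m[, paste0("b[", i, "]")] * xbar
    if (condition_random)
      for (k in seq_len(dat$C))
        m[, paste0("cc[", k, "]")] <- m[, paste0("cc[", k, "]")] -
          m[, paste0("d[", k, "]")] * xbar
    m
  }
  chains_mat <- lapply(samp, function(s) uncenter(as.matrix(s)))
  draws <- do.call(rbind, chains_mat)
  dat$x <- x  # raw scale for the stored data and pointwise log-likelihood
  scalar_pars <- intersect(
    c("alpha", "beta", "sigma_a", "sigma_b", "sigma_c", "sigma_d",
      "sigma_res"), colnames(draws))
  rh <- vapply(scalar_pars, function(p)
    split_rhat(lapply(chains_mat, function(m) m[, p])), numeric(1))

  ll <- .pointwise_loglik(draws, dat, condition_random)
  fit <- structure(list(
    draws = draws, chains = chains_mat, rhat = rh,
    condition_random = condition_random,
    data = dat, pointwise_loglik = ll,
    n_chains = chains, iter = iter, warmup = warmup, seed = seed),
    class = "norm_hfit")
  if (any(rh > 1.05, na.rm = TRUE))
    warning(sprintf("possible non-convergence: max rhat = %.3f (%s)",
                    max(rh), paste(names(rh)[rh > 1.05], collapse = ", ")),
            call. = FALSE)
  fit
}

# Per-draw, per-observation Gaussian log-likelihood from stored draws.
.pointwise_loglik <- function(draws, dat, condition_random) {
  A <- draws[, paste0("a[", seq_len(dat$P), "]"), drop = FALSE]
  B <- draws[, paste0("b[", seq_len(dat$P), "]"), drop = FALSE]
  mu <- draws[, "alpha"] + A[, dat$pid, drop = FALSE] +
    (draws[, "beta"] + B[, dat$pid, drop = FALSE]) *
      matrix(dat$x, nrow(draws), dat$J, byrow = TRUE)
  if (condition_random) {
    CC <- draws[, paste0("cc[", seq_len(dat$C), "]"), drop = FALSE]
    D <- draws[, paste0("d[", seq_len(dat$C), "]"), drop = FALSE]
    mu <- mu + CC[, dat$cid, drop = FALSE] +
      D[, dat$cid, drop = FALSE] *
        matrix(dat$x, nrow(draws), dat$J, byrow = TRUE)
  }
  yv <- matrix(dat$y, nrow(draws), dat$J, byrow = TRUE)
  stats::dnorm(yv, mu, draws[, "sigma_res"], log = TRUE)
}

#' Split-half R-hat convergence diagnostic
#'
#' Splits each chain in half, then computes the classic potential
#' scale-reduction factor from the between- and within-half variances. Values
#' near 1 indicate convergence; the package warns above 1.05.
#'
#' @param chains list (length >= 2) of numeric vectors, one per chain, equal
#'   lengths >= 4.
#' @return the split R-hat statistic.
#' @export
split_rhat <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stop("need >= 2 chains", call. = FALSE)
  n <- unique(vapply(chains, length, 1L))
  if (length(n) != 1 || n < 4)
    stop("chains must have equal length >= 4", call. = FALSE)
  half <- n %/% 2
  splits <- unlist(lapply(chains, function(ch)
    list(ch[seq_len(half)], ch[(n - half + 1):n])), recursive = FALSE)
  m <- length(splits); len <- half
  means <- vapply(splits, mean, numeric(1))
  vars <- vapply(splits, stats::var, numeric(1))
  W <- mean(vars)
  B <- len * stats::var(means)
  if (W == 0) return(1)
  sqrt(((len - 1) / len * W + B / len) / W)
}

#' Standardized slope effect size
#'
#' The slope divided by the square root of the sum of all variance
#' components in the model (random-intercept, random-slope and residual
#' variances; plus the condition components when present). With
#' `method = "draws"` (default) the ratio is computed per posterior draw and
#' averaged; `method = "means"` forms the ratio of posterior means.
#'
#' @param fit a `"norm_hfit"` object.
#' @param method `"draws"` or `"means"`.
#' @return the effect size (scalar).
#' @export
delta_t <- function(fit, method = c("draws", "means")) {
  method <- match.arg(method)
  sds <- intersect(c("sigma_a", "sigma_b", "sigma_c", "sigma_d",
                     "sigma_res"), colnames(fit$draws))
  v <- fit$draws[, sds, drop = FALSE]^2
  tot <- rowSums(v)
  if (all(tot == 0)) stop("all variance components are zero", call. = FALSE)
  if (method == "draws") mean(fit$draws[, "beta"] / sqrt(tot))
  else mean(fit$draws[, "beta"]) / sqrt(mean(tot))
}

#' Highest-density interval of a sample
#'
#' @param draws numeric sample.
#' @param prob interval mass (default 0.95).
#' @return length-2 vector (lower, upper).
#' @export
hdi <- function(draws, prob = 0.95) {
  s <- sort(draws)
  n <- length(s)
  k <- max(1, floor(prob * n))
  starts <- seq_len(n - k)
  widths <- s[starts + k] - s[starts]
  i <- which.min(widths)
  c(s[i], s[i + k])
}

#' Summarize a hierarchical regression fit
#'
#' Reports the population slope beta: posterior mean, 95% credible interval
#' (equal-tailed or highest-density), the posterior probability that the
#' slope is positive, the standardized effect size and the maximum R-hat.
#'
#' @param fit a `"norm_hfit"`.
#' @param interval `"eti"` (equal-tailed, default) or `"hdi"`.
#' @return one-row `data.frame` with columns `beta`, `cri_lower`,
#'   `cri_upper`, `pr_beta_gt_0` (percent), `delta_t`, `max_rhat`.
#' @export
summarize_fit <- function(fit, interval = c("eti", "hdi")) {
  interval <- match.arg(interval)
  b <- fit$draws[, "beta"]
  ci <- if (interval == "eti") unname(stats::quantile(b, c(0.025, 0.975)))
        else hdi(b)
  data.frame(beta = mean(b), cri_lower = ci[1], cri_upper = ci[2],
             pr_beta_gt_0 = round(100 * mean(b > 0), 2),
             delta_t = delta_t(fit), max_rhat = max(fit$rhat))
}

#' @export
print.norm_hfit <- function(x, ...) {
  s <- summarize_fit(x)
  cat("Bayesian hierarchical linear regression",
      if (x$condition_random) "(participant + condition random effects)"
      else "(participant random effects)", "\n")
  cat(sprintf("  beta = %.2f, 95%% CrI = [%.2f, %.2f], Pr(beta > 0) = %.2f%%, delta_t = %.2f\n",
              s$beta, s$cri_lower, s$cri_upper, s$pr_beta_gt_0, s$delta_t))
  cat(sprintf("  max Rhat = %.3f over %d chains x %d post-warmup iterations\n",
              s$max_rhat, x$n_chains, x$iter - x$warmup))
  invisible(x)
}
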