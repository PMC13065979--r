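# Leave-one-out cross-validation by Pareto-smoothed importance sampling
# (PSIS), from a pointwise log-likelihood matrix (draws x observations).

# Generalized Pareto fit (k, sigma) to exceedances, by the profile-likelihood
# quadrature of Zhang & Stephens (2009), with the weak prior regularization
# toward k = 0.5 used by the standard PSIS recipe.
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || x[n] <= 0) return(list(k = Inf, sigma = NA_real_))
  prior <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior * xstar)
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l_j - l_j[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- -mean(log1p(-theta_hat * x))
  sigma <- k / theta_hat
  k <- k * n / (n + 10) + 0.5 * 10 / (n + 10)  # regularization
  list(k = k, sigma = sigma)
}

.gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p)
  else sigma * expm1(-k * log1p(-p)) / k
}

# Smooth the largest importance ratios of one observation. lw: log weights.
.psis_smooth <- function(lw) {
  S <- length(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) return(list(lw = lw - max(lw), k = Inf))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  fit <- .gpd_fit(exp(lw[tail_ids]) - exp(cutoff))
  if (is.finite(fit$k)) {
    p <- (seq_len(M) - 0.5) / M
    qs <- exp(cutoff) + vapply(p, .gpd_quantile, numeric(1),
                               k = fit$k, sigma = fit$sigma)
    lw[tail_ids[order(lw[tail_ids])]] <- log(qs)
  }
  lw <- pmin(lw, max(lw))  # cap at the raw maximum
  list(lw = lw - max(lw), k = fit$k)
}

#' PSIS leave-one-out cross-validation of a fitted model
#'
#' Estimates each observation's expected log predictive density under
#' leave-one-out cross-validation by importance sampling with
#' Pareto-smoothed weights: the raw weights are the inverse pointwise
#' likelihoods, and the largest `min(0.2 S, 3 sqrt(S))` weights per
#' observation are replaced by the order statistics of a fitted generalized
#' Pareto tail. Observations with Pareto tail-shape `k > 0.7` are flagged as
#' unreliable.
#'
#' @param loglik matrix of pointwise log-likelihoods, draws x observations
#'   (as stored by [fit_hierarchical()]), with at least 100 draws.
#' @param model optional model label carried into comparisons.
#' @return an object of class `"loo_result"`: `elpd_loo`, `looic`
#'   (`-2 * elpd_loo`), `pointwise` elpd per observation, `pareto_k`
#'   diagnostics, `p_loo` (effective parameters) and `lppd` (in-sample).
#' @export
psis_loo <- function(loglik, model = "model") {
  if (!is.matrix(loglik) || !all(is.finite(loglik)))
    stop("loglik must be a finite draws x observations matrix",
         call. = FALSE)
  S <- nrow(loglik)
  if (S < 100) stop("need >= 100 draws for PSIS", call. = FALSE)
  n <- ncol(loglik)
  elpd <- numeric(n); kk <- numeric(n)
  for (i in seq_len(n)) {
    sm <- .psis_smooth(-loglik[, i])
    w <- exp(sm$lw)
    elpd[i] <- log(sum(w * exp(loglik[, i] - max(loglik[, i]))) / sum(w)) +
      max(loglik[, i])
    kk[i] <- sm$k
  }
  lppd <- sum(apply(loglik, 2, function(l) log(mean(exp(l - max(l)))) +
                      max(l)))
  structure(list(model = model, elpd_loo = sum(elpd),
                 looic = -2 * sum(elpd), pointwise = elpd, pareto_k = kk,
                 p_loo = lppd - sum(elpd), lppd = lppd, n_draws = S,
                 n_obs = n),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("PSIS-LOO (%s): elpd_loo = %.2f, LOOIC = %.2f, p_loo = %.2f\n",
              x$model, x$elpd_loo, x$looic, x$p_loo))
  bad <- sum(x$pareto_k > 0.7)
  if (bad) cat(sprintf("  %d of %d observations with pareto_k > 0.7\n",
                       bad, x$n_obs))
  invisible(x)
}

#' Rank candidate models by LOOIC
#'
#' @param ... `"loo_result"` objects, or a single list of them.
#' @return a `data.frame` sorted ascending by `looic` with `delta_looic`
#'   relative to the best (smallest-LOOIC) model; ties keep declaration
#'   order. All results must cover the same observations.
#' @export
compare_loo <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "loo_result"))
    fits <- fits[[1]]
  stopifnot(all(vapply(fits, inherits, TRUE, "loo_result")))
  n_obs <- vapply(fits, function(f) f$n_obs, 1)
  if (length(unique(n_obs)) != 1)
    stop("models were fit to different numbers of observations",
         call. = FALSE)
  tab <- data.frame(
    model = vapply(fits, function(f) f$model, ""),
    looic = vapply(fits, function(f) f$looic, 1),
    elpd_loo = vapply(fits, function(f) f$elpd_loo, 1),
    max_pareto_k = vapply(fits, function(f) max(f$pareto_k), 1))
  tab <- tab[order(tab$looic), , drop = FALSE]  # stable: ties keep order
  tab$delta_looic <- tab$looic - tab$looic[1]
  rownames(tab) <- NULL
  tab[, c("model", "looic", "delta_looic", "elpd_loo", "max_pareto_k")]
}
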