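# Repeated-measures descriptive layer: one-way within-subject ANOVA with
# Greenhouse-Geisser correction and partial eta squared, paired post-hoc
# t tests between adjacent conditions, and one-sample t tests against a
# reference value, all Bonferroni-corrected.

#' Reshape an aggregated measure to participants x conditions
#'
#' @param agg long aggregated table from [aggregate_by_condition()].
#' @param measure which measure to extract.
#' @return numeric matrix, rows = participants, columns = conditions
#'   (ascending), with condition values as column names.
#' @export
condition_matrix <- function(agg, measure) {
  sub <- agg[agg$measure == measure, , drop = FALSE]
  if (!nrow(sub)) stop("measure not found: ", measure, call. = FALSE)
  conds <- sort(unique(sub$condition))
  parts <- sort(unique(sub$participant))
  m <- matrix(NA_real_, length(parts), length(conds),
              dimnames = list(parts, conds))
  m[cbind(match(sub$participant, parts), match(sub$condition, conds))] <-
    sub$value
  if (anyNA(m)) stop("incomplete participant x condition cells",
                     call. = FALSE)
  m
}

# Greenhouse-Geisser epsilon from the sample covariance of the k conditions:
# eps = tr(Sc)^2 / ((k-1) * sum(Sc^2)) with Sc the double-centered covariance.
.gg_epsilon <- function(S) {
  k <- ncol(S)
  if (k == 2) return(1)
  Sc <- sweep(S, 1, rowMeans(S))
  Sc <- sweep(Sc, 2, colMeans(Sc))
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

# Mauchly's sphericity test on orthonormal contrasts of the covariance.
.mauchly <- function(S, n) {
  k <- ncol(S)
  if (k < 3) return(list(W = NA_real_, p = NA_real_))
  C <- stats::contr.helmert(k)
  C <- C %*% diag(1 / sqrt(colSums(C^2)), k - 1)
  V <- t(C) %*% S %*% C
  kk <- k - 1
  W <- det(V) / (sum(diag(V)) / kk)^kk
  if (!is.finite(W) || W <= 0) return(list(W = W, p = 0))
  f <- 1 - (2 * kk^2 + kk + 2) / (6 * kk * (n - 1))
  chi2 <- -(n - 1) * f * log(W)
  df <- kk * (kk + 1) / 2 - 1
  list(W = W, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classic within-subject sums-of-squares decomposition: the condition effect
#' is tested against the participant x condition interaction. When Mauchly's
#' test rejects sphericity (p < 0.05, the `"auto"` policy) the degrees of
#' freedom are multiplied by the Greenhouse-Geisser epsilon computed from the
#' sample covariance of the condition columns. Effect size is partial eta
#' squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' @param wide numeric matrix participants x conditions (see
#'   [condition_matrix()]), at least 3 rows and 2 columns, complete.
#' @param correction `"auto"` (GG iff Mauchly p < 0.05), `"GG"` (always) or
#'   `"none"`.
#' @return list of class `"rm_anova"`: `f_value`, `df_effect`, `df_error`
#'   (possibly fractional), `p_value`, `partial_eta_sq`, `gg_epsilon`,
#'   `mauchly_w`, `mauchly_p`, `corrected`, `p_uncorrected`.
#' @export
rm_anova <- function(wide, correction = c("auto", "GG", "none")) {
  correction <- match.arg(correction)
  wide <- as.matrix(wide)
  n <- nrow(wide); k <- ncol(wide)
  if (k < 2) stop("need >= 2 conditions", call. = FALSE)
  if (n < 3) stop("need >= 3 participants", call. = FALSE)
  if (anyNA(wide)) stop("missing cells", call. = FALSE)
  grand <- mean(wide)
  ss_cond <- n * sum((colMeans(wide) - grand)^2)
  ss_subj <- k * sum((rowMeans(wide) - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  eps <- .gg_epsilon(stats::cov(wide))
  mau <- .mauchly(stats::cov(wide), n)
  use_gg <- switch(correction,
                   auto = !is.na(mau$p) && mau$p < 0.05,
                   GG = k > 2, none = FALSE)
  e <- if (use_gg) eps else 1
  structure(list(
    f_value = f, df_effect = e * df1, df_error = e * df2,
    p_value = stats::pf(f, e * df1, e * df2, lower.tail = FALSE),
    p_uncorrected = stats::pf(f, df1, df2, lower.tail = FALSE),
    partial_eta_sq = ss_cond / (ss_cond + ss_err),
    gg_epsilon = eps, mauchly_w = mau$W, mauchly_p = mau$p,
    corrected = use_gg, n = n, k = k), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  p <- if (x$p_value < 0.001) "p < 0.001"
       else sprintf("p = %.3f", x$p_value)
  cat(sprintf("F (%.2f, %.2f) = %.2f, %s, partial eta^2 = %.2f%s\n",
              x$df_effect, x$df_error, x$f_value, p, x$partial_eta_sq,
              if (x$corrected)
                sprintf(" [Greenhouse-Geisser, epsilon = %.3f]", x$gg_epsilon)
              else ""))
  invisible(x)
}

#' Bonferroni-corrected paired t tests between adjacent conditions
#'
#' Cohen's d for a paired contrast uses the average-sd denominator: the mean
#' difference divided by the average of the two condition standard
#' deviations.
#'
#' @param wide participants x conditions matrix, columns in condition order.
#' @param comparisons matrix with two columns of column indices to compare;
#'   defaults to all adjacent pairs.
#' @return `data.frame` with one row per comparison: `comparison`,
#'   `t_value`, `df`, `p_raw`, `p_bonferroni`, `cohen_d`.
#' @export
paired_posthoc <- function(wide, comparisons = NULL) {
  wide <- as.matrix(wide)
  k <- ncol(wide)
  if (is.null(comparisons))
    comparisons <- cbind(seq_len(k - 1), 2:k)
  m <- nrow(comparisons)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    a <- wide[, comparisons[i, 1]]; b <- wide[, comparisons[i, 2]]
    if (stats::sd(a - b) < 1e-10) {
      if (abs(mean(a - b)) > 1e-10)
        # constant nonzero difference: t would be infinite
        stop("zero-variance difference for comparison ",
             paste(comparisons[i, ], collapse = " vs "), call. = FALSE)
      # identical columns: no difference at all
      tt <- list(statistic = 0, parameter = length(a) - 1, p.value = 1)
      d <- 0
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      d <- mean(a - b) / mean(c(stats::sd(a), stats::sd(b)))
    }
    lab <- paste(colnames(wide)[comparisons[i, 1]] %||% comparisons[i, 1],
                 "vs",
                 colnames(wide)[comparisons[i, 2]] %||% comparisons[i, 2])
    out[[i]] <- data.frame(comparison = lab,
                           t_value = unname(tt$statistic),
                           df = unname(tt$parameter),
                           p_raw = tt$p.value,
                           cohen_d = d)
  }
  res <- do.call(rbind, out)
  res$p_bonferroni <- pmin(1, res$p_raw * m)
  res[, c("comparison", "t_value", "df", "p_raw", "p_bonferroni",
          "cohen_d")]
}

#' One-sample t test against a reference probability
#'
#' Used to compare per-condition priors against 0.5 (maximal uncertainty)
#' and belief-updating scores against 0 (no updating), Bonferroni-corrected
#' over the family of conditions.
#'
#' @param values numeric vector (one value per participant).
#' @param mu reference value (0.5 for probabilities, 0 for divergences).
#' @param m number of comparisons in the Bonferroni family (default 1).
#' @param label optional comparison label.
#' @return one-row `data.frame`: `comparison`, `t_value`, `df`, `p_raw`,
#'   `p_bonferroni`, `cohen_d` (`(mean - mu) / sd`).
#' @export
one_sample_t <- function(values, mu, m = 1, label = NULL) {
  if (length(values) < 2) stop("need n >= 2", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation", call. = FALSE)
  tt <- stats::t.test(values, mu = mu)
  data.frame(comparison = label %||% sprintf("mean vs %g", mu),
             t_value = unname(tt$statistic),
             df = unname(tt$parameter),
             p_raw = tt$p.value,
             p_bonferroni = min(1, tt$p.value * m),
             cohen_d = (mean(values) - mu) / s)
}
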