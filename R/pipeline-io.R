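# Readers/writers, run configuration and the seeded end-to-end analysis
# runner that reproduces each experiment's full pipeline on synthetic (or
# OSF-format) trial tables.

.trial_columns <- c("participant", "experiment", "condition", "trial",
                    "measure", "value")

#' Write a trial table as CSV
#'
#' @param trials long trial table.
#' @param path output file; UTF-8, header row, proportions on the 0-1 scale.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(.trial_columns %in% names(trials)))
  utils::write.csv(trials[, .trial_columns], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a trial table
#'
#' Accepts slider values stored either as proportions (0-1) or as percents
#' (0-100); the scale is auto-detected from the maximum value and percents
#' are rescaled, with a message. Extra columns are dropped with a warning.
#'
#' @param path CSV file with the trial-table schema.
#' @return validated long `data.frame` with values as proportions.
#' @export
read_trials <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.trial_columns, names(tab))
  if (length(missing))
    stop("trial table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(tab), .trial_columns)
  if (length(extra)) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    tab <- tab[, .trial_columns]
  }
  if (!is.numeric(tab$value) || any(!is.finite(tab$value)))
    stop("'value' must be finite numeric", call. = FALSE)
  if (any(tab$value < 0) || any(tab$value > 100))
    stop("'value' outside [0, 100]", call. = FALSE)
  if (max(tab$value) > 1.5) {
    message("values look like percents (max > 1.5); rescaling to 0-1")
    tab$value <- tab$value / 100
  }
  tab
}

#' Configuration of a full experiment run
#'
#' @param experiment 1, 2 or 3.
#' @param models models whose posteriors are regressed against judgments;
#'   Experiments 1-2 allow `c("BAYES", "FREQ")`, Experiment 3 additionally
#'   the networks. Defaults to the experiment's full set.
#' @param design an [experiment_design()]; built from `experiment` and
#'   `seed` when omitted.
#' @param observer an [observer_params()]; defaults to a BAYES generator for
#'   Experiments 1-2 and an IE generator for Experiment 3.
#' @param chains,iter,warmup MCMC settings for every regression.
#' @param seed global seed; stage seeds are derived from it by fixed offsets
#'   so stages are individually reproducible.
#' @param out_dir optional directory; when given, [run_experiment()] writes
#'   the trial table, aggregated table, test reports and regression/LOO
#'   tables there as CSV plus a run log.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(experiment, models = NULL, design = NULL,
                       observer = NULL, chains = 2, iter = 2000,
                       warmup = 500, seed = 1L, out_dir = NULL) {
  stopifnot(experiment %in% 1:3)
  models <- models %||%
    (if (experiment < 3) c("BAYES", "FREQ")
     else c("IE", "FC", "DM", "BAYES", "FREQ"))
  if (experiment < 3 && !all(models %in% c("BAYES", "FREQ")))
    stop("Experiments 1-2 restrict models to BAYES and FREQ", call. = FALSE)
  if (!length(models)) stop("models must be non-empty", call. = FALSE)
  design <- design %||% experiment_design(experiment, seed = seed)
  observer <- observer %||%
    observer_params(if (experiment < 3) "BAYES" else "IE")
  structure(list(experiment = experiment, models = models, design = design,
                 observer = observer, chains = chains, iter = iter,
                 warmup = warmup, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the [run_config()] arguments, with `design` and
#' `observer` blocks mapping onto [experiment_design()] and
#' [observer_params()].
#'
#' @param path YAML file.
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- if (!is.null(y$design)) {
    args <- c(list(experiment = y$experiment), y$design)
    if (is.null(args$seed)) args$seed <- y$seed %||% 1L
    do.call(experiment_design, args)
  }
  observer <- if (!is.null(y$observer)) do.call(observer_params, y$observer)
  run_config(experiment = y$experiment, models = y$models,
             design = design, observer = observer,
             chains = y$chains %||% 2, iter = y$iter %||% 2000,
             warmup = y$warmup %||% 500, seed = y$seed %||% 1L,
             out_dir = y$out_dir)
}

#' Run one experiment's full analysis pipeline
#'
#' Stage order: simulate (or ingest) trials, compute per-trial belief
#' updating, aggregate to participant x condition means, descriptive
#' frequentist layer (repeated-measures ANOVA, adjacent-condition post-hoc
#' tests, one-sample tests of priors against 0.5 and of updating against 0),
#' per-model posteriors and hierarchical regressions (participant-only and
#' condition-random-effect variants), and a LOO model-comparison table.
#'
#' @param config a [run_config()].
#' @param trials optional pre-loaded trial table (e.g. from
#'   [read_trials()]); when omitted, trials are generated from the config's
#'   design and observer.
#' @return list of class `"norm_run"` with elements `trials`, `aggregated`,
#'   `anova` (per measure), `posthoc`, `one_sample`, `regressions` (per
#'   model, both variants), `loo` (comparison table) and `config`.
#' @export
run_experiment <- function(config, trials = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(trials))
    trials <- generate_experiment(config$design, config$observer)
  trials_kl <- add_kl_rows(trials)
  agg <- aggregate_by_condition(trials_kl)

  measures <- c("prior_norm", "posterior_norm", "d_kl")
  anova_res <- lapply(measures, function(ms)
    rm_anova(condition_matrix(agg, ms)))
  names(anova_res) <- measures
  posthoc <- lapply(measures, function(ms)
    paired_posthoc(condition_matrix(agg, ms)))
  names(posthoc) <- measures

  prior_w <- condition_matrix(agg, "prior_norm")
  dkl_w <- condition_matrix(agg, "d_kl")
  k <- ncol(prior_w)
  one_sample <- rbind(
    do.call(rbind, lapply(seq_len(k), function(i)
      one_sample_t(prior_w[, i], 0.5, m = k,
                   label = sprintf("prior_norm@%s vs 0.5",
                                   colnames(prior_w)[i])))),
    do.call(rbind, lapply(seq_len(k), function(i)
      one_sample_t(dkl_w[, i], 0, m = k,
                   label = sprintf("d_kl@%s vs 0", colnames(dkl_w)[i])))))

  mpt <- model_posterior_table(trials, config$models)
  regressions <- list()
  loos <- list()
  for (m in config$models) {
    fit <- fit_hierarchical(mpt[[m]], mpt$judgment, mpt$participant,
                            condition = mpt$condition,
                            chains = config$chains, iter = config$iter,
                            warmup = config$warmup, seed = config$seed)
    fit_c <- fit_hierarchical(mpt[[m]], mpt$judgment, mpt$participant,
                              condition = mpt$condition,
                              condition_random = TRUE,
                              chains = config$chains, iter = config$iter,
                              warmup = config$warmup,
                              seed = config$seed + 1L)
    regressions[[m]] <- list(participant = fit, condition = fit_c)
    loos[[m]] <- psis_loo(fit$pointwise_loglik, model = m)
  }
  loo_tab <- if (length(loos) >= 2) compare_loo(loos) else NULL

  res <- structure(list(trials = trials_kl, aggregated = agg,
                        model_table = mpt, anova = anova_res,
                        posthoc = posthoc, one_sample = one_sample,
                        regressions = regressions, loo = loo_tab,
                        config = config),
                   class = "norm_run")
  if (!is.null(config$out_dir)) .write_bundle(res, config$out_dir)
  res
}

.write_bundle <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(res$trials[res$trials$measure != "d_kl", ],
               file.path(dir, "trials.csv"))
  utils::write.csv(res$aggregated, file.path(dir, "aggregated.csv"),
                   row.names = FALSE)
  utils::write.csv(res$model_table, file.path(dir, "model_posteriors.csv"),
                   row.names = FALSE)
  anova_tab <- do.call(rbind, lapply(names(res$anova), function(ms) {
    a <- res$anova[[ms]]
    data.frame(measure = ms, f_value = a$f_value, df_effect = a$df_effect,
               df_error = a$df_error, p_value = a$p_value,
               partial_eta_sq = a$partial_eta_sq, gg_epsilon = a$gg_epsilon)
  }))
  utils::write.csv(anova_tab, file.path(dir, "anova.csv"),
                   row.names = FALSE)
  utils::write.csv(res$one_sample, file.path(dir, "one_sample_t.csv"),
                   row.names = FALSE)
  reg_tab <- do.call(rbind, lapply(names(res$regressions), function(m) {
    s1 <- summarize_fit(res$regressions[[m]]$participant)
    s2 <- summarize_fit(res$regressions[[m]]$condition)
    s1$model <- m; s1$variant <- "participant"
    s2$model <- m; s2$variant <- "participant+condition"
    rbind(s1, s2)
  }))
  utils::write.csv(reg_tab, file.path(dir, "regressions.csv"),
                   row.names = FALSE)
  if (!is.null(res$loo))
    utils::write.csv(res$loo, file.path(dir, "loo_comparison.csv"),
                     row.names = FALSE)
  log <- c(sprintf("norminfer %s", as.character(utils::packageVersion("norminfer"))),
           sprintf("R %s", getRversion()),
           sprintf("experiment %d, seed %d", res$config$experiment,
                   res$config$seed),
           sprintf("generating model %s",
                   res$config$observer$generating_model),
           sprintf("mcmc: %d chains x %d iterations (%d warmup)",
                   res$config$chains, res$config$iter, res$config$warmup))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.norm_run <- function(x, ...) {
  cat(sprintf("Experiment %d pipeline run (%d participants, seed %d)\n",
              x$config$experiment, x$config$design$n_participants,
              x$config$seed))
  cat("\nRepeated-measures ANOVA:\n")
  for (ms in names(x$anova)) {
    cat(sprintf("  %-15s ", ms)); print(x$anova[[ms]])
  }
  cat("\nHierarchical regressions (participant random effects):\n")
  for (m in names(x$regressions)) {
    s <- summarize_fit(x$regressions[[m]]$participant)
    cat(sprintf("  %-6s beta = %.2f, 95%% CrI = [%.2f, %.2f], Pr(beta > 0) = %.2f%%\n",
                m, s$beta, s$cri_lower, s$cri_upper, s$pr_beta_gt_0))
  }
  if (!is.null(x$loo)) {
    cat("\nLOO comparison:\n")
    print(x$loo, digits = 4)
  }
  invisible(x)
}

#' Minimal condition-means plot
#'
#' Base-graphics summary of a measure's participant-level distribution per
#' condition (boxes) with the condition means overlaid.
#'
#' @param agg aggregated table.
#' @param measure measure to plot.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the participants x conditions matrix plotted.
#' @export
plot_condition_means <- function(agg, measure, ...) {
  w <- condition_matrix(agg, measure)
  graphics::boxplot(w, xlab = "condition", ylab = measure, ...)
  graphics::points(seq_len(ncol(w)), colMeans(w), pch = 19, col = "red3")
  invisible(w)
}
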