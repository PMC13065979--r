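#' Design of a slider experiment on norm inference
#'
#' Encodes the three within-participant designs: Experiment 1 manipulates the
#' number of norm-consistent behaviors (1-4 of 4 sample agents moving, the
#' rest static; 8 trials per condition, 32 trials), Experiments 2 and 3
#' manipulate the proportion of norm-consistent behaviors among four moving
#' agents (25/50/75/100%; 12 trials per condition, 48 trials). Experiment 3
#' additionally elicits desire judgments and the conditional probabilities
#' each causal model requires.
#'
#' @param experiment 1, 2 or 3.
#' @param n_participants number of synthetic observers (default 32).
#' @param trials_per_condition trials per condition; defaults to the design
#'   (8 for Experiment 1, 12 otherwise).
#' @param slider_step slider granularity on the probability scale; must
#'   divide 1 exactly (default 0.01, a percent-step 0-100% slider).
#' @param seed integer seed making generation deterministic.
#' @return an object of class `"experiment_design"`.
#' @export
experiment_design <- function(experiment, n_participants = 32,
                              trials_per_condition = NULL,
                              slider_step = 0.01, seed = 1L) {
  stopifnot(experiment %in% 1:3, n_participants >= 1)
  if (is.null(trials_per_condition))
    trials_per_condition <- if (experiment == 1) 8L else 12L
  conditions <- if (experiment == 1) 1:4 else c(0.25, 0.5, 0.75, 1)
  stopifnot(all(diff(conditions) > 0),
            abs(1 / slider_step - round(1 / slider_step)) < 1e-8)
  structure(list(experiment = as.integer(experiment),
                 n_participants = as.integer(n_participants),
                 trials_per_condition = as.integer(trials_per_condition),
                 conditions = conditions,
                 slider_step = slider_step,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Noise model of a synthetic observer
#'
#' A synthetic observer holds one generating causal model with
#' condition-dependent "true" conditional probabilities, and reports all
#' slider values with truncated-normal noise on the probability scale,
#' rounded to the slider grid: the prior around 0.5 (sd `sigma_prior`), each
#' elicited conditional around its true value (sd `sigma_elicit`), and the
#' final judgment around the generating model's posterior computed from that
#' trial's elicited values (sd `sigma_response`).
#'
#' @param generating_model `"BAYES"` or `"FREQ"` for Experiments 1-2;
#'   `"IE"`, `"FC"` or `"DM"` for Experiment 3.
#' @param sigma_prior,sigma_elicit,sigma_response noise standard deviations
#'   on the probability scale; all default 0.05.
#' @param true_cpt optional function `(condition, experiment) -> named list`
#'   of true CPT values; defaults to [default_true_cpt()].
#' @return an object of class `"observer_params"`.
#' @export
observer_params <- function(generating_model = "BAYES",
                            sigma_prior = 0.05, sigma_elicit = 0.05,
                            sigma_response = 0.05, true_cpt = NULL) {
  generating_model <- match.arg(generating_model,
                                c("BAYES", "FREQ", "IE", "FC", "DM"))
  stopifnot(sigma_prior >= 0, sigma_elicit >= 0, sigma_response >= 0)
  structure(list(generating_model = generating_model,
                 sigma_prior = sigma_prior, sigma_elicit = sigma_elicit,
                 sigma_response = sigma_response, true_cpt = true_cpt),
            class = "observer_params")
}

#' Default generating conditional probabilities
#'
#' The defaults encode the qualitative structure the designs require: the
#' likelihood of the observed behaviors given a norm rises with the
#' number/proportion of norm-consistent behaviors and exceeds the no-norm
#' likelihood at high prevalence, so that condition-mean posteriors rise with
#' the condition, dip below 0.5 only when deviants are in the majority
#' (proportion designs), and stay above 0.5 throughout the no-deviant count
#' design.
#'
#' @param model generating model identifier.
#' @param condition a count (Experiment 1) or proportion (Experiments 2-3).
#' @param experiment 1, 2 or 3.
#' @return named list of true CPT values for that condition.
#' @export
default_true_cpt <- function(model, condition, experiment) {
  prop <- if (experiment == 1) condition / 4 else condition
  act4 <- list(p_A_given_N_D = 0.15 + 0.80 * prop,
               p_A_given_N_notD = 0.05 + 0.75 * prop,
               p_A_given_notN_D = 0.55,
               p_A_given_notN_notD = 0.30)
  switch(model,
    BAYES = if (experiment == 1)
      list(p_A_given_N = 0.55 + 0.10 * condition, p_A_given_notN = 0.40)
    else
      list(p_A_given_N = 0.10 + 0.85 * prop, p_A_given_notN = 0.45),
    IE = c(list(p_D = 0.60), act4),
    FC = c(list(p_D_given_N = 0.70, p_D_given_notN = 0.40), act4),
    DM = list(p_D_given_N = 0.75, p_D_given_notN = 0.30,
              p_A_given_D = 0.15 + 0.80 * prop, p_A_given_notD = 0.35),
    FREQ = list(),
    stop("unknown generating model ", model, call. = FALSE))
}

# Full joint over (N, D, A) for a network with true prior p_N; rows named
# by the (n, d) cell, columns a = 1 / a = 0. BAYES has no D (2 x 2 joint).
.true_joint <- function(model, cpt, p_N = 0.5) {
  if (model == "BAYES") {
    pa <- c(cpt$p_A_given_N, cpt$p_A_given_notN)
    pn <- c(p_N, 1 - p_N)
    return(cbind(a1 = pn * pa, a0 = pn * (1 - pa)))
  }
  pn <- c(1, 1, 0, 0); pd <- c(1, 0, 1, 0)  # cells (n,d): 11,10,01,00
  p_n <- ifelse(pn == 1, p_N, 1 - p_N)
  p_d <- switch(model,
    IE = ifelse(pd == 1, cpt$p_D, 1 - cpt$p_D),
    FC = ,
    DM = {
      pdn <- ifelse(pn == 1, cpt$p_D_given_N, cpt$p_D_given_notN)
      ifelse(pd == 1, pdn, 1 - pdn)
    })
  p_a <- switch(model,
    IE = ,
    FC = c(cpt$p_A_given_N_D, cpt$p_A_given_N_notD,
           cpt$p_A_given_notN_D, cpt$p_A_given_notN_notD),
    DM = ifelse(pd == 1, cpt$p_A_given_D, cpt$p_A_given_notD))
  cell <- p_n * p_d
  cbind(a1 = cell * p_a, a0 = cell * (1 - p_a))
}

# True values of every elicited conditional, as conditionals of the
# generating joint. The observer holds ONE joint belief; items phrased for
# other factorizations are answered from that same joint.
.elicited_truths <- function(model, cpt, experiment, p_N = 0.5) {
  J <- .true_joint(model, cpt, p_N)
  if (model == "BAYES")
    return(list(p_A_given_N = cpt$p_A_given_N,
                p_A_given_notN = cpt$p_A_given_notN))
  pn <- c(1, 1, 0, 0); pd <- c(1, 0, 1, 0)
  pa1 <- J[, "a1"]; tot <- rowSums(J)
  cond <- function(mask) sum(pa1[mask]) / sum(tot[mask])
  p_d_marg <- sum(tot[pd == 1])
  out <- list(
    p_A_given_N = cond(pn == 1),
    p_A_given_notN = cond(pn == 0),
    prior_desire = p_d_marg,
    p_D_given_N = sum(tot[pn == 1 & pd == 1]) / sum(tot[pn == 1]),
    p_D_given_notN = sum(tot[pn == 0 & pd == 1]) / sum(tot[pn == 0]),
    p_A_given_N_D = pa1[1] / tot[1],
    p_A_given_N_notD = pa1[2] / tot[2],
    p_A_given_notN_D = pa1[3] / tot[3],
    p_A_given_notN_notD = pa1[4] / tot[4],
    p_A_given_D = cond(pd == 1),
    p_A_given_notD = cond(pd == 0))
  lapply(out, unname)
}

# Measures emitted per trial, by experiment. cpt:* names carry the entry.
.trial_measures <- function(experiment) {
  base <- c("prior_norm", "posterior_norm")
  if (experiment < 3)
    c(base, "p_A_given_N", "p_A_given_notN")
  else
    c(base, "prior_desire", "posterior_desire",
      "p_A_given_N", "p_A_given_notN",
      paste0("cpt:", c("p_D_given_N", "p_D_given_notN",
                       "p_A_given_N_D", "p_A_given_N_notD",
                       "p_A_given_notN_D", "p_A_given_notN_notD",
                       "p_A_given_D", "p_A_given_notD")))
}

# Build a network_spec for `model` out of one trial's elicited values.
.spec_from_elicited <- function(model, el) {
  cpt <- switch(model,
    BAYES = list(p_N = el[["prior_norm"]],
                 p_A_given_N = el[["p_A_given_N"]],
                 p_A_given_notN = el[["p_A_given_notN"]]),
    IE = list(p_N = el[["prior_norm"]], p_D = el[["prior_desire"]],
              p_A_given_N_D = el[["cpt:p_A_given_N_D"]],
              p_A_given_N_notD = el[["cpt:p_A_given_N_notD"]],
              p_A_given_notN_D = el[["cpt:p_A_given_notN_D"]],
              p_A_given_notN_notD = el[["cpt:p_A_given_notN_notD"]]),
    FC = list(p_N = el[["prior_norm"]],
              p_D_given_N = el[["cpt:p_D_given_N"]],
              p_D_given_notN = el[["cpt:p_D_given_notN"]],
              p_A_given_N_D = el[["cpt:p_A_given_N_D"]],
              p_A_given_N_notD = el[["cpt:p_A_given_N_notD"]],
              p_A_given_notN_D = el[["cpt:p_A_given_notN_D"]],
              p_A_given_notN_notD = el[["cpt:p_A_given_notN_notD"]]),
    DM = list(p_N = el[["prior_norm"]],
              p_D_given_N = el[["cpt:p_D_given_N"]],
              p_D_given_notN = el[["cpt:p_D_given_notN"]],
              p_A_given_D = el[["cpt:p_A_given_D"]],
              p_A_given_notD = el[["cpt:p_A_given_notD"]]))
  network_spec(model, cpt)
}

#' Generate a synthetic trial table
#'
#' Simulates every participant x trial of the design: the elicited prior, the
#' elicited conditional probabilities, the judgmental posterior (the
#' generating model's posterior evaluated on that trial's elicited values,
#' plus response noise) and, for Experiment 3, desire-related prior and
#' posterior judgments derived from the generating network's `P(D|A)`. All
#' values are truncated-normal draws rounded to the slider grid.
#'
#' @param design an [experiment_design()].
#' @param obs an [observer_params()]; the generating model must be BAYES or
#'   FREQ for Experiments 1-2 and a network (IE/FC/DM) for Experiment 3.
#' @return a long-format `data.frame` with columns `participant`,
#'   `experiment`, `condition`, `trial`, `measure`, `value` — one row per
#'   measure per trial, deterministic given `design$seed`.
#' @export
generate_experiment <- function(design, obs) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(obs, "observer_params"))
  gm <- obs$generating_model
  if (design$experiment < 3 && !gm %in% c("BAYES", "FREQ"))
    stop("Experiments 1-2 support generating models BAYES and FREQ",
         call. = FALSE)
  if (design$experiment == 3 && !gm %in% c("IE", "FC", "DM"))
    stop("Experiment 3 requires a network generating model (IE, FC, DM)",
         call. = FALSE)
  cpt_fun <- obs$true_cpt %||%
    function(cond, exp) default_true_cpt(gm, cond, exp)

  measures <- .trial_measures(design$experiment)
  elic_measures <- setdiff(measures,
    c("prior_norm", "posterior_norm", "posterior_desire"))
  step <- design$slider_step
  conds <- design$conditions
  tpc <- design$trials_per_condition
  n_trial <- length(conds) * tpc

  # per-condition elicitation truths (condition-dependent CPTs)
  truths <- lapply(conds, function(co) {
    if (gm == "FREQ") return(list())
    .elicited_truths(gm, cpt_fun(co, design$experiment), design$experiment)
  })
  names(truths) <- as.character(conds)

  set.seed(design$seed)
  rows <- vector("list", design$n_participants * n_trial)
  idx <- 0L
  # noise + grid rounding; sigma = 0 reports the value exactly (ideal
  # observer), keeping the noise-free table equal to the model output
  respond <- function(truth, sd)
    if (sd == 0) truth else round_grid(rtnorm01(truth, sd), step)
  for (p in seq_len(design$n_participants)) {
    trial_id <- 0L
    for (ci in seq_along(conds)) {
      co <- conds[ci]
      for (tr in seq_len(tpc)) {
        trial_id <- trial_id + 1L
        el <- list()
        el[["prior_norm"]] <- respond(0.5, obs$sigma_prior)
        for (m in elic_measures) {
          key <- sub("^cpt:", "", m)
          tv <- if (gm == "FREQ") 0.5 else truths[[ci]][[key]]
          el[[m]] <- respond(tv, obs$sigma_elicit)
        }
        if (gm == "FREQ") {
          k <- if (design$experiment == 1) co else co * 4
          y <- frequency_estimate(k, 4)
          el[["posterior_norm"]] <- respond(y, obs$sigma_response)
        } else {
          spec <- .spec_from_elicited(gm, el)
          y <- network_posterior(spec)
          el[["posterior_norm"]] <- respond(y, obs$sigma_response)
          if (design$experiment == 3) {
            yd <- desire_posterior(spec)
            el[["posterior_desire"]] <- respond(yd, obs$sigma_response)
          }
        }
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          participant = p, experiment = design$experiment, condition = co,
          trial = trial_id, measure = measures,
          value = unlist(el[measures], use.names = FALSE))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-trial belief-updating rows
#'
#' Computes the KL divergence between each trial's posterior and prior norm
#' belief (two-point distributions, nats) and appends the result as
#' `measure = "d_kl"` rows, so the aggregation and ANOVA layers treat belief
#' updating like any other measure.
#'
#' @param trials a trial table from [generate_experiment()] or
#'   [read_trials()].
#' @param eps clipping bound passed to [kl_update()].
#' @return the trial table with `d_kl` rows appended.
#' @export
add_kl_rows <- function(trials, eps = 1e-6) {
  w <- .trials_wide(trials, c("prior_norm", "posterior_norm"))
  d <- w[, c("participant", "experiment", "condition", "trial")]
  d$measure <- "d_kl"
  d$value <- kl_update(w$prior_norm, w$posterior_norm, eps)
  out <- rbind(trials, d)
  out[order(out$participant, out$trial), , drop = FALSE]
}

# reshape selected measures of a trial table to wide (one row per trial)
.trials_wide <- function(trials, measures) {
  sub <- trials[trials$measure %in% measures, , drop = FALSE]
  w <- stats::reshape(sub, direction = "wide",
                      idvar = c("participant", "experiment", "condition",
                                "trial"),
                      timevar = "measure", v.names = "value")
  names(w) <- sub("^value\\.", "", names(w))
  miss <- setdiff(measures, names(w))
  if (length(miss))
    stop("missing measures in trial table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  w
}

#' Aggregate trials to participant x condition means
#'
#' @param trials a long trial table (optionally with `d_kl` and model
#'   posterior rows added).
#' @param measures which measures to aggregate; defaults to all present.
#' @return a long `data.frame` with one row per participant x condition x
#'   measure holding the mean trial value. Incomplete cells (a participant
#'   missing a measure in some condition entirely) raise an error naming the
#'   cells.
#' @export
aggregate_by_condition <- function(trials, measures = NULL) {
  measures <- measures %||% unique(trials$measure)
  sub <- trials[trials$measure %in% measures, , drop = FALSE]
  agg <- stats::aggregate(value ~ participant + experiment + condition +
                            measure, data = sub, FUN = mean)
  counts <- table(agg$measure, agg$participant)
  n_cond <- length(unique(sub$condition))
  bad <- which(counts < n_cond, arr.ind = TRUE)
  if (nrow(bad))
    stop("incomplete cells for measure(s): ",
         paste(unique(rownames(counts)[bad[, 1]]), collapse = ", "),
         call. = FALSE)
  agg <- agg[order(agg$measure, agg$participant, agg$condition), ]
  rownames(agg) <- NULL
  agg
}

#' Per-trial model posteriors, aggregated for regression
#'
#' For each candidate model, computes the model-derived posterior from each
#' trial's elicited values (FREQ from the condition's tally), then averages
#' within participant x condition alongside the judgmental posterior.
#'
#' @param trials a trial table.
#' @param models character vector from `c("BAYES", "FREQ", "IE", "FC",
#'   "DM")`; networks require the Experiment 3 elicitations.
#' @return a wide `data.frame`: `participant`, `condition`, `judgment` (mean
#'   judgmental posterior) and one mean model-posterior column per model.
#' @export
model_posterior_table <- function(trials, models = c("BAYES", "FREQ")) {
  experiment <- unique(trials$experiment)
  stopifnot(length(experiment) == 1)
  models <- match.arg(models, c("BAYES", "FREQ", "IE", "FC", "DM"),
                      several.ok = TRUE)
  if (experiment < 3 && any(!models %in% c("BAYES", "FREQ")))
    stop("network models need the Experiment 3 elicitations", call. = FALSE)
  w <- .trials_wide(trials, .trial_measures(experiment))
  per_trial <- data.frame(participant = w$participant,
                          condition = w$condition,
                          judgment = w$posterior_norm)
  for (m in models) {
    per_trial[[m]] <- if (m == "FREQ") {
      k <- if (experiment == 1) w$condition else w$condition * 4
      frequency_estimate(k, 4)
    } else {
      el <- as.list(w)
      network_posterior(.spec_from_elicited(m, el))
    }
  }
  agg <- stats::aggregate(per_trial[, c("judgment", models), drop = FALSE],
                          by = per_trial[, c("participant", "condition")],
                          FUN = mean)
  agg[order(agg$participant, agg$condition), , drop = FALSE]
}
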