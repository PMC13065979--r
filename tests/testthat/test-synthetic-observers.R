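test_that("designs encode the three experiments", {
  d1 <- experiment_design(1)
  expect_equal(d1$conditions, 1:4)
  expect_equal(d1$trials_per_condition * length(d1$conditions), 32)
  d2 <- experiment_design(2)
  expect_equal(d2$conditions, c(0.25, 0.5, 0.75, 1))
  expect_equal(d2$trials_per_condition * length(d2$conditions), 48)
  expect_error(experiment_design(4), "experiment")
  expect_error(observer_params(sigma_prior = -0.1), "sigma_prior")
})

test_that("noise-free ideal observers reproduce the model posterior exactly", {
  d <- small_design(1, n = 4)
  obs <- observer_params("BAYES", sigma_prior = 0, sigma_elicit = 0,
                         sigma_response = 0)
  tr <- generate_experiment(d, obs)
  w <- tr[tr$measure %in% c("prior_norm", "posterior_norm", "p_A_given_N",
                            "p_A_given_notN"), ]
  for (id in unique(paste(w$participant, w$trial))) {
    rows <- w[paste(w$participant, w$trial) == id, ]
    v <- setNames(rows$value, rows$measure)
    expect_equal(v[["posterior_norm"]],
                 bayes_posterior(v[["prior_norm"]], v[["p_A_given_N"]],
                                 v[["p_A_given_notN"]]),
                 tolerance = 1e-12)
    expect_equal(v[["prior_norm"]], 0.5)  # sigma_prior = 0
  }
})

test_that("generation is deterministic given the seed and on the grid", {
  d <- small_design(2, n = 6, seed = 99)
  obs <- observer_params("BAYES")
  t1 <- generate_experiment(d, obs)
  t2 <- generate_experiment(d, obs)
  expect_identical(t1, t2)
  d2 <- small_design(2, n = 6, seed = 100)
  expect_false(identical(t1, generate_experiment(d2, obs)))
  # all values in [0,1] and on the percent grid
  expect_true(all(t1$value >= 0 & t1$value <= 1))
  expect_true(all(abs(t1$value * 100 - round(t1$value * 100)) < 1e-9))
})

test_that("condition-mean judgments rise with the condition under the defaults", {
  # Monte-Carlo property over seeds: the default generating CPTs give a
  # likelihood ratio monotone in condition, so mean posteriors are ordered
  for (seed in 1:20) {
    d <- experiment_design(1, seed = seed)
    tr <- generate_experiment(d, observer_params("BAYES"))
    post <- tr[tr$measure == "posterior_norm", ]
    mns <- tapply(post$value, post$condition, mean)
    expect_true(all(diff(mns) > 0),
                info = sprintf("seed %d: %s", seed,
                               paste(round(mns, 3), collapse = " ")))
  }
})

test_that("experiment 3 tables carry desire and CPT elicitations", {
  d <- small_design(3, n = 3)
  tr <- generate_experiment(d, observer_params("IE"))
  ms <- unique(tr$measure)
  expect_true(all(c("prior_desire", "posterior_desire",
                    "cpt:p_A_given_N_D", "cpt:p_D_given_N",
                    "cpt:p_A_given_D") %in% ms))
  # one row per measure per participant x trial
  counts <- table(tr$participant, tr$trial, tr$measure)
  expect_true(all(counts == 1))
  # generator restrictions by experiment
  expect_error(generate_experiment(small_design(1), observer_params("IE")),
               "BAYES and FREQ")
  expect_error(generate_experiment(small_design(3), observer_params("BAYES")),
               "network generating model")
})

test_that("noise-free experiment 3 elicitations are consistent conditionals of one joint", {
  d <- small_design(3, n = 2, trials_per_condition = 1)
  obs <- observer_params("FC", sigma_prior = 0, sigma_elicit = 0,
                         sigma_response = 0)
  tr <- generate_experiment(d, obs)
  one <- tr[tr$participant == 1 & tr$trial == 2, ]
  v <- setNames(one$value, one$measure)
  cpt <- default_true_cpt("FC", 0.5, 3)
  cpt$p_N <- 0.5
  # every elicited item equals the corresponding conditional of the
  # generating joint, via the enumeration oracle
  expect_equal(v[["cpt:p_A_given_D"]],
               {
                 j <- oracle_joint("FC", cpt)
                 sum(j$p[j$d == 1 & j$a == 1]) / sum(j$p[j$d == 1])
               }, tolerance = 1e-12)
  expect_equal(v[["prior_desire"]],
               cpt$p_N * cpt$p_D_given_N + (1 - cpt$p_N) * cpt$p_D_given_notN,
               tolerance = 1e-12)
  expect_equal(v[["posterior_desire"]],
               oracle_conditional("FC", cpt, "d", 1), tolerance = 1e-12)
  expect_equal(v[["posterior_norm"]],
               oracle_conditional("FC", cpt, "n", 1), tolerance = 1e-12)
})

test_that("aggregation means per cell and flags missing cells", {
  d <- small_design(1, n = 4)
  tr <- generate_experiment(d, observer_params("BAYES"))
  agg <- aggregate_by_condition(tr)
  # 4 participants x 4 conditions per measure
  expect_equal(sum(agg$measure == "posterior_norm"), 16)
  cell <- tr[tr$participant == 2 & tr$condition == 3 &
               tr$measure == "posterior_norm", "value"]
  expect_equal(agg[agg$participant == 2 & agg$condition == 3 &
                     agg$measure == "posterior_norm", "value"], mean(cell))
  # hand check on constant and two-point cells
  toy <- data.frame(participant = 1, experiment = 1,
                    condition = rep(1:2, each = 2), trial = 1:4,
                    measure = "posterior_norm", value = c(0.6, 0.6, 0.5, 0.7))
  a <- aggregate_by_condition(toy)
  expect_equal(a$value, c(0.6, 0.6))
  # dropping one cell entirely is an error, not silence
  broken <- tr[!(tr$participant == 1 & tr$condition == 1 &
                   tr$measure == "posterior_norm"), ]
  expect_error(aggregate_by_condition(broken), "incomplete")
})

test_that("per-trial KL rows aggregate like any measure", {
  d <- small_design(2, n = 3)
  tr <- generate_experiment(d, observer_params("BAYES"))
  trk <- add_kl_rows(tr)
  dk <- trk[trk$measure == "d_kl", ]
  expect_equal(nrow(dk), 3 * 16)
  expect_true(all(dk$value >= 0))
  w <- trk[trk$participant == 1 & trk$trial == 1, ]
  v <- setNames(w$value, w$measure)
  expect_equal(v[["d_kl"]],
               kl_update(v[["prior_norm"]], v[["posterior_norm"]]))
})

test_that("model posterior table averages per-trial model outputs", {
  d <- small_design(1, n = 3)
  tr <- generate_experiment(d, observer_params("BAYES"))
  mpt <- model_posterior_table(tr, c("BAYES", "FREQ"))
  expect_equal(nrow(mpt), 12)
  expect_equal(mpt$FREQ, rep(c(0.25, 0.5, 0.75, 1), 3))
  # BAYES column equals the mean of per-trial Eq-style updates
  w <- tr[tr$participant == 1 & tr$condition == 2, ]
  v <- split(setNames(w$value, w$measure), w$trial)
  xs <- vapply(v, function(tv)
    bayes_posterior(tv[["prior_norm"]], tv[["p_A_given_N"]],
                    tv[["p_A_given_notN"]]), numeric(1))
  expect_equal(mpt[mpt$participant == 1 & mpt$condition == 2, "BAYES"],
               mean(xs), tolerance = 1e-12)
  expect_error(model_posterior_table(tr, "IE"), "Experiment 3")
})
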