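test_that("single-step Bayes update matches hand evaluation and edge cases", {
  # uninformative likelihood leaves the prior untouched
  expect_equal(bayes_posterior(0.5, 0.8, 0.8), 0.5)
  # hand evaluation: 0.45 / (0.45 + 0.15)
  expect_equal(bayes_posterior(0.5, 0.9, 0.3), 0.75)
  # dogmatic prior is immovable (up to clipping)
  expect_equal(bayes_posterior(1, 0.2, 0.9), 1, tolerance = 1e-5)
  expect_equal(bayes_posterior(0, 0.9, 0.2), 0, tolerance = 1e-5)
  # vectorized
  expect_equal(bayes_posterior(c(0.5, 0.5), c(0.9, 0.8), c(0.3, 0.8)),
               c(0.75, 0.5))
  expect_error(bayes_posterior(0.5, 0, 0), "degenerate")
  expect_error(bayes_posterior(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("Bayes update is monotone in the likelihoods for interior priors", {
  set.seed(42)
  for (i in 1:200) {
    p <- runif(1, 0.05, 0.95)
    l1 <- sort(runif(2, 0.05, 0.95))
    l0 <- runif(1, 0.05, 0.95)
    expect_lt(bayes_posterior(p, l1[1], l0), bayes_posterior(p, l1[2], l0))
    expect_gt(bayes_posterior(p, l0, l1[1]), bayes_posterior(p, l0, l1[2]))
  }
})

test_that("KL belief updating matches direct evaluation in nats", {
  expect_equal(kl_update(0.7, 0.7), 0)
  expect_equal(kl_update(0.5, 0.75), 0.75 * log(1.5) + 0.25 * log(0.5),
               tolerance = 1e-10)
  expect_equal(kl_update(0.5, 0.75), 0.13081, tolerance = 1e-4)
  # limit under clipping: certain posterior from an even prior -> ln 2
  expect_equal(kl_update(0.5, 1), log(2), tolerance = 1e-4)
})

test_that("KL updating is non-negative and monotone in belief change", {
  set.seed(7)
  prior <- runif(300); post <- runif(300)
  d <- kl_update(prior, post)
  expect_true(all(d >= 0))
  expect_true(all(d[abs(prior - post) < 1e-12] == 0))
  # monotone in |posterior - prior| for fixed prior 0.5
  deltas <- seq(0, 0.49, by = 0.01)
  expect_true(all(diff(kl_update(0.5, 0.5 + deltas)) > 0))
  expect_true(all(diff(kl_update(0.5, 0.5 - deltas)) > 0))
})

test_that("network specs validate their structure's CPT entries", {
  expect_error(network_spec("IE", list(p_N = 0.5)), "missing CPT")
  expect_error(network_spec("DM", list(p_N = 0.5, p_D_given_N = 1,
                                       p_D_given_notN = 0, p_A_given_D = 1,
                                       p_A_given_notD = 0, extra = 0.5)),
               "unknown CPT")
  expect_error(network_spec("FREQ", list(p_N = 0.5)), "no CPT")
  expect_setequal(required_cpt_entries("DM"),
                  c("p_N", "p_D_given_N", "p_D_given_notN", "p_A_given_D",
                    "p_A_given_notD"))
})

test_that("network posteriors match hand-derived values", {
  ie <- network_spec("IE", list(p_N = 0.5, p_D = 0.5,
    p_A_given_N_D = 0.9, p_A_given_N_notD = 0.7,
    p_A_given_notN_D = 0.6, p_A_given_notN_notD = 0.1))
  expect_equal(network_posterior(ie), 0.8 / 1.15, tolerance = 1e-10)

  fc <- network_spec("FC", list(p_N = 0.5, p_D_given_N = 0.8,
    p_D_given_notN = 0.3, p_A_given_N_D = 0.9, p_A_given_N_notD = 0.6,
    p_A_given_notN_D = 0.7, p_A_given_notN_notD = 0.1))
  # P(A|N) = 0.84, P(A|notN) = 0.28
  expect_equal(network_posterior(fc), 0.75, tolerance = 1e-10)
  # P(D|A): joint cells (0.5*0.8*0.9 + 0.5*0.3*0.7) / 0.56
  expect_equal(desire_posterior(fc), 0.465 / 0.56, tolerance = 1e-10)

  dm <- network_spec("DM", list(p_N = 0.5, p_D_given_N = 0.8,
    p_D_given_notN = 0.3, p_A_given_D = 0.8, p_A_given_notD = 0.1))
  expect_equal(desire_posterior(dm), (0.55 * 0.8) / (0.55 * 0.8 + 0.45 * 0.1),
               tolerance = 1e-10)
  # mediator with no norm dependence transmits nothing: P(N|A) = P(N)
  dm_flat <- network_spec("DM", list(p_N = 0.35, p_D_given_N = 0.6,
    p_D_given_notN = 0.6, p_A_given_D = 0.9, p_A_given_notD = 0.2))
  expect_equal(network_posterior(dm_flat), 0.35, tolerance = 1e-10)
  # IE with action independent of desire: P(D|A) = P(D)
  ie_flat <- network_spec("IE", list(p_N = 0.5, p_D = 0.42,
    p_A_given_N_D = 0.8, p_A_given_N_notD = 0.8,
    p_A_given_notN_D = 0.3, p_A_given_notN_notD = 0.3))
  expect_equal(desire_posterior(ie_flat), 0.42, tolerance = 1e-10)
})

test_that("network posteriors agree with joint-table enumeration on random CPTs", {
  set.seed(11)
  for (model in c("IE", "FC", "DM")) {
    for (rep in 1:200) {
      cpt <- random_cpt(model)
      spec <- network_spec(model, cpt)
      for (a_obs in c(1, 0)) {
        expect_equal(network_posterior(spec, action_observed = a_obs == 1),
                     oracle_conditional(model, cpt, "n", a_obs),
                     tolerance = 1e-12)
        expect_equal(desire_posterior(spec, action_observed = a_obs == 1),
                     oracle_conditional(model, cpt, "d", a_obs),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("structural reductions connect the model family", {
  set.seed(3)
  for (rep in 1:50) {
    p_n <- runif(1, 0.05, 0.95)
    # IE with a degenerate desire equals the collapsed two-node update
    for (p_d in c(0, 1)) {
      a <- runif(4, 0.05, 0.95)
      ie <- network_spec("IE", list(p_N = p_n, p_D = p_d,
        p_A_given_N_D = a[1], p_A_given_N_notD = a[2],
        p_A_given_notN_D = a[3], p_A_given_notN_notD = a[4]))
      row <- if (p_d == 1) c(a[1], a[3]) else c(a[2], a[4])
      expect_equal(network_posterior(ie),
                   bayes_posterior(p_n, row[1], row[2]), tolerance = 1e-12)
    }
    # FC with desire cut loose from norms and actions desire-independent
    # collapses to the two-node update
    p_d <- runif(1, 0.05, 0.95)
    lik <- runif(2, 0.05, 0.95)
    fc <- network_spec("FC", list(p_N = p_n, p_D_given_N = p_d,
      p_D_given_notN = p_d, p_A_given_N_D = lik[1],
      p_A_given_N_notD = lik[1], p_A_given_notN_D = lik[2],
      p_A_given_notN_notD = lik[2]))
    expect_equal(network_posterior(fc), bayes_posterior(p_n, lik[1], lik[2]),
                 tolerance = 1e-12)
  }
})

test_that("frequency tracking returns the tally proportion only", {
  expect_equal(frequency_estimate(4, 4), 1)
  expect_equal(frequency_estimate(1, 4), 0.25)
  # attainable outputs over the four-agent designs are exactly four values
  expect_equal(sort(unique(frequency_estimate(1:4, 4))),
               c(0.25, 0.5, 0.75, 1))
  expect_error(frequency_estimate(5, 4), "k_consistent")
  expect_error(frequency_estimate(1, 0), "positive")
})
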