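test_that("posterior updating follows Bayes' rule and depends only on color counts", {
  s1 <- posterior_update(belief_state(0.5, 0), 1, test_jar)
  expect_equal(s1$p_jar_A, 0.8)
  expect_equal(s1$n_drawn, 1L)
  s2 <- posterior_update(s1, 1, test_jar)
  expect_equal(s2$p_jar_A, 16 / 17)
  # exchangeability: posterior depends on counts, not order
  seqs <- list(c(1, 1, 0, 1), c(1, 0, 1, 1), c(0, 1, 1, 1))
  finals <- vapply(seqs, function(bb) {
    s <- belief_state(0.5, 0)
    for (b in bb) s <- posterior_update(s, b, test_jar)
    s$p_jar_A
  }, 0)
  expect_equal(max(finals) - min(finals), 0)
  # closed form after k dominant beads: q^k / (q^k + (1-q)^k)
  q <- 0.8
  s <- belief_state(0.5, 0)
  for (k in 1:6) {
    s <- posterior_update(s, 1, test_jar)
    expect_equal(s$p_jar_A, q^k / (q^k + (1 - q)^k), tolerance = 1e-12)
  }
})

test_that("backward-induction action values match exhaustive expectimax enumeration", {
  cases <- expand.grid(horizon = 3:5, cost = c(0, 0.05, 0.2),
                       p = c(0.3, 0.5, 0.8), n = 0:1)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    got <- action_values(belief_state(cs$p, cs$n),
                         costed_bayes_params(cs$cost, 0.1),
                         test_jar, horizon = cs$horizon)
    want <- expectimax_values(cs$p, cs$n, cs$cost, test_jar, cs$horizon)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("terminal and free-information action values behave as the theory demands", {
  # at the horizon only declare actions exist, valued at the expected error cost
  av <- action_values(belief_state(0.9, 10), costed_bayes_params(0.05, 0.1), test_jar)
  expect_equal(unname(av), c(-0.1, -0.9))
  expect_false("draw" %in% names(av))
  # free information never hurts an optimal agent
  for (p in c(0.2, 0.5, 0.65, 0.9)) {
    av0 <- action_values(belief_state(p, 3), costed_bayes_params(0, 0.1), test_jar)
    expect_gte(av0[["draw"]], max(av0[["declare_A"]], av0[["declare_B"]]) - 1e-12)
  }
  expect_error(action_values(belief_state(0.5, 11), costed_bayes_params(0, 0.1),
                             test_jar), "beyond the horizon")
})

test_that("softmax choice probabilities normalize, respect temperature limits and symmetry", {
  expect_equal(choice_probabilities(c(a = 0, b = -1), 1),
               c(a = exp(0), b = exp(-1)) / (exp(0) + exp(-1)))
  # argmax limit at temperature 0
  expect_equal(unname(choice_probabilities(c(declare_A = -0.1, declare_B = -0.9,
                                             draw = -0.3), 0)), c(1, 0, 0))
  # equal values give uniform probabilities at positive temperature
  expect_equal(unname(choice_probabilities(c(a = -0.4, b = -0.4, c = -0.4), 0.7)),
               rep(1 / 3, 3))
  # declare ties at temperature 0 split uniformly
  expect_equal(unname(choice_probabilities(c(declare_A = -0.5, declare_B = -0.5), 0)),
               c(0.5, 0.5))
  expect_error(choice_probabilities(c(0, 1), -0.1), "decision_noise")
  # normalization across random value vectors and temperatures
  set.seed(8)
  for (i in 1:50) {
    p <- choice_probabilities(rnorm(3), runif(1, 0.01, 3))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
})

test_that("simulated agents respond to sampling cost in the deterministic limits", {
  free <- simulate_agent(costed_bayes_params(0, 0), test_pool, seed = 6)
  expect_equal(vapply(free, function(o) o$n_drawn, 0L), rep(10L, 5))
  costly <- simulate_agent(costed_bayes_params(5, 0), test_pool, seed = 7)
  expect_equal(vapply(costly, function(o) o$n_drawn, 0L), rep(1L, 5))
  # reproducible under seed; distinct sequences without replacement
  again <- simulate_agent(costed_bayes_params(5, 0), test_pool, seed = 7)
  expect_identical(vapply(again, function(o) o$block_id, 0L),
                   vapply(costly, function(o) o$block_id, 0L))
  expect_error(simulate_agent(costed_bayes_params(0, 0.1), test_pool,
                              n_blocks = 17, seed = 1), "pool size")
})

test_that("mean simulated draws decrease with the cost of sampling", {
  grid <- c(0, 0.05, 0.1, 0.2)
  means <- vapply(seq_along(grid), function(g) {
    mean(unlist(lapply(1:120, function(i) {
      obs <- simulate_agent(costed_bayes_params(grid[g], 0.1), test_pool,
                            seed = g * 10000 + i)
      vapply(obs, function(o) o$n_drawn, 0L)
    })))
  }, 0)
  expect_true(all(diff(means) <= 0))
})

test_that("the DTD log-likelihood composes per-decision softmax terms", {
  params <- costed_bayes_params(0.1, 0.3)
  s <- test_pool$sequences[[1]]
  obs <- list(dtd_observation(s, 1L, 1L, 1))
  # single block stopping at the first bead: only one decision point
  tab <- beadmodels:::dtd_value_table(0.1, test_jar, 10)
  lp <- beadmodels:::dtd_step_logprobs(tab, 1L, s$beads[1], 0.3, 10)
  expect_equal(dtd_loglik(params, obs, test_jar), unname(lp[1]))
  # and it equals log P(declare) + log P(chosen jar | declare)
  pr <- exp(lp)
  expect_equal(dtd_loglik(params, obs, test_jar),
               unname(log(pr[1] + pr[2]) + log(pr[1] / (pr[1] + pr[2]))),
               tolerance = 1e-12)
  # a zero-probability action under the argmax limit is a large finite penalty
  obs_bad <- list(dtd_observation(s, 1L, 2L, 1))  # declare the dominated jar
  ll0 <- dtd_loglik(costed_bayes_params(0.1, 0), obs_bad, test_jar)
  expect_true(is.finite(ll0))
  expect_lt(ll0, -100)
})

test_that("the likelihood is larger at the generating parameters than far away", {
  truth <- costed_bayes_params(0.2, 0.1)
  far <- costed_bayes_params(0.9, 1.0)
  diffs <- vapply(1:20, function(i) {
    obs <- simulate_agent(truth, test_pool, seed = 300 + i)
    dtd_loglik(truth, obs, test_jar) - dtd_loglik(far, obs, test_jar)
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("MAP fitting recovers simulated agents and is deterministic", {
  obs <- simulate_agent(costed_bayes_params(0.2, 0.1), test_pool, seed = 41)
  f1 <- fit_dtd(obs, test_jar)
  f2 <- fit_dtd(obs, test_jar)
  expect_true(f1$convergence)
  expect_equal(f1$params$cost_of_sampling, f2$params$cost_of_sampling, tolerance = 1e-8)
  expect_equal(f1$params$decision_noise, f2$params$decision_noise, tolerance = 1e-8)
  # cost-free behavior (always draws out the sequence) puts cost at the bottom
  obs10 <- blocks_with_draws(rep(10, 5), test_pool)
  f10 <- fit_dtd(obs10, test_jar)
  expect_lt(f10$params$cost_of_sampling, 0.02)
  # median recovery across replicate subjects stays within 25% of truth
  ests <- vapply(1:60, function(i) {
    o <- simulate_agent(costed_bayes_params(0.2, 0.1), test_pool, seed = 1000 + i)
    f <- fit_dtd(o, test_jar)
    c(f$params$cost_of_sampling, f$params$decision_noise)
  }, numeric(2))
  expect_lt(abs(median(ests[1, ]) - 0.2) / 0.2, 0.25)
  expect_lt(abs(median(ests[2, ]) - 0.1) / 0.1, 0.25)
})
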