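test_that("the filter step mixes through the switch probability and tempers the update", {
  # hand arithmetic: prior 0.8, r 0.1 -> predictive 0.74; Bayes with q = 0.8
  expect_equal(hmm_filter_step(0.8, 1, r_t = 0.1, a = 1, test_jar),
               0.8 * 0.74 / (0.8 * 0.74 + 0.2 * 0.26), tolerance = 1e-12)
  # r = 0, a = 1 reduces exactly to the static-jar Bayes update
  for (p in c(0.2, 0.5, 0.8)) {
    for (b in 0:1) {
      expect_equal(hmm_filter_step(p, b, 0, 1, test_jar),
                   posterior_update(belief_state(p, 0), b, test_jar)$p_jar_A,
                   tolerance = 1e-15)
    }
  }
  # r = 0.5 makes the predictive belief 0.5 regardless of the prior
  s1 <- hmm_filter_step(0.95, 1, 0.5, 1, test_jar)
  s2 <- hmm_filter_step(0.05, 1, 0.5, 1, test_jar)
  expect_equal(s1, s2, tolerance = 1e-15)
})

test_that("reversal re-estimation is the Beta posterior mean over the trailing window", {
  p <- hmm_params(0.1, 1, 10, 5, 10)
  # 5 transitions in window, expected switches 1 -> (10*0.1 + 1)/(10 + 5) = 2/15
  sp <- c(NA, rep(0.2, 5))
  expect_equal(reestimate_reversal(sp, 6, p), 2 / 15, tolerance = 1e-12)
  # infinitely confident prior never moves
  p_inf <- hmm_params(0.1, 1, Inf, 5, 10)
  expect_equal(reestimate_reversal(c(NA, runif(8)), 9, p_inf), 0.1)
  # all evidence against reversal with a weak prior drives r toward 0
  p_weak <- hmm_params(0.1, 1, 0.01, 5, 10)
  expect_lt(reestimate_reversal(c(NA, rep(1e-8, 9)), 10, p_weak), 1e-3)
  expect_error(reestimate_reversal(sp, 1, p), "t must be")
})

test_that("the full filter pass is consistent with its per-step operations", {
  params <- hmm_params(0.15, 0.8, 5, 4, 20)
  sq <- make_probest_sequence(test_jar, 30, 15, seed = 2)
  tr <- run_hmm_filter(params, sq)
  expect_equal(nrow(tr), 30)
  expect_true(all(tr$belief >= 0 & tr$belief <= 1))
  expect_true(all(tr$r >= 0 & tr$r <= 1))
  # the online r sequence is reproduced by reestimate_reversal
  for (t in 2:29) {
    expect_equal(reestimate_reversal(tr, t, params), tr$r[t + 1], tolerance = 1e-12)
  }
  # each belief is reproduced by hmm_filter_step
  b <- 0.5
  for (t in 1:30) {
    b <- hmm_filter_step(b, sq$beads[t], tr$r[t], params$a, test_jar)
    expect_equal(b, tr$belief[t], tolerance = 1e-12)
  }
  # switch probability equals r_t under uninformative evidence (b = 0.5 symmetric)
  expect_equal(switch_probability(0.5, 1, 0.123, 1, test_jar), 0.123, tolerance = 1e-12)
})

test_that("beliefs and reversal estimates stay in [0,1] across the parameter space", {
  set.seed(13)
  sq <- make_probest_sequence(test_jar, 30, 15, seed = 9)
  for (i in 1:25) {
    p <- hmm_params(runif(1, 0, 0.9), runif(1, 0.05, 1), exp(runif(1, log(0.2), log(100))),
                    sample(1:15, 1), exp(runif(1, log(1.1), log(200))))
    tr <- run_hmm_filter(p, sq)
    expect_true(all(tr$belief >= 0 & tr$belief <= 1))
    expect_true(all(tr$r >= 0 & tr$r <= 1))
    expect_true(all(tr$switch_prob >= 0 & tr$switch_prob <= 1))
  }
})

test_that("the Beta response model matches direct density evaluation and its limits", {
  # nu = 2 with predicted 0.5 is exactly Uniform(0,1)
  expect_equal(response_loglik(0.3, 0.5, 2), 0, tolerance = 1e-12)
  expect_equal(response_loglik(0.9, 0.5, 2), 0, tolerance = 1e-12)
  # closed-form Beta(7,3) check via log-gamma (independent of dbeta)
  lbeta_dens <- function(x, a, b) {
    lgamma(a + b) - lgamma(a) - lgamma(b) + (a - 1) * log(x) + (b - 1) * log(1 - x)
  }
  expect_equal(response_loglik(0.7, 0.7, 10), lbeta_dens(0.7, 7, 3), tolerance = 1e-12)
  expect_equal(response_loglik(0.2, 0.7, 10), lbeta_dens(0.2, 7, 3), tolerance = 1e-12)
  # density at the prediction increases with precision
  nus <- c(5, 20, 80, 320)
  dens <- vapply(nus, function(nu) response_loglik(0.7, 0.7, nu), 0)
  expect_true(all(diff(dens) > 0))
  expect_error(response_loglik(0.5, 0.5, -1), "nu")
  expect_error(response_loglik(1.5, 0.5, 2), "rating")
})

test_that("simulated responses are seeded Beta noise around the filter predictions", {
  params <- hmm_params(0.1, 0.9, 10, 5, 25)
  sq <- make_probest_sequence(test_jar, 30, 15, seed = 5)
  t1 <- simulate_responses(params, sq, seed = 100)
  t2 <- simulate_responses(params, sq, seed = 100)
  expect_identical(t1$ratings, t2$ratings)
  # noiseless limit reproduces the predictions exactly
  noiseless <- simulate_responses(hmm_params(0.1, 0.9, 10, 5, Inf), sq, seed = 1)
  expect_equal(noiseless$ratings, run_hmm_filter(hmm_params(0.1, 0.9, 10, 5, Inf), sq)$predicted)
  # volatile beliefs (high r0, weak confidence) move ratings more than stable ones
  jumps <- function(p) {
    mean(vapply(1:150, function(s) {
      r <- simulate_responses(p, sq, seed = s)$ratings
      mean(abs(diff(r)))
    }, 0))
  }
  expect_gt(jumps(hmm_params(0.45, 1, 0.5, 3, 50)),
            jumps(hmm_params(0.02, 1, 50, 3, 50)))
})

test_that("after the reversal the filter's prediction crosses to the other jar", {
  # hand-built sequence: 15 jar-A beads then a run of jar-B evidence
  beads <- c(rep(1L, 15), rep(0L, 15))
  sq <- bead_sequence(beads, c(rep(1L, 15), rep(2L, 15)), 15L)
  tr <- run_hmm_filter(hmm_params(0.1, 1, 10, 5, 50), sq)
  expect_true(all(tr$predicted[5:15] > 0.5))
  crossed <- which(tr$predicted < 0.5 & tr$trial > 15)
  expect_gt(length(crossed), 0)
  expect_lte(min(crossed), 20)  # crosses within a handful of disconfirming beads
})

test_that("model inversion recovers parameters and is deterministic", {
  params <- hmm_params(0.12, 0.85, 8, 4, 30)
  sq <- make_probest_sequence(test_jar, 30, 15, seed = 31)
  traj <- simulate_responses(params, sq, seed = 32)
  fit <- fit_hmm(traj)
  expect_true(fit$convergence)
  # the fitted log-likelihood equals the recomposed per-trial response terms
  tr <- run_hmm_filter(fit$params, sq)
  ll <- sum(response_loglik(pmin(pmax(traj$ratings, 1e-4), 1 - 1e-4),
                            tr$predicted, fit$params$nu))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
  # permuting the multi-start order does not change the estimate
  cfg <- hmm_fit_config()
  cfg2 <- cfg
  cfg2$starts <- cfg$starts[rev(seq_len(nrow(cfg$starts))), ]
  fit2 <- fit_hmm(traj, config = cfg2)
  expect_equal(fit$params$r0, fit2$params$r0, tolerance = 1e-6)
  expect_equal(fit$params$nu, fit2$params$nu, tolerance = 1e-6)
  expect_equal(fit$params$L, fit2$params$L)
})

test_that("degenerate ratings are flagged rather than silently fitted", {
  sq <- make_probest_sequence(test_jar, 30, 15, seed = 3)
  flat <- rating_trajectory(rep(0.5, 30), sq)
  fit <- fit_hmm(flat)
  expect_true(fit$flat_likelihood)
  extreme <- rating_trajectory(c(rep(1, 15), rep(0, 15)), sq)
  expect_warning(fit_hmm(extreme, config = hmm_fit_config(L_grid = c(2L, 5L))),
                 "clipped")
})
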