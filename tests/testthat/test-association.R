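test_that("categorization rules split, flag and transform as documented", {
  # strictly above the 85th empirical percentile of 1..100: exactly 15 flagged
  expect_equal(sum(categorize(1:100, categorization_rule("percentile-binary", 85))), 15L)
  expect_equal(sum(categorize(1:100, categorization_rule("percentile-binary", 95))), 5L)
  # tertiles of 1..9 split 3/3/3 with the middle tertile as reference
  f <- categorize(1:9, categorization_rule("tertile"))
  expect_equal(as.vector(table(f)[c("low", "mid", "high")]), c(3L, 3L, 3L))
  expect_equal(levels(f)[1], "mid")
  expect_equal(categorize(1, categorization_rule("identity-transform", transform = "log")), 0)
  expect_equal(categorize(0.5, categorization_rule("identity-transform", transform = "logit")), 0)
  expect_error(categorize(rep(2, 20), categorization_rule("percentile-binary", 85)),
               "constant")
  expect_error(categorization_rule("percentile-binary", 100), "cutoff")
})

test_that("logistic regression recovers a planted exposure effect with Wald inference", {
  set.seed(21)
  n <- 1e5
  x <- rbinom(n, 1, 0.3)
  ccov <- rnorm(n)
  y <- rbinom(n, 1, plogis(-3 + log(3.6) * x + 0.3 * ccov))
  dat <- data.frame(x = x, y = y, ccov = ccov)
  est <- fit_exposure_outcome(dat, "x", "y", "ccov", family = "logistic")
  expect_equal(est$scale, "OR")
  expect_lt(est$conf_low[1], 3.6)
  expect_gt(est$conf_high[1], 3.6)
  expect_lt(est$p_value[1], 1e-10)
  # CI brackets the point estimate
  expect_lt(est$conf_low[1], est$estimate[1])
  expect_gt(est$conf_high[1], est$estimate[1])
})

test_that("regression estimates agree with a hand-rolled IRLS reference to 6 decimals", {
  set.seed(5)
  n <- 400
  x <- rnorm(n)
  z <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x + 0.4 * z))
  dat <- data.frame(x = x, z = z, y = y)
  est <- fit_exposure_outcome(dat, "x", "y", "z", family = "logistic")
  # independent IRLS implementation (Fisher scoring for logistic regression)
  X <- cbind(1, x, z)
  beta <- rep(0, 3)
  for (it in 1:50) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    zresp <- eta + (y - mu) / W
    beta_new <- solve(t(X) %*% (W * X), t(X) %*% (W * zresp))
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  expect_equal(log(est$estimate[1]), unname(beta[2]), tolerance = 1e-6)
})

test_that("quadratic exposure terms are detected when planted", {
  set.seed(31)
  n <- 2e4
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0.1 * x + 0.3 * x^2))
  dat <- data.frame(x = x, y = y)
  est <- fit_exposure_outcome(dat, "x", "y", family = "logistic", quadratic = TRUE)
  expect_equal(nrow(est), 2L)
  qrow <- est[est$term == "x^2", ]
  expect_gt(qrow$conf_low, 1)  # OR scale: CI excludes the null
})

test_that("ordinal, multinomial and linear families report effects on their native scales", {
  set.seed(41)
  n <- 5000
  x <- rnorm(n)
  latent <- 0.8 * x + rlogis(n)
  yord <- cut(latent, c(-Inf, -1, 1, Inf), labels = c("low", "mid", "high"),
              ordered_result = TRUE)
  dat <- data.frame(x = x, yord = yord)
  esto <- fit_exposure_outcome(dat, "x", "yord", family = "ordinal")
  expect_equal(esto$scale, "OR")
  expect_equal(log(esto$estimate[1]), 0.8, tolerance = 0.15)
  # multinomial with a 3-level outcome
  dat$ymult <- factor(ifelse(latent > 1, "c", ifelse(latent > -1, "b", "a")))
  estm <- fit_exposure_outcome(dat, "x", "ymult", family = "multinomial")
  expect_true(all(estm$scale == "RRR"))
  expect_equal(nrow(estm), 2L)
  # linear
  dat$ylin <- 1.5 * x + rnorm(n)
  estl <- fit_exposure_outcome(dat, "x", "ylin", family = "linear")
  expect_equal(estl$estimate[1], 1.5, tolerance = 0.05)
  expect_equal(estl$scale, "beta")
})

test_that("blocked mediation paths give an exactly null indirect effect", {
  # exposure -> mediator slope exactly zero by construction (equal group means)
  dat <- data.frame(x = rep(c(0, 3), each = 4),
                    m = rep(c(0.2, 0.4, 0.6, 0.8), 2),
                    y = rep(c(0, 1), 4))
  # toy fixture: prevalence and bootstrap-separation warnings are expected
  est <- suppressWarnings(
    mediate_counterfactual(dat, "x", "m", "y", ci_method = "bootstrap",
                           n_boot = 10, seed = 1))
  expect_equal(unname(est$nie["estimate"]), 1.0, tolerance = 1e-12)
  expect_equal(est$percent_mediated, 0, tolerance = 1e-8)
})

test_that("mediation closed forms satisfy decomposition and invariance properties", {
  set.seed(61)
  n <- 3e4
  x <- sample(c(0, 3), n, replace = TRUE)
  m <- 0.5 + 0.1 * x + rnorm(n, 0, 0.4)
  y <- rbinom(n, 1, plogis(-3.5 + 0.3 * x + 0.5 * m))
  dat <- data.frame(x = x, m = m, y = y)
  est <- mediate_counterfactual(dat, "x", "m", "y", contrast = c(3, 0))
  # log-scale additivity of the decomposition
  expect_equal(log(est$total[["estimate"]]),
               log(est$nde[["estimate"]]) + log(est$nie[["estimate"]]),
               tolerance = 1e-8)
  # linear rescaling of the mediator leaves the decomposition unchanged
  dat2 <- transform(dat, m = 10 * m - 3)
  est2 <- mediate_counterfactual(dat2, "x", "m", "y", contrast = c(3, 0))
  expect_equal(est2$nie[["estimate"]], est$nie[["estimate"]], tolerance = 1e-8)
  expect_equal(est2$percent_mediated, est$percent_mediated, tolerance = 1e-6)
  # exchanging the exposure contrast inverts the odds ratios
  est_rev <- mediate_counterfactual(dat, "x", "m", "y", contrast = c(0, 3))
  expect_equal(est_rev$nde[["estimate"]], 1 / est$nde[["estimate"]], tolerance = 1e-8)
  expect_equal(est_rev$nie[["estimate"]], 1 / est$nie[["estimate"]], tolerance = 1e-8)
})

test_that("binary mediators route to the binary closed form and prevalence is checked", {
  set.seed(71)
  n <- 2e4
  x <- sample(c(0, 3), n, replace = TRUE)
  m <- rbinom(n, 1, plogis(-1 + 0.3 * x))
  y <- rbinom(n, 1, plogis(-3.5 + 0.25 * x + 0.6 * m))
  dat <- data.frame(x = x, m = m, y = y)
  est <- mediate_counterfactual(dat, "x", "m", "y", n_boot = 30, seed = 2)
  expect_true(est$binary_mediator)
  expect_gt(est$nie[["estimate"]], 1)
  ycommon <- rbinom(n, 1, 0.4)
  dat$ycommon <- ycommon
  expect_warning(mediate_counterfactual(dat, "x", "m", "ycommon",
                                        n_boot = 5, seed = 3), "prevalence")
})
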