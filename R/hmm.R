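#' Parameters of the retrospective-inference hidden Markov model
#'
#' The probability-estimation task is treated as joint inference (which jar is
#' the current source) and parameter learning (how often the jar switches).
#' Five subject-level parameters govern the model:
#' * `r0` — initial subjective per-trial reversal probability;
#' * `a` — adjustment rate: each bead's emission likelihood is raised to the
#'   power `a` before the Bayes update (a = 1 is full Bayesian adjustment,
#'   a < 1 under-adjustment), akin to a learning rate;
#' * `kappa` — confidence in `r0`: the concentration of a Beta prior on the
#'   reversal probability; large `kappa` means the initial estimate is barely
#'   revised during the task;
#' * `L` — window length: the number of trailing trial transitions used to
#'   re-estimate the reversal probability online;
#' * `nu` — response precision: slider ratings are Beta-distributed around the
#'   model's predicted probability with precision `nu` (response noise is
#'   conventionally reported as 1/nu).
#'
#' @param r0 Initial reversal probability in \[0, 1) (0 = never-switching limit).
#' @param a Adjustment rate in (0, 1].
#' @param kappa Confidence (Beta concentration) > 0; `Inf` pins the reversal
#'   estimate at `r0`.
#' @param L Window length, integer >= 1.
#' @param nu Response precision > 0; `Inf` gives noiseless reporting.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(r0, a, kappa, L, nu) {
  if (!is.numeric(r0) || r0 < 0 || r0 >= 1) stop("r0 must lie in [0, 1)")
  if (!is.numeric(a) || a <= 0 || a > 1) stop("a must lie in (0, 1]")
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  if (!is.numeric(nu) || nu <= 0) stop("nu must be > 0")
  structure(list(r0 = as.numeric(r0), a = as.numeric(a),
                 kappa = as.numeric(kappa), L = L, nu = as.numeric(nu)),
            class = "hmm_params")
}

#' One filtering step of the reversal-learning model
#'
#' Mixes the prior belief through the subjective switch probability, then
#' applies a Bayes update with the emission likelihoods tempered by the
#' adjustment rate:
#' predictive = (1 - r_t) * prior + r_t * (1 - prior);
#' posterior proportional to predictive * P(bead | jar)^a.
#'
#' @param prior_belief Probability that the current source is jar A, before
#'   this bead.
#' @param bead_color Observed color (0 or 1).
#' @param r_t Subjective reversal probability on this trial, in [0, 1].
#' @param a Adjustment rate in (0, 1].
#' @param jar A [jar_spec()].
#' @return The filtered posterior probability of jar A.
#' @examples
#' hmm_filter_step(0.8, 1, r_t = 0.1, a = 1, jar_spec(0.8))  # ~0.919
#' @export
hmm_filter_step <- function(prior_belief, bead_color, r_t, a, jar) {
  stopifnot(inherits(jar, "jar_spec"))
  if (prior_belief < 0 || prior_belief > 1) stop("prior_belief must lie in [0, 1]")
  if (r_t < 0 || r_t > 1) stop("r_t must lie in [0, 1]")
  if (a <= 0 || a > 1) stop("a must lie in (0, 1]")
  pred <- (1 - r_t) * prior_belief + r_t * (1 - prior_belief)
  lA <- emission_prob(bead_color, 1L, jar)^a
  lB <- emission_prob(bead_color, 2L, jar)^a
  z <- pred * lA + (1 - pred) * lB
  if (z <= 0) stop("zero normalizer in filter step")
  pred * lA / z
}

#' Retrospective probability that the jar switched at a transition
#'
#' The two-slice transition posterior of the hidden Markov model:
#' the probability, given the belief before the transition and the bead just
#' seen, that the hidden jar switched at this transition. With subjective
#' switch probability `r_t` and tempered emission likelihoods
#' lA = P(bead | A)^a, lB = P(bead | B)^a,
#' P(switch) = r (b lB + (1-b) lA) / \[(1-r)(b lA + (1-b) lB) + r (b lB + (1-b) lA)\]
#' where b is the pre-transition belief in jar A. Under uninformative evidence
#' this equals `r_t` exactly, so the online reversal estimate moves away from
#' its prior only when the data indicate a reversal.
#'
#' @param b_prev Filtered belief in jar A before the transition.
#' @param bead_color Bead observed after the transition (0 or 1).
#' @param r_t Subjective reversal probability on this trial.
#' @param a Adjustment rate (likelihood-tempering exponent).
#' @param jar A [jar_spec()].
#' @return P(jar switched at this transition | data).
#' @export
switch_probability <- function(b_prev, bead_color, r_t, a, jar) {
  stopifnot(inherits(jar, "jar_spec"))
  lA <- emission_prob(bead_color, 1L, jar)^a
  lB <- emission_prob(bead_color, 2L, jar)^a
  stay <- (1 - r_t) * (b_prev * lA + (1 - b_prev) * lB)
  sw <- r_t * (b_prev * lB + (1 - b_prev) * lA)
  sw / (stay + sw)
}

#' Online re-estimation of the reversal probability
#'
#' After trial t the reversal probability is re-estimated as the posterior
#' mean of a Beta prior with mean `r0` and concentration `kappa`, updated with
#' the expected number of switches over the trailing `min(L, t - 1)` trial
#' transitions (the per-transition [switch_probability()] values):
#' r = (kappa * r0 + expected switches) / (kappa + window transitions).
#' The re-estimated value is used on trial t + 1.
#'
#' @param traj A `belief_trajectory` from [run_hmm_filter()] (its
#'   `switch_prob` column holds the per-transition switch probabilities), or a
#'   plain numeric vector of switch probabilities indexed by the trial they
#'   lead into (element 1 unused).
#' @param t Trial index (>= 2) after which to re-estimate.
#' @param params An [hmm_params()].
#' @return The re-estimated reversal probability.
#' @examples
#' # 5 transitions in window with expected switches 1, r0 = 0.1, kappa = 10:
#' # r = (10 * 0.1 + 1) / (10 + 5) = 2/15
#' sp <- c(NA, rep(0.2, 5))
#' reestimate_reversal(sp, 6, hmm_params(0.1, 1, 10, 5, 10))
#' @export
reestimate_reversal <- function(traj, t, params) {
  stopifnot(inherits(params, "hmm_params"))
  sp <- if (is.data.frame(traj)) traj$switch_prob else as.numeric(traj)
  t <- as.integer(t)
  if (t < 2L) stop("t must be >= 2")
  if (length(sp) < t) stop("switch probabilities must cover trials 1..t")
  if (is.infinite(params$kappa)) return(params$r0)
  w <- min(params$L, t - 1L)
  idx <- (t - w + 1L):t
  (params$kappa * params$r0 + sum(sp[idx])) / (params$kappa + w)
}

# Deterministic filter pass over a whole bead sequence. Returns per-trial
# filtered belief, the reversal estimate in force on each trial, and the
# predicted rating. The loop keeps a running window sum so the pass is O(n).
run_hmm_filter_core <- function(beads, q, r0, a, kappa, L) {
  n <- length(beads)
  lA <- ifelse(beads == 1L, q, 1 - q)^a
  lB <- ifelse(beads == 1L, 1 - q, q)^a
  belief <- numeric(n)
  rvec <- numeric(n)
  sp <- numeric(n)
  b_prev <- 0.5
  r <- r0
  wsum <- 0
  fixed_r <- is.infinite(kappa)
  for (t in seq_len(n)) {
    rvec[t] <- r
    pred <- (1 - r) * b_prev + r * (1 - b_prev)
    num <- pred * lA[t]
    b <- num / (num + (1 - pred) * lB[t])
    belief[t] <- b
    if (t >= 2L) {
      # two-slice transition posterior: P(jar switched at this transition),
      # retrospective inference from the previous belief and current evidence
      stay <- (1 - r) * (b_prev * lA[t] + (1 - b_prev) * lB[t])
      sw <- r * (b_prev * lB[t] + (1 - b_prev) * lA[t])
      s <- sw / (stay + sw)
      sp[t] <- s
      if (!fixed_r) {
        wsum <- wsum + s
        if (t - 1L > L) wsum <- wsum - sp[t - L]
        r <- (kappa * r0 + wsum) / (kappa + min(L, t - 1L))
      }
    }
    b_prev <- b
  }
  list(belief = belief, r = rvec, switch_prob = sp)
}

#' Run the reversal-learning filter over a bead sequence
#'
#' Applies [hmm_filter_step()] trial by trial, re-estimating the reversal
#' probability after each trial (from trial 2 on) via [reestimate_reversal()];
#' the updated estimate is used on the next trial. The initial belief is 0.5.
#'
#' @param params An [hmm_params()].
#' @param sequence A [bead_sequence()].
#' @param jar A [jar_spec()].
#' @return A data frame (class `belief_trajectory`) with columns `trial`,
#'   `bead`, `belief` (filtered posterior of jar A), `r` (reversal estimate in
#'   force on the trial) and `predicted` (predicted rating, belief clipped to
#'   the interior of [0, 1]).
#' @export
run_hmm_filter <- function(params, sequence, jar = jar_spec()) {
  stopifnot(inherits(params, "hmm_params"), inherits(sequence, "bead_sequence"),
            inherits(jar, "jar_spec"))
  core <- run_hmm_filter_core(sequence$beads, jar$dominant_fraction,
                              params$r0, params$a, params$kappa, params$L)
  out <- data.frame(trial = seq_along(sequence$beads), bead = sequence$beads,
                    belief = core$belief, r = core$r,
                    switch_prob = core$switch_prob,
                    predicted = predict_rating(core$belief))
  class(out) <- c("belief_trajectory", class(out))
  out
}

#' Map a filtered belief onto the slider scale
#'
#' The predicted rating is the filtered posterior itself, clipped to the
#' interior of [0, 1] so that the Beta response density is well defined.
#'
#' @param belief Probability (or vector of probabilities) in [0, 1].
#' @param eps Interior clipping boundary (default 1e-4).
#' @return The predicted rating(s).
#' @export
predict_rating <- function(belief, eps = 1e-4) {
  if (any(belief < 0 | belief > 1)) stop("belief must lie in [0, 1]")
  clip01(belief, eps)
}

#' Log-density of a slider rating under the Beta response model
#'
#' Ratings are Beta-distributed with mean equal to the predicted rating and
#' precision `nu`: shape parameters `predicted * nu` and `(1 - predicted) * nu`.
#' With nu = 2 and predicted 0.5 this is exactly Uniform(0, 1); larger nu
#' concentrates the density at the prediction. Ratings and predictions are
#' clipped to the interior of [0, 1].
#'
#' @param rating Observed rating(s) in [0, 1].
#' @param predicted Predicted rating(s) in [0, 1].
#' @param nu Response precision > 0 (finite).
#' @param eps Interior clipping boundary.
#' @return Log-density value(s).
#' @export
response_loglik <- function(rating, predicted, nu, eps = 1e-4) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0) {
    stop("nu must be a single finite number > 0")
  }
  if (any(rating < 0 | rating > 1) || any(predicted < 0 | predicted > 1)) {
    stop("rating and predicted must lie in [0, 1]")
  }
  r <- clip01(rating, eps)
  m <- clip01(predicted, eps)
  stats::dbeta(r, m * nu, (1 - m) * nu, log = TRUE)
}

#' Simulate slider responses on the probability-estimation task
#'
#' Runs the filter with online reversal re-estimation over the bead sequence,
#' then samples each trial's rating from the Beta response distribution around
#' the predicted rating. With `nu = Inf` the ratings equal the predictions.
#'
#' @param params An [hmm_params()].
#' @param sequence A [bead_sequence()].
#' @param seed Integer seed.
#' @param jar A [jar_spec()].
#' @return A [rating_trajectory()].
#' @export
simulate_responses <- function(params, sequence, seed = NULL, jar = jar_spec()) {
  traj <- run_hmm_filter(params, sequence, jar)
  m <- traj$predicted
  ratings <- if (is.infinite(params$nu)) {
    m
  } else {
    # clip draws to the interior of [0,1]: the response density lives there,
    # and extreme Beta draws can underflow to exactly 0 or 1
    clip01(with_seed(seed, stats::rbeta(length(m), m * params$nu,
                                        (1 - m) * params$nu)), 1e-4)
  }
  rating_trajectory(ratings, sequence)
}

#' Fitting configuration for the reversal-learning model
#'
#' @param L_grid Integer grid for the window length profile (default 1..15).
#' @param r0_bounds,a_bounds,kappa_bounds,nu_bounds Natural-scale bounds for
#'   the continuous parameters.
#' @param starts Data frame of natural-scale starting values for
#'   (r0, a, kappa, nu); default is a fixed 3-point set.
#' @param prior_sd Standard deviation of the weak normal priors on the
#'   transformed (logit/log) scales.
#' @param prior_center Natural-scale centers of those priors.
#' @return A list of class `hmm_fit_config`.
#' @export
hmm_fit_config <- function(L_grid = 1:15,
                           r0_bounds = c(0.002, 0.9),
                           a_bounds = c(0.05, 0.999),
                           kappa_bounds = c(0.1, 200),
                           nu_bounds = c(1.05, 500),
                           starts = NULL,
                           prior_sd = 1,
                           prior_center = c(r0 = 0.2, a = 0.7, kappa = 7, nu = 14)) {
  if (is.null(starts)) {
    starts <- data.frame(r0 = c(0.08, 0.3, 0.15),
                         a = c(0.9, 0.5, 0.7),
                         kappa = c(15, 3, 40),
                         nu = c(8, 40, 15))
  }
  structure(list(L_grid = as.integer(L_grid),
                 r0_bounds = r0_bounds, a_bounds = a_bounds,
                 kappa_bounds = kappa_bounds, nu_bounds = nu_bounds,
                 starts = starts, prior_sd = prior_sd,
                 prior_center = prior_center),
            class = "hmm_fit_config")
}

# Negative log posterior for the continuous parameters at a fixed window
# length. theta = (logit r0, logit a, log kappa, log nu).
hmm_negpost <- function(theta, L, beads, ratings, q, config) {
  r0 <- inv_logit(theta[1])
  a <- inv_logit(theta[2])
  kappa <- exp(theta[3])
  nu <- exp(theta[4])
  core <- run_hmm_filter_core(beads, q, r0, a, kappa, L)
  m <- clip01(core$belief, 1e-4)
  ll <- sum(stats::dbeta(ratings, m * nu, (1 - m) * nu, log = TRUE))
  ctr <- config$prior_center
  lp <- stats::dnorm(theta[1], logit(ctr[["r0"]]), config$prior_sd, log = TRUE) +
        stats::dnorm(theta[2], logit(ctr[["a"]]), config$prior_sd, log = TRUE) +
        stats::dnorm(theta[3], log(ctr[["kappa"]]), config$prior_sd, log = TRUE) +
        stats::dnorm(theta[4], log(ctr[["nu"]]), config$prior_sd, log = TRUE)
  v <- -(ll + lp)
  if (!is.finite(v)) v <- 1e10
  v
}

#' Fit the reversal-learning model to one subject's rating trajectory
#'
#' Maximum a posteriori estimation: the four continuous parameters are
#' optimized by multi-start L-BFGS-B on logit/log-transformed scales under
#' weak normal priors; the integer window length is profiled over a bounded
#' grid. Ratings exactly at 0 or 1 are clipped to the interior (with a
#' warning) before the Beta likelihood is evaluated.
#'
#' @param traj A [rating_trajectory()].
#' @param config An [hmm_fit_config()].
#' @param jar A [jar_spec()].
#' @return A list with `params` ([hmm_params()]), `loglik` (data
#'   log-likelihood at the estimate), `logpost`, `convergence`,
#'   `L_profile` (best objective per window length) and `flat_likelihood`
#'   (`TRUE` when the data barely constrain the fit).
#' @export
fit_hmm <- function(traj, config = hmm_fit_config(), jar = jar_spec()) {
  stopifnot(inherits(traj, "rating_trajectory"))
  beads <- traj$sequence$beads
  ratings <- traj$ratings
  if (any(ratings <= 0 | ratings >= 1)) {
    warning("ratings at 0 or 1 clipped to the interior for the Beta likelihood")
  }
  ratings <- clip01(ratings, 1e-4)
  q <- jar$dominant_fraction
  lb <- c(logit(config$r0_bounds[1]), logit(config$a_bounds[1]),
          log(config$kappa_bounds[1]), log(config$nu_bounds[1]))
  ub <- c(logit(config$r0_bounds[2]), logit(config$a_bounds[2]),
          log(config$kappa_bounds[2]), log(config$nu_bounds[2]))
  starts <- config$starts
  theta0s <- lapply(seq_len(nrow(starts)), function(i) {
    pmin(pmax(c(logit(starts$r0[i]), logit(starts$a[i]),
                log(starts$kappa[i]), log(starts$nu[i])), lb), ub)
  })
  best <- NULL
  best_L <- NA_integer_
  any_conv <- FALSE
  L_profile <- stats::setNames(rep(NA_real_, length(config$L_grid)),
                               config$L_grid)
  for (L in config$L_grid) {
    bL <- NULL
    for (th0 in theta0s) {
      fit <- try(stats::optim(th0, hmm_negpost, method = "L-BFGS-B",
                              lower = lb, upper = ub,
                              L = L, beads = beads, ratings = ratings,
                              q = q, config = config,
                              control = list(maxit = 300)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (fit$convergence == 0) any_conv <- TRUE
      if (is.null(bL) || fit$value < bL$value) bL <- fit
    }
    if (is.null(bL)) next
    L_profile[as.character(L)] <- -bL$value
    if (is.null(best) || bL$value < best$value) {
      best <- bL
      best_L <- L
    }
  }
  if (is.null(best)) stop("all optimization starts failed")
  th <- best$par
  est <- hmm_params(inv_logit(th[1]), inv_logit(th[2]), exp(th[3]),
                    best_L, exp(th[4]))
  core <- run_hmm_filter_core(beads, q, est$r0, est$a, est$kappa, est$L)
  m <- clip01(core$belief, 1e-4)
  ll <- sum(stats::dbeta(ratings, m * est$nu, (1 - m) * est$nu, log = TRUE))
  # near-uniform fitted response model => the data barely constrain the fit
  flat <- est$nu < 1.2 || stats::sd(ratings) < 1e-6
  list(params = est, loglik = ll, logpost = -best$value,
       convergence = any_conv, L_profile = L_profile,
       flat_likelihood = flat)
}
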