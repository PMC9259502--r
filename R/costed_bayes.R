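#' Parameters of the costed Bayesian draws-to-decision model
#'
#' The model assumes a Bayes-optimal observer who, after each bead, chooses
#' between declaring jar A, declaring jar B, or drawing again. Declaring
#' carries an expected error cost (the cost of a wrong choice is normalized to
#' 1); each further draw carries `cost_of_sampling`. Action selection is a
#' softmax over action values with temperature `decision_noise`, applied at
#' every draw/declare choice point and to the final jar choice.
#'
#' @param cost_of_sampling Per-draw cost, relative to a unit cost of a wrong
#'   final choice; finite and >= 0.
#' @param decision_noise Softmax temperature; finite and >= 0 (0 = deterministic
#'   argmax with ties split uniformly).
#' @return An object of class `costed_bayes_params`.
#' @export
costed_bayes_params <- function(cost_of_sampling, decision_noise) {
  if (!is.finite(cost_of_sampling) || cost_of_sampling < 0) {
    stop("cost_of_sampling must be finite and >= 0")
  }
  if (!is.finite(decision_noise) || decision_noise < 0) {
    stop("decision_noise must be finite and >= 0")
  }
  structure(list(cost_of_sampling = as.numeric(cost_of_sampling),
                 decision_noise = as.numeric(decision_noise)),
            class = "costed_bayes_params")
}

#' Belief state of the ideal observer
#'
#' @param p_jar_A Posterior probability that the source is jar A, in [0, 1].
#' @param n_drawn Number of beads seen so far (0..10).
#' @return An object of class `belief_state`.
#' @export
belief_state <- function(p_jar_A = 0.5, n_drawn = 0L) {
  if (!is.finite(p_jar_A) || p_jar_A < 0 || p_jar_A > 1) {
    stop("p_jar_A must lie in [0, 1]")
  }
  structure(list(p_jar_A = as.numeric(p_jar_A), n_drawn = as.integer(n_drawn)),
            class = "belief_state")
}

#' Bayes-optimal posterior update after one bead
#'
#' Applies Bayes' rule with the jars' emission probabilities q and 1 - q and
#' increments the draw count. The posterior depends only on the counts of each
#' color seen, not their order.
#'
#' @param state A [belief_state()].
#' @param bead_color Observed color (0 or 1; color 1 is jar A's dominant color).
#' @param jar A [jar_spec()].
#' @return The updated [belief_state()].
#' @examples
#' s <- posterior_update(belief_state(0.5, 0), 1, jar_spec(0.8))
#' s$p_jar_A  # 0.8
#' @export
posterior_update <- function(state, bead_color, jar) {
  stopifnot(inherits(state, "belief_state"), inherits(jar, "jar_spec"))
  if (!bead_color %in% c(0, 1)) stop("bead_color must be 0 or 1")
  p <- state$p_jar_A
  lA <- emission_prob(bead_color, 1L, jar)
  lB <- emission_prob(bead_color, 2L, jar)
  post <- p * lA / (p * lA + (1 - p) * lB)
  belief_state(post, state$n_drawn + 1L)
}

# Backward-induction value tables anchored at an arbitrary belief state.
#
# From a current posterior p0 after n0 draws, future states are indexed by
# (j, k): j more beads seen, k of them color 1. Terminal states (at the
# horizon) allow only declaring; the optimal value there is -min(p, 1 - p).
# Before the horizon, the draw value is -cost plus the predictive expectation
# of the optimal continuation value. Returns, for each future layer j, the
# posteriors and the optimal and draw values over k = 0..j.
dtd_backward <- function(p0, n0, cost, jar, horizon) {
  q <- jar$dominant_fraction
  m <- horizon - n0
  lr <- q / (1 - q)  # likelihood ratio contributed by one color-1 bead
  odds0 <- p0 / (1 - p0)
  post <- vector("list", m + 1L)   # posteriors, layer j has j + 1 entries
  vopt <- vector("list", m + 1L)   # optimal value at each state
  vdraw <- vector("list", m + 1L)  # value of drawing (NA at the horizon)
  for (j in 0:m) {
    k <- 0:j
    if (is.finite(odds0) && odds0 > 0) {
      lodds <- log(odds0) + (2 * k - j) * log(lr)
      post[[j + 1L]] <- 1 / (1 + exp(-lodds))
    } else {
      post[[j + 1L]] <- rep(p0, j + 1L)  # degenerate belief stays degenerate
    }
  }
  p_m <- post[[m + 1L]]
  vopt[[m + 1L]] <- -pmin(p_m, 1 - p_m)
  vdraw[[m + 1L]] <- rep(NA_real_, m + 1L)
  if (m > 0) {
    for (j in (m - 1L):0) {
      p <- post[[j + 1L]]
      pd1 <- p * q + (1 - p) * (1 - q)  # marginal predictive of color 1
      vnext <- vopt[[j + 2L]]
      vd <- -cost + pd1 * vnext[2:(j + 2L)] + (1 - pd1) * vnext[1:(j + 1L)]
      vdraw[[j + 1L]] <- vd
      vopt[[j + 1L]] <- pmax(-pmin(p, 1 - p), vd)
    }
  }
  list(post = post, vopt = vopt, vdraw = vdraw, m = m)
}

#' Action values under the costed Bayesian model
#'
#' Values of declaring jar A, declaring jar B, and (before the horizon)
#' drawing another bead. Declare values are the negative expected error cost,
#' -(1 - posterior of the declared jar). The draw value is the sampling cost
#' plus the marginal-predictive expectation of the optimal continuation value,
#' computed by backward induction from the horizon.
#'
#' @param state A [belief_state()] with `n_drawn <= horizon`.
#' @param params A [costed_bayes_params()].
#' @param jar A [jar_spec()].
#' @param horizon Maximum number of draws (default 10).
#' @return A named numeric vector with elements `declare_A`, `declare_B` and,
#'   before the horizon, `draw`.
#' @export
action_values <- function(state, params, jar, horizon = 10L) {
  stopifnot(inherits(state, "belief_state"),
            inherits(params, "costed_bayes_params"),
            inherits(jar, "jar_spec"))
  horizon <- as.integer(horizon)
  if (state$n_drawn > horizon) stop("state is beyond the horizon")
  p <- state$p_jar_A
  vals <- c(declare_A = -(1 - p), declare_B = -p)
  if (state$n_drawn < horizon) {
    bw <- dtd_backward(p, state$n_drawn, params$cost_of_sampling, jar, horizon)
    vals <- c(vals, draw = bw$vdraw[[1L]][1L])
  }
  vals
}

#' Softmax choice probabilities over action values
#'
#' @param values Named numeric vector of action values.
#' @param decision_noise Softmax temperature >= 0. At temperature 0 the choice
#'   is a deterministic argmax with ties split uniformly.
#' @return A probability vector over the actions (sums to 1).
#' @examples
#' choice_probabilities(c(a = 0, b = -1), 1)  # ~ (0.731, 0.269)
#' @export
choice_probabilities <- function(values, decision_noise) {
  if (!is.numeric(decision_noise) || length(decision_noise) != 1L ||
      !is.finite(decision_noise) || decision_noise < 0) {
    stop("decision_noise must be a single finite number >= 0")
  }
  v <- as.numeric(values)
  if (decision_noise == 0) {
    top <- v >= max(v) - 1e-12
    # deterministic optimal-stopping policy: when drawing ties the best
    # declare exactly (costless, indifferent information), keep sampling;
    # ties among declare actions split uniformly
    nm <- names(values)
    if (!is.null(nm) && "draw" %in% nm[top] && sum(top) > 1L) {
      top <- top & nm == "draw"
    }
    p <- as.numeric(top) / sum(top)
  } else {
    z <- (v - max(v)) / decision_noise
    e <- exp(z)
    p <- e / sum(e)
  }
  names(p) <- names(values)
  p
}

# Global value/posterior tables on the (n, k) count lattice with prior 0.5,
# the representation used by the simulator and the likelihood: at n draws with
# k color-1 beads the posterior and action values are read off layer n.
dtd_value_table <- function(cost, jar, horizon = 10L) {
  dtd_backward(0.5, 0L, cost, jar, horizon)
}

# Log choice probabilities at one decision point, given the lattice tables.
# n = beads seen, k = color-1 count. Returns the log-probability vector over
# (declare_A, declare_B[, draw]).
dtd_step_logprobs <- function(tab, n, k, decision_noise, horizon = 10L) {
  p <- tab$post[[n + 1L]][k + 1L]
  vals <- c(declare_A = -(1 - p), declare_B = -p)
  if (n < horizon) vals <- c(vals, draw = tab$vdraw[[n + 1L]][k + 1L])
  pr <- choice_probabilities(vals, decision_noise)
  log(pmax(pr, 1e-300))  # degenerate softmax handled as a large finite penalty
}

#' Simulate an agent on the draws-to-decision task
#'
#' For each block a sequence is sampled from the pool; the agent walks it,
#' applying the softmax over action values at each decision point (starting
#' after `min_draws` beads), and stops when a declare action is sampled. At
#' the horizon declaration is forced and only the jar choice is stochastic.
#'
#' @param params A [costed_bayes_params()].
#' @param pool A `sequence_pool`.
#' @param n_blocks Number of blocks (default 5).
#' @param seed Integer seed.
#' @param replace Sample sequences with replacement? Default `FALSE`.
#' @param min_draws Minimum beads seen before declaring is allowed (default 1).
#' @param jar Jar specification; defaults to the pool's generating jars.
#' @return A list of [dtd_observation()]s.
#' @export
simulate_agent <- function(params, pool, n_blocks = 5L, seed = NULL,
                           replace = FALSE, min_draws = 1L, jar = NULL) {
  stopifnot(inherits(params, "costed_bayes_params"),
            inherits(pool, "sequence_pool"))
  n_blocks <- as.integer(n_blocks)
  n_pool <- length(pool$sequences)
  if (!replace && n_blocks > n_pool) {
    stop("n_blocks exceeds pool size when sampling without replacement")
  }
  if (is.null(jar)) jar <- jar_spec(pool$provenance$q %||% 0.8)
  horizon <- length(pool$sequences[[1L]]$beads)
  tab <- dtd_value_table(params$cost_of_sampling, jar, horizon)
  tau <- params$decision_noise
  with_seed(seed, {
    idx <- sample.int(n_pool, n_blocks, replace = replace)
    lapply(seq_len(n_blocks), function(b) {
      s <- pool$sequences[[idx[b]]]
      k <- 0L
      n_drawn <- NA_integer_
      choice <- NA_integer_
      for (n in seq_len(horizon)) {
        k <- k + s$beads[n]
        if (n < min_draws) next
        lp <- dtd_step_logprobs(tab, n, k, tau, horizon)
        act <- sample.int(length(lp), 1L, prob = exp(lp))
        if (n == horizon && act > 2L) act <- which.max(lp[1:2])  # unreachable guard
        if (act <= 2L) {
          n_drawn <- n
          choice <- act
          break
        }
      }
      dtd_observation(s, n_drawn, choice, block_id = b)
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-likelihood of draws-to-decision data under the costed Bayesian model
#'
#' Sums, over blocks and decision points, the log softmax probabilities of the
#' observed draw/declare actions and the final jar choice. Zero-probability
#' observed actions (deterministic limit) contribute a large finite penalty
#' rather than -Inf.
#'
#' @param params A [costed_bayes_params()].
#' @param observed A list of [dtd_observation()]s.
#' @param jar A [jar_spec()].
#' @param min_draws Minimum beads before declaring (must match the task; default 1).
#' @param horizon Maximum draws (default 10).
#' @return The log-likelihood (a single number).
#' @export
dtd_loglik <- function(params, observed, jar, min_draws = 1L, horizon = 10L) {
  stopifnot(inherits(params, "costed_bayes_params"), inherits(jar, "jar_spec"))
  tab <- dtd_value_table(params$cost_of_sampling, jar, horizon)
  tau <- params$decision_noise
  ll <- 0
  for (obs in observed) {
    beads <- obs$sequence$beads
    if (obs$n_drawn > length(beads)) stop("observation inconsistent with sequence length")
    k <- cumsum(beads)
    for (n in seq_len(obs$n_drawn)) {
      if (n < min_draws) next
      lp <- dtd_step_logprobs(tab, n, k[n], tau, horizon)
      if (n < obs$n_drawn) {
        ll <- ll + lp[3L]            # chose to draw again
      } else {
        ll <- ll + lp[obs$choice]    # declared this jar
      }
    }
  }
  as.numeric(ll)
}

#' Fitting configuration for the costed Bayesian model
#'
#' MAP estimation runs bounded multi-start optimization on log-transformed
#' parameters with weakly informative log-normal priors.
#'
#' @param cost_bounds Bounds for cost_of_sampling (natural scale).
#' @param noise_bounds Bounds for decision_noise (natural scale).
#' @param starts Matrix of natural-scale starting values (one row per start);
#'   default is a fixed 4-point lattice.
#' @param prior_cost_meanlog,prior_cost_sdlog Log-normal prior on cost.
#' @param prior_noise_meanlog,prior_noise_sdlog Log-normal prior on noise.
#' @return A list of class `dtd_fit_config`.
#' @export
dtd_fit_config <- function(cost_bounds = c(1e-4, 1.5),
                           noise_bounds = c(1e-3, 3),
                           starts = NULL,
                           prior_cost_meanlog = log(0.1), prior_cost_sdlog = 1.5,
                           prior_noise_meanlog = log(0.2), prior_noise_sdlog = 1.5) {
  if (is.null(starts)) {
    starts <- as.matrix(expand.grid(cost = c(0.02, 0.2),
                                    noise = c(0.05, 0.5)))
  }
  structure(list(cost_bounds = cost_bounds, noise_bounds = noise_bounds,
                 starts = starts,
                 prior_cost = c(prior_cost_meanlog, prior_cost_sdlog),
                 prior_noise = c(prior_noise_meanlog, prior_noise_sdlog)),
            class = "dtd_fit_config")
}

#' Fit the costed Bayesian model to one subject's draws-to-decision data
#'
#' Maximum a posteriori estimation by multi-start L-BFGS-B on log-transformed
#' parameters. The DTD task yields sparse data (five decisions per subject),
#' so weakly informative log-normal priors regularize the estimates.
#'
#' @param observed A list of [dtd_observation()]s (>= 1 block).
#' @param jar A [jar_spec()].
#' @param config A [dtd_fit_config()].
#' @param min_draws,horizon Task settings as in [dtd_loglik()].
#' @return A list with elements `params` ([costed_bayes_params()]), `loglik`
#'   (data log-likelihood at the estimate), `logpost`, `convergence`
#'   (`TRUE` if any start converged), `se` (delta-method standard errors on the
#'   natural scale, from the numerical Hessian), and `n_blocks`.
#' @export
fit_dtd <- function(observed, jar = jar_spec(), config = dtd_fit_config(),
                    min_draws = 1L, horizon = 10L) {
  if (length(observed) == 0L) stop("at least one block is required")
  lb <- log(c(config$cost_bounds[1], config$noise_bounds[1]))
  ub <- log(c(config$cost_bounds[2], config$noise_bounds[2]))
  negpost <- function(theta) {
    cs <- exp(theta[1]); tau <- exp(theta[2])
    ll <- dtd_loglik(costed_bayes_params(cs, tau), observed, jar,
                     min_draws = min_draws, horizon = horizon)
    lp <- stats::dnorm(theta[1], config$prior_cost[1], config$prior_cost[2], log = TRUE) +
          stats::dnorm(theta[2], config$prior_noise[1], config$prior_noise[2], log = TRUE)
    -(ll + lp)
  }
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(config$starts))) {
    th0 <- pmin(pmax(log(as.numeric(config$starts[i, ])), lb), ub)
    fit <- try(stats::optim(th0, negpost, method = "L-BFGS-B",
                            lower = lb, upper = ub,
                            control = list(maxit = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed")
  theta <- best$par
  hess <- try(stats::optimHess(theta, negpost), silent = TRUE)
  se <- c(NA_real_, NA_real_)
  if (!inherits(hess, "try-error")) {
    cov <- try(solve(hess), silent = TRUE)
    if (!inherits(cov, "try-error") && all(diag(cov) > 0)) {
      # delta method: sd on natural scale = exp(theta) * sd(theta)
      se <- exp(theta) * sqrt(diag(cov))
    }
  }
  est <- costed_bayes_params(exp(theta[1]), exp(theta[2]))
  ll <- dtd_loglik(est, observed, jar, min_draws = min_draws, horizon = horizon)
  list(params = est, loglik = ll, logpost = -best$value,
       convergence = any_conv, se = stats::setNames(se, c("cost_of_sampling", "decision_noise")),
       n_blocks = length(observed))
}
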