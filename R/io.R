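#' Trial-level tables for task data
#'
#' `dtd_trials_frame()` flattens a subject's draws-to-decision blocks into a
#' long table (one row per shown bead: `subject`, `block`, `bead_index`,
#' `color`, `n_drawn`, `choice`), the format consumed by [fit_dtd_table()].
#' `probest_trials_frame()` does the same for a rating trajectory (`subject`,
#' `bead_index`, `color`, `rating`), consumed by [fit_hmm_table()].
#'
#' @param blocks A list of [dtd_observation()]s.
#' @param traj A [rating_trajectory()].
#' @param subject Subject identifier.
#' @return A data frame.
#' @export
dtd_trials_frame <- function(blocks, subject = "s1") {
  do.call(rbind, lapply(seq_along(blocks), function(b) {
    o <- blocks[[b]]
    data.frame(subject = subject, block = b,
               bead_index = seq_along(o$sequence$beads),
               color = o$sequence$beads,
               n_drawn = o$n_drawn, choice = o$choice)
  }))
}

#' @rdname dtd_trials_frame
#' @export
probest_trials_frame <- function(traj, subject = "s1") {
  data.frame(subject = subject,
             bead_index = seq_along(traj$sequence$beads),
             color = traj$sequence$beads,
             rating = traj$ratings)
}

#' Fit the task models to every subject in a trial-level table
#'
#' Per-subject wrappers around [fit_dtd()] and [fit_hmm()] producing tidy
#' parameter tables ready to serialize as CSV: point estimates (natural and,
#' for the reversal-learning model, transformed scales), standard errors
#' where available, log-likelihood and a convergence flag per subject.
#'
#' @param trials A trial-level data frame as produced by
#'   [dtd_trials_frame()] / [probest_trials_frame()].
#' @param jar A [jar_spec()].
#' @param config Fitting configuration ([dtd_fit_config()] /
#'   [hmm_fit_config()]).
#' @return A data frame with one row per subject.
#' @export
fit_dtd_table <- function(trials, jar = jar_spec(), config = dtd_fit_config()) {
  need <- c("subject", "block", "bead_index", "color", "n_drawn", "choice")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns: ", paste(need, collapse = ", "))
  }
  do.call(rbind, lapply(unique(trials$subject), function(s) {
    d <- trials[trials$subject == s, ]
    obs <- lapply(sort(unique(d$block)), function(b) {
      db <- d[d$block == b, ]
      db <- db[order(db$bead_index), ]
      sq <- bead_sequence(db$color, rep(1L, nrow(db)))
      dtd_observation(sq, db$n_drawn[1], db$choice[1], block_id = b)
    })
    f <- fit_dtd(obs, jar = jar, config = config)
    data.frame(subject = s,
               cost_of_sampling = f$params$cost_of_sampling,
               decision_noise = f$params$decision_noise,
               se_cost = f$se[["cost_of_sampling"]],
               se_noise = f$se[["decision_noise"]],
               loglik = f$loglik, converged = f$convergence)
  }))
}

#' @rdname fit_dtd_table
#' @export
fit_hmm_table <- function(trials, jar = jar_spec(), config = hmm_fit_config()) {
  need <- c("subject", "bead_index", "color", "rating")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns: ", paste(need, collapse = ", "))
  }
  do.call(rbind, lapply(unique(trials$subject), function(s) {
    d <- trials[trials$subject == s, ]
    d <- d[order(d$bead_index), ]
    traj <- rating_trajectory(d$rating, bead_sequence(d$color, rep(1L, nrow(d))))
    f <- fit_hmm(traj, config = config, jar = jar)
    p <- f$params
    data.frame(subject = s, r0 = p$r0, a = p$a, kappa = p$kappa, L = p$L,
               nu = p$nu, response_noise = 1 / p$nu,
               logit_r0 = logit(p$r0), log_kappa = log(p$kappa),
               log_nu = log(p$nu),
               loglik = f$loglik, converged = f$convergence,
               flat_likelihood = f$flat_likelihood)
  }))
}
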