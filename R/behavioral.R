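#' Construct a draws-to-decision observation
#'
#' One block of the draws-to-decision (DTD) task: the bead sequence shown, the
#' number of beads the participant requested before declaring, and the declared
#' jar.
#'
#' @param sequence A [bead_sequence()] of up to 10 beads.
#' @param n_drawn Number of beads drawn before the decision (1..sequence length).
#' @param choice Declared jar (1 = jar A, 2 = jar B).
#' @param block_id Optional block label.
#' @return An object of class `dtd_observation`.
#' @export
dtd_observation <- function(sequence, n_drawn, choice, block_id = NA_integer_) {
  stopifnot(inherits(sequence, "bead_sequence"))
  n_drawn <- as.integer(n_drawn)
  choice <- as.integer(choice)
  if (n_drawn < 1L || n_drawn > length(sequence$beads)) {
    stop("n_drawn must be between 1 and the sequence length")
  }
  if (!choice %in% c(1L, 2L)) stop("choice must be jar 1 or jar 2")
  structure(list(block_id = block_id, sequence = sequence,
                 n_drawn = n_drawn, choice = choice),
            class = "dtd_observation")
}

#' Construct a rating trajectory
#'
#' Per-trial slider estimates from the probability-estimation task: after each
#' bead the participant rates the probability (on [0, 1]) that the current
#' source is jar A.
#'
#' @param ratings Numeric vector of probability estimates in [0, 1], one per bead.
#' @param sequence The [bead_sequence()] rated (30 beads by default design).
#' @return An object of class `rating_trajectory`.
#' @export
rating_trajectory <- function(ratings, sequence) {
  stopifnot(inherits(sequence, "bead_sequence"))
  ratings <- as.numeric(ratings)
  if (length(ratings) != length(sequence$beads)) {
    stop("ratings length must equal the number of beads")
  }
  if (any(!is.finite(ratings)) || any(ratings < 0) || any(ratings > 1)) {
    stop("all ratings must lie in [0, 1]")
  }
  structure(list(ratings = ratings, sequence = sequence),
            class = "rating_trajectory")
}

#' Average draws to decision
#'
#' Arithmetic mean of the number of beads drawn before a decision, across a
#' participant's blocks (five in the standard design).
#'
#' @param blocks A list of [dtd_observation()]s.
#' @return Mean draws to decision.
#' @examples
#' jar <- jar_spec()
#' pool <- make_sequence_pool(jar, seed = 1)
#' obs <- lapply(1:5, function(i) dtd_observation(pool$sequences[[i]], i * 2, 1))
#' average_dtd(obs)
#' @export
average_dtd <- function(blocks) {
  if (length(blocks) == 0L) stop("at least one block is required")
  stopifnot(all(vapply(blocks, inherits, logical(1), "dtd_observation")))
  mean(vapply(blocks, function(b) b$n_drawn, numeric(1)))
}

#' Jumping-to-conclusions bias
#'
#' Hasty decision making, operationalized as an average draws-to-decision of
#' two beads or fewer across the blocks.
#'
#' @inheritParams average_dtd
#' @return `TRUE` if average DTD is at most 2.
#' @export
jtc_bias <- function(blocks) {
  average_dtd(blocks) <= 2
}

#' Contrary (disconfirmatory) belief updating
#'
#' The size of belief updating after seeing a bead of a different color from
#' the immediately preceding run of two or more identically colored beads.
#' A trial t qualifies when bead t differs in color from beads t-1 and t-2
#' (which are the tail of a same-color run); the measure is the mean absolute
#' rating change |rating_t - rating_{t-1}| over qualifying trials.
#'
#' @param traj A [rating_trajectory()].
#' @return Mean absolute rating change on disconfirming trials, on the [0, 1]
#'   probability scale; `NA` if no trial qualifies.
#' @examples
#' jar <- jar_spec()
#' s <- bead_sequence(c(1, 1, 0), rep(1, 3))
#' contrary_updating(rating_trajectory(c(0.8, 0.9, 0.5), s))  # 0.4
#' @export
contrary_updating <- function(traj) {
  stopifnot(inherits(traj, "rating_trajectory"))
  beads <- traj$sequence$beads
  r <- traj$ratings
  n <- length(beads)
  if (n < 3L) stop("at least 3 beads are required")
  qualifies <- vapply(3:n, function(t) {
    beads[t] != beads[t - 1L] && beads[t - 1L] == beads[t - 2L]
  }, logical(1))
  idx <- (3:n)[qualifies]
  if (length(idx) == 0L) return(NA_real_)
  mean(abs(r[idx] - r[idx - 1L]))
}

#' Compute per-subject behavioral measures from trial-level tables
#'
#' `dtd_measures` takes a data frame with columns `subject`, `block`, `n_drawn`
#' (one row per block) and returns per-subject average DTD and JTC flag.
#' `probest_measures` takes a data frame with columns `subject`, `bead_index`,
#' `color`, `rating` and returns per-subject contrary updating.
#'
#' @param trials A data frame of trial-level data.
#' @return A data frame of per-subject measures.
#' @export
dtd_measures <- function(trials) {
  need <- c("subject", "block", "n_drawn")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns: ", paste(need, collapse = ", "))
  }
  subjects <- unique(trials$subject)
  out <- lapply(subjects, function(s) {
    d <- trials[trials$subject == s, ]
    avg <- mean(d$n_drawn)
    data.frame(subject = s, average_dtd = avg, jtc = avg <= 2)
  })
  do.call(rbind, out)
}

#' @rdname dtd_measures
#' @export
probest_measures <- function(trials) {
  need <- c("subject", "bead_index", "color", "rating")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns: ", paste(need, collapse = ", "))
  }
  subjects <- unique(trials$subject)
  out <- lapply(subjects, function(s) {
    d <- trials[trials$subject == s, ]
    d <- d[order(d$bead_index), ]
    traj <- rating_trajectory(d$rating,
                              bead_sequence(d$color, rep(1L, nrow(d))))
    data.frame(subject = s, contrary_updating = contrary_updating(traj))
  })
  do.call(rbind, out)
}
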