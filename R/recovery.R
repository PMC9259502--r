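#' Typical parameter ranges for simulate-then-refit studies
#'
#' Sampling ranges spanning behavior from near-ideal to highly noisy.
#' Location-like parameters are drawn uniformly; scale-like parameters
#' (Dirichlet confidence, response precision, decision noise) are drawn
#' log-uniformly. Window length is drawn uniformly over 1..10.
#'
#' @param model `"probest"` (reversal-learning model) or `"dtd"` (costed
#'   Bayesian model).
#' @return A named list of `c(lower, upper)` ranges with a `log` attribute
#'   marking log-uniform sampling.
#' @export
typical_ranges <- function(model = c("probest", "dtd")) {
  model <- match.arg(model)
  if (model == "probest") {
    r <- list(r0 = c(0.01, 0.5), a = c(0.3, 1), kappa = c(1, 50),
              L = c(1, 10), nu = c(2, 100))
    attr(r, "log") <- c(r0 = FALSE, a = FALSE, kappa = TRUE, L = FALSE,
                        nu = TRUE)
  } else {
    r <- list(cost_of_sampling = c(0, 0.5), decision_noise = c(0.01, 1))
    attr(r, "log") <- c(cost_of_sampling = FALSE, decision_noise = TRUE)
  }
  r
}

#' Design of a parameter-recovery study
#'
#' @param model `"probest"` or `"dtd"`.
#' @param n_subjects Number of simulated subjects (default 200).
#' @param seed Integer seed governing the whole run.
#' @param ranges Per-parameter sampling ranges; default [typical_ranges()].
#' @param fit_config Fitting configuration ([hmm_fit_config()] or
#'   [dtd_fit_config()]); `NULL` for the defaults.
#' @param jar Jar specification (default 80:20).
#' @return An object of class `recovery_design`.
#' @export
recovery_design <- function(model = c("probest", "dtd"), n_subjects = 200L,
                            seed = 11L, ranges = NULL, fit_config = NULL,
                            jar = jar_spec()) {
  model <- match.arg(model)
  if (is.null(ranges)) ranges <- typical_ranges(model)
  legal <- typical_ranges(model)
  for (nm in names(ranges)) {
    if (!nm %in% names(legal)) stop("unknown parameter in ranges: ", nm)
  }
  if (is.null(fit_config)) {
    fit_config <- if (model == "probest") hmm_fit_config() else dtd_fit_config()
  }
  structure(list(model = model, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), ranges = ranges,
                 fit_config = fit_config, jar = jar),
            class = "recovery_design")
}

draw_from_ranges <- function(ranges, n) {
  islog <- attr(ranges, "log")
  out <- lapply(names(ranges), function(nm) {
    r <- ranges[[nm]]
    if (isTRUE(islog[[nm]])) {
      exp(stats::runif(n, log(r[1]), log(r[2])))
    } else if (nm == "L") {
      sample(seq(r[1], r[2]), n, replace = TRUE)
    } else {
      stats::runif(n, r[1], r[2])
    }
  })
  names(out) <- names(ranges)
  as.data.frame(out)
}

#' Run a simulate-then-refit parameter-recovery study
#'
#' For each simulated subject, true parameters are drawn from the design
#' ranges, one subject's task data are simulated (five draws-to-decision
#' blocks sampled from a 16-sequence pool, or one 30-bead rating trajectory
#' with a jar reversal after bead 15), and the corresponding model is fitted.
#' Rank (Spearman) and linear (Pearson) correlations between generating and
#' recovered values are reported per parameter. The whole run is reproducible
#' from the design seed.
#'
#' @param design A [recovery_design()].
#' @param progress Print a progress line every 50 subjects?
#' @return An object of class `recovery_result`: list with `model`, `draws`
#'   (per-subject data frame of `true_*` and `fit_*` columns plus a
#'   convergence flag), `correlations` (per-parameter Spearman/Pearson, bias,
#'   RMSE), `convergence_rate`, `n_subjects`, `seed`.
#' @export
run_recovery <- function(design, progress = FALSE) {
  stopifnot(inherits(design, "recovery_design"))
  n <- design$n_subjects
  jar <- design$jar
  res <- with_seed(design$seed, {
    truth <- draw_from_ranges(design$ranges, n)
    subject_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
    list(truth = truth, seeds = subject_seeds)
  })
  truth <- res$truth
  seeds <- res$seeds
  pool <- if (design$model == "dtd") {
    make_sequence_pool(jar, 16L, 10L, seed = design$seed)
  } else NULL

  fits <- vector("list", n)
  conv <- logical(n)
  for (i in seq_len(n)) {
    if (design$model == "probest") {
      pars <- hmm_params(truth$r0[i], truth$a[i], truth$kappa[i],
                         truth$L[i], truth$nu[i])
      seq_i <- make_probest_sequence(jar, 30L, 15L, seed = seeds[2L * i - 1L])
      traj <- simulate_responses(pars, seq_i, seed = seeds[2L * i], jar = jar)
      fit <- fit_hmm(traj, config = design$fit_config, jar = jar)
      fits[[i]] <- data.frame(r0 = fit$params$r0, a = fit$params$a,
                              kappa = fit$params$kappa, L = fit$params$L,
                              nu = fit$params$nu)
    } else {
      pars <- costed_bayes_params(truth$cost_of_sampling[i],
                                  truth$decision_noise[i])
      obs <- simulate_agent(pars, pool, n_blocks = 5L,
                            seed = seeds[2L * i - 1L], jar = jar)
      fit <- fit_dtd(obs, jar = jar, config = design$fit_config)
      fits[[i]] <- data.frame(cost_of_sampling = fit$params$cost_of_sampling,
                              decision_noise = fit$params$decision_noise)
    }
    conv[i] <- isTRUE(fit$convergence)
    if (progress && i %% 50L == 0L) {
      message(sprintf("  recovery: %d / %d subjects fitted", i, n))
    }
  }
  fitted <- do.call(rbind, fits)
  names(truth) <- paste0("true_", names(truth))
  names(fitted) <- paste0("fit_", names(fitted))
  draws <- cbind(subject = seq_len(n), truth, fitted, converged = conv)

  par_names <- sub("^true_", "", names(truth))
  correlations <- do.call(rbind, lapply(par_names, function(p) {
    tv <- draws[[paste0("true_", p)]]
    fv <- draws[[paste0("fit_", p)]]
    if (n < 2L || stats::sd(tv) == 0) {
      data.frame(parameter = p, spearman = NA_real_, pearson = NA_real_,
                 bias = mean(fv - tv), rmse = sqrt(mean((fv - tv)^2)),
                 degenerate = TRUE)
    } else {
      data.frame(parameter = p,
                 spearman = stats::cor(tv, fv, method = "spearman"),
                 pearson = stats::cor(tv, fv, method = "pearson"),
                 bias = mean(fv - tv), rmse = sqrt(mean((fv - tv)^2)),
                 degenerate = FALSE)
    }
  }))
  structure(list(model = design$model, draws = draws,
                 correlations = correlations,
                 convergence_rate = mean(conv), n_subjects = n,
                 seed = design$seed),
            class = "recovery_result")
}

#' Write a parameter-recovery report
#'
#' Writes the per-subject scatter data as CSV and the per-parameter summary
#' (Spearman rho, Pearson r, bias, RMSE, convergence rate) as JSON; the output
#' is a deterministic function of the result.
#'
#' @param result A `recovery_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
recovery_report <- function(result, dir) {
  stopifnot(inherits(result, "recovery_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv_path <- file.path(dir, paste0("recovery_", result$model, ".csv"))
  json_path <- file.path(dir, paste0("recovery_", result$model, "_summary.json"))
  utils::write.csv(result$draws, csv_path, row.names = FALSE)
  summ <- list(model = result$model, n_subjects = result$n_subjects,
               seed = result$seed, convergence_rate = result$convergence_rate,
               correlations = result$correlations)
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("Parameter recovery (%s model, n = %d, %.0f%% converged)\n",
              x$model, x$n_subjects, 100 * x$convergence_rate))
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
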