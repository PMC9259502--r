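#' Categorization / transformation rules for belief-updating parameters
#'
#' Skewed parameter estimates are transformed or collapsed into categorical
#' measures before being used as regression outcomes: tertiles (middle tertile
#' as reference), a binary flag for values above a percentile cutoff (85th or
#' 95th in the sensitivity analyses), or a direct log/logit transform.
#'
#' @param kind One of `"tertile"`, `"percentile-binary"`, `"identity-transform"`.
#' @param cutoff Percentile cutoff in (0, 100) for `"percentile-binary"`.
#' @param transform One of `"none"`, `"log"`, `"logit"` for
#'   `"identity-transform"`.
#' @return An object of class `categorization_rule`.
#' @export
categorization_rule <- function(kind = c("tertile", "percentile-binary",
                                         "identity-transform"),
                                cutoff = 85, transform = c("none", "log", "logit")) {
  kind <- match.arg(kind)
  transform <- match.arg(transform)
  if (kind == "percentile-binary" && (cutoff <= 0 || cutoff >= 100)) {
    stop("cutoff percentile must lie in (0, 100)")
  }
  structure(list(kind = kind, cutoff = cutoff, transform = transform),
            class = "categorization_rule")
}

#' Apply a categorization rule to per-subject values
#'
#' Tertiles are split at the empirical 33.3rd/66.7th percentiles (linear
#' interpolation), returning a factor with the middle tertile as the reference
#' level. Percentile-binary flags values strictly above the empirical cutoff
#' percentile. Identity-transform returns the transformed values.
#'
#' @param values Numeric vector (>= 10 non-missing values for percentile rules).
#' @param rule A [categorization_rule()].
#' @return A factor (`tertile`), integer 0/1 vector (`percentile-binary`) or
#'   numeric vector (`identity-transform`).
#' @examples
#' sum(categorize(1:100, categorization_rule("percentile-binary", 85)))  # 15
#' @export
categorize <- function(values, rule) {
  stopifnot(inherits(rule, "categorization_rule"))
  x <- values[!is.na(values)]
  if (rule$kind == "percentile-binary" && length(x) < 10L) {
    stop("at least 10 non-missing values are required")
  }
  if (rule$kind %in% c("tertile", "percentile-binary") &&
      length(x) > 0L && max(x) == min(x)) {
    stop("constant input: percentile cutpoints undefined")
  }
  switch(rule$kind,
    "tertile" = {
      qs <- stats::quantile(values, c(1 / 3, 2 / 3), na.rm = TRUE, type = 7)
      f <- cut(values, breaks = c(-Inf, qs[1], qs[2], Inf),
               labels = c("low", "mid", "high"), right = TRUE)
      stats::relevel(f, ref = "mid")
    },
    "percentile-binary" = {
      cutpoint <- stats::quantile(values, rule$cutoff / 100, na.rm = TRUE, type = 7)
      as.integer(values > cutpoint)  # strictly above the cutoff
    },
    "identity-transform" = {
      switch(rule$transform,
             none = values,
             log = {
               if (any(values <= 0, na.rm = TRUE)) stop("log transform requires positive values")
               log(values)
             },
             logit = {
               if (any(values <= 0 | values >= 1, na.rm = TRUE)) {
                 stop("logit transform requires values in (0, 1)")
               }
               logit(values)
             })
    })
}

#' Exposure-outcome regression with Wald inference
#'
#' Fits logistic, ordinal (proportional odds), multinomial or linear
#' regression of an outcome on an exposure plus covariates, and returns the
#' per-unit exposure effect on the family's natural scale (odds ratio,
#' relative risk ratio, or beta coefficient) with a Wald 95% CI and two-sided
#' p value. With `quadratic = TRUE` the model adds a squared exposure term and
#' both the linear and quadratic estimates are returned.
#'
#' @param cohort A data frame.
#' @param exposure Name of the exposure column (numeric).
#' @param outcome Name of the outcome column (binary for logistic, ordered
#'   factor for ordinal, factor for multinomial, numeric for linear).
#' @param covariates Character vector of covariate column names.
#' @param family One of `"logistic"`, `"ordinal"`, `"multinomial"`, `"linear"`.
#' @param quadratic Add a squared exposure term?
#' @param conf_level Confidence level (default 0.95).
#' @return A data frame of class `effect_estimate` with one row per reported
#'   term: `term`, `scale` (OR/RRR/beta), `estimate`, `conf_low`, `conf_high`,
#'   `p_value`, `family`, `adjusted_for`.
#' @export
fit_exposure_outcome <- function(cohort, exposure, outcome,
                                 covariates = character(),
                                 family = c("logistic", "ordinal",
                                            "multinomial", "linear"),
                                 quadratic = FALSE, conf_level = 0.95) {
  family <- match.arg(family)
  need <- c(exposure, outcome, covariates)
  if (!all(need %in% names(cohort))) {
    stop("missing columns: ", paste(setdiff(need, names(cohort)), collapse = ", "))
  }
  dat <- cohort[, need, drop = FALSE]
  if (anyNA(dat)) stop("missing values present; complete-case input required")
  terms <- exposure
  if (quadratic) {
    dat[[".exposure_sq"]] <- dat[[exposure]]^2
    terms <- c(terms, ".exposure_sq")
  }
  rhs <- paste(c(terms, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  adj <- if (length(covariates)) paste(covariates, collapse = ",") else "unadjusted"
  label <- function(t) if (t == ".exposure_sq") paste0(exposure, "^2") else t

  rows <- switch(family,
    "logistic" = {
      if (!all(dat[[outcome]] %in% c(0, 1))) stop("logistic family requires a 0/1 outcome")
      fit <- stats::glm(fml, data = dat, family = stats::binomial())
      if (!fit$converged) stop("logistic fit did not converge (possible separation)")
      cf <- summary(fit)$coefficients
      if (any(abs(cf[terms, "Estimate"]) > 15)) {
        stop("implausibly large coefficients: possible separation or singular design")
      }
      lapply(terms, function(t) {
        b <- cf[t, "Estimate"]; s <- cf[t, "Std. Error"]
        data.frame(term = label(t), scale = "OR", estimate = exp(b),
                   conf_low = exp(b - z * s), conf_high = exp(b + z * s),
                   p_value = 2 * stats::pnorm(-abs(b / s)))
      })
    },
    "linear" = {
      fit <- stats::lm(fml, data = dat)
      cf <- summary(fit)$coefficients
      lapply(terms, function(t) {
        b <- cf[t, "Estimate"]; s <- cf[t, "Std. Error"]
        data.frame(term = label(t), scale = "beta", estimate = b,
                   conf_low = b - z * s, conf_high = b + z * s,
                   p_value = 2 * stats::pnorm(-abs(b / s)))
      })
    },
    "ordinal" = {
      y <- dat[[outcome]]
      if (!is.ordered(y)) dat[[outcome]] <- factor(y, ordered = TRUE)
      fit <- MASS::polr(fml, data = dat, Hess = TRUE)
      cf <- summary(fit)$coefficients
      lapply(terms, function(t) {
        b <- cf[t, "Value"]; s <- cf[t, "Std. Error"]
        data.frame(term = label(t), scale = "OR", estimate = exp(b),
                   conf_low = exp(b - z * s), conf_high = exp(b + z * s),
                   p_value = 2 * stats::pnorm(-abs(b / s)))
      })
    },
    "multinomial" = {
      dat[[outcome]] <- factor(dat[[outcome]])
      fit <- nnet::multinom(fml, data = dat, trace = FALSE, Hess = TRUE)
      cf <- summary(fit)$coefficients
      se <- summary(fit)$standard.errors
      if (is.null(dim(cf))) {  # two-level outcome degenerates to one row
        cf <- matrix(cf, nrow = 1, dimnames = list(levels(dat[[outcome]])[2], names(cf)))
        se <- matrix(se, nrow = 1, dimnames = dimnames(cf))
      }
      unlist(lapply(rownames(cf), function(lev) {
        lapply(terms, function(t) {
          b <- cf[lev, t]; s <- se[lev, t]
          data.frame(term = paste0(label(t), " [", lev, "]"), scale = "RRR",
                     estimate = exp(b),
                     conf_low = exp(b - z * s), conf_high = exp(b + z * s),
                     p_value = 2 * stats::pnorm(-abs(b / s)))
        })
      }), recursive = FALSE)
    })
  out <- do.call(rbind, rows)
  out$family <- family
  out$adjusted_for <- adj
  class(out) <- c("effect_estimate", class(out))
  out
}

#' Counterfactual mediation analysis with natural direct and indirect effects
#'
#' Decomposes the exposure-outcome association into a natural direct effect
#' (NDE) and natural indirect effect (NIE) through a mediator, on the odds
#' ratio scale under the rare-outcome approximation. Internally fits a linear
#' mediator model (or logistic, for a binary mediator) and a logistic outcome
#' model, optionally with an exposure-by-mediator product term, and composes
#' the closed-form natural-effect odds ratios for the stated exposure
#' contrast with covariates held at their means. Percent mediated is computed
#' on the log-OR scale: 100 * log(NIE) / log(NDE * NIE).
#'
#' For a continuous mediator without interaction, confidence intervals come
#' from the delta method; otherwise a seeded nonparametric bootstrap is used.
#'
#' @param cohort A data frame.
#' @param exposure Name of the (numeric) exposure column.
#' @param mediator Name of the mediator column (continuous, or binary 0/1
#'   which routes to the binary-mediator closed form).
#' @param outcome Name of the rare binary outcome column. A warning is issued
#'   when prevalence exceeds 10% (the odds-ratio approximation degrades).
#' @param covariates Character vector of covariate names.
#' @param contrast Exposure contrast `c(x, x_ref)`; default `c(3, 0)`
#'   (three-or-more trauma types vs none).
#' @param interaction Include an exposure-by-mediator product term?
#' @param ci_method `"delta"` (continuous mediator, no interaction) or
#'   `"bootstrap"`.
#' @param n_boot Bootstrap replicates (when bootstrapping).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return A list of class `mediation_estimate` with elements `nde`, `nie`,
#'   `total` (each a vector of `estimate`, `conf_low`, `conf_high` on the OR
#'   scale), `percent_mediated`, `contrast`, `interaction`,
#'   `outcome_prevalence`.
#' @export
mediate_counterfactual <- function(cohort, exposure, mediator, outcome,
                                   covariates = character(),
                                   contrast = c(3, 0), interaction = FALSE,
                                   ci_method = c("delta", "bootstrap"),
                                   n_boot = 200L, seed = 1L,
                                   conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  need <- c(exposure, mediator, outcome, covariates)
  if (!all(need %in% names(cohort))) {
    stop("missing columns: ", paste(setdiff(need, names(cohort)), collapse = ", "))
  }
  dat <- as.data.frame(cohort)[, need, drop = FALSE]
  if (anyNA(dat)) stop("missing values present; complete-case input required")
  prev <- mean(dat[[outcome]])
  if (prev > 0.10) {
    warning(sprintf("outcome prevalence %.1f%% exceeds 10%%: the rare-outcome odds-ratio approximation may be poor", 100 * prev))
  }
  mvals <- unique(dat[[mediator]])
  binary_mediator <- length(mvals) == 2L && all(mvals %in% c(0, 1))
  if (binary_mediator && ci_method == "delta") ci_method <- "bootstrap"
  if (interaction && ci_method == "delta") ci_method <- "bootstrap"

  point <- mediation_point(dat, exposure, mediator, outcome, covariates,
                           contrast, interaction, binary_mediator)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "delta") {
    v <- point$delta_var  # variances of log NDE and log NIE
    nde_ci <- exp(log(point$nde) + c(-z, z) * sqrt(v["nde"]))
    nie_ci <- exp(log(point$nie) + c(-z, z) * sqrt(v["nie"]))
    tot_ci <- exp(log(point$nde * point$nie) + c(-z, z) * sqrt(v["nde"] + v["nie"]))
  } else {
    reps <- with_seed(seed, {
      replicate(n_boot, {
        idx <- sample.int(nrow(dat), replace = TRUE)
        p <- try(mediation_point(dat[idx, , drop = FALSE], exposure, mediator,
                                 outcome, covariates, contrast, interaction,
                                 binary_mediator), silent = TRUE)
        if (inherits(p, "try-error")) c(NA_real_, NA_real_)
        else c(log(p$nde), log(p$nie))
      })
    })
    alpha <- (1 - conf_level) / 2
    qs <- apply(reps, 1, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
    nde_ci <- exp(qs[, 1])
    nie_ci <- exp(qs[, 2])
    tot_ci <- exp(stats::quantile(colSums(reps), probs = c(alpha, 1 - alpha),
                                  na.rm = TRUE))
  }
  total <- point$nde * point$nie
  pm <- if (abs(log(total)) < 1e-12) 0 else 100 * log(point$nie) / log(total)
  structure(list(
    nde = c(estimate = point$nde, conf_low = nde_ci[1], conf_high = nde_ci[2]),
    nie = c(estimate = point$nie, conf_low = nie_ci[1], conf_high = nie_ci[2]),
    total = c(estimate = total, conf_low = unname(tot_ci[1]),
              conf_high = unname(tot_ci[2])),
    percent_mediated = pm, contrast = contrast, interaction = interaction,
    binary_mediator = binary_mediator, outcome_prevalence = prev,
    ci_method = ci_method),
    class = "mediation_estimate")
}

# Point estimates of the natural-effect odds ratios (rare-outcome closed
# forms of the counterfactual natural-effects framework). Covariates are held
# at their sample means.
mediation_point <- function(dat, exposure, mediator, outcome, covariates,
                            contrast, interaction, binary_mediator) {
  x1 <- contrast[1]; x0 <- contrast[2]
  d <- x1 - x0
  cov_rhs <- if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""
  med_fml <- stats::as.formula(paste(mediator, "~", exposure, cov_rhs))
  int_term <- if (interaction) paste("+", exposure, ":", mediator) else ""
  out_fml <- stats::as.formula(paste(outcome, "~", exposure, "+", mediator,
                                     int_term, cov_rhs))
  ofit <- stats::glm(out_fml, data = dat, family = stats::binomial())
  oc <- stats::coef(ofit)
  th1 <- oc[[exposure]]
  th2 <- oc[[mediator]]
  th3 <- if (interaction) oc[[paste0(exposure, ":", mediator)]] else 0
  cbar <- vapply(covariates, function(v) mean(dat[[v]]), numeric(1))

  if (binary_mediator) {
    mfit <- stats::glm(med_fml, data = dat, family = stats::binomial())
    mc <- stats::coef(mfit)
    lin_m <- function(x) {
      mc[["(Intercept)"]] + mc[[exposure]] * x +
        if (length(covariates)) sum(mc[covariates] * cbar) else 0
    }
    nde <- exp(th1 * d) *
      (1 + exp(th2 + th3 * x1 + lin_m(x0))) /
      (1 + exp(th2 + th3 * x0 + lin_m(x0)))
    nie <- ((1 + exp(lin_m(x0))) * (1 + exp(lin_m(x1) + th2 + th3 * x1))) /
      ((1 + exp(lin_m(x1))) * (1 + exp(lin_m(x0) + th2 + th3 * x1)))
    return(list(nde = unname(nde), nie = unname(nie), delta_var = NULL))
  }

  mfit <- stats::lm(med_fml, data = dat)
  mc <- stats::coef(mfit)
  b0 <- mc[["(Intercept)"]]
  b1 <- mc[[exposure]]
  bC <- if (length(covariates)) sum(mc[covariates] * cbar) else 0
  s2 <- sum(stats::resid(mfit)^2) / stats::df.residual(mfit)
  log_nde <- (th1 + th3 * (b0 + b1 * x0 + bC + th2 * s2)) * d +
    0.5 * th3^2 * s2 * (x1^2 - x0^2)
  log_nie <- (th2 * b1 + th3 * b1 * x1) * d
  delta_var <- NULL
  if (!interaction) {
    vth1 <- summary(ofit)$coefficients[exposure, "Std. Error"]^2
    vth2 <- summary(ofit)$coefficients[mediator, "Std. Error"]^2
    vb1 <- summary(mfit)$coefficients[exposure, "Std. Error"]^2
    # theta2 and beta1 come from independent model fits
    delta_var <- c(nde = d^2 * vth1,
                   nie = d^2 * (b1^2 * vth2 + th2^2 * vb1))
  }
  list(nde = unname(exp(log_nde)), nie = unname(exp(log_nie)),
       delta_var = delta_var)
}

#' @export
print.mediation_estimate <- function(x, ...) {
  cat(sprintf("Counterfactual mediation (exposure contrast %g vs %g)\n",
              x$contrast[1], x$contrast[2]))
  f <- function(v) sprintf("%.3f (%.3f-%.3f)", v["estimate"], v["conf_low"], v["conf_high"])
  cat("  Natural direct effect OR:  ", f(x$nde), "\n")
  cat("  Natural indirect effect OR:", f(x$nie), "\n")
  cat("  Total effect OR:           ", f(x$total), "\n")
  cat(sprintf("  Percent mediated: %.1f%%\n", x$percent_mediated))
  invisible(x)
}
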