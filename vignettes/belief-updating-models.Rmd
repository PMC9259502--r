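---
title: "Computational models of belief updating in beads tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational models of belief updating in beads tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadmodels)
```

## The tasks and the scientific question

In the beads paradigm a participant watches beads drawn from one of two
hidden jars with complementary color ratios (80:20 by default). Two variants
are modeled here:

* **Draws to decision (DTD).** The participant may request up to 10 beads
  and at any point declare which jar is the source; five blocks are played,
  each using a sequence sampled from a pool of 16. The behavioral index is
  the average number of draws before the decision; an average of two beads
  or fewer is the conventional jumping-to-conclusions (JTC) flag.
* **Probability estimation.** Thirty beads are shown one at a time and the
  participant rates, on a slider, the probability that the current source is
  one jar or the other. The jar switches once, after bead 15. The behavioral
  index is contrary (disconfirmatory) updating: the mean absolute rating
  change on trials where a bead contradicts an immediately preceding run of
  two or more same-colored beads.

Behavioral indices conflate many cognitive causes, so each task also gets a
generative model whose subject-level parameters are estimated by likelihood
inversion, and the fitted parameters feed an epidemiological stage that asks
whether atypical belief updating is associated with exposures and outcomes
(here: an ordinal trauma dose and a rare binary psychotic-experiences
outcome), and how much of an exposure-outcome association a parameter
mediates.

Because the cohort that motivated this package is access-controlled, every
analysis here runs on synthetic data whose generating structure is explicit
and whose planted coefficients are retained for checking the estimators.

## The costed Bayesian model of the DTD task

The observer holds a posterior $p_t = P(\text{jar A} \mid \text{beads so
far})$, updated by Bayes' rule with emission probabilities $q$ and $1-q$
(`posterior_update()`). At each decision point three actions exist: declare
A, declare B, or draw again. With the cost of a wrong declaration
normalized to 1:

* declare values are $-(1 - p_t)$ and $-p_t$ (negative expected error cost);
* the draw value is $-c_s$ plus the predictive expectation of the optimal
  continuation value, computed by backward induction from the 10-draw
  horizon (`action_values()`), where $c_s \ge 0$ is the **cost of
  sampling** per draw.

Actions are selected by a softmax over these values with temperature $\tau$,
the **decision noise** (`choice_probabilities()`), applied at every
draw/declare choice point and at the final jar choice. Larger $c_s$ makes an
optimal agent stop earlier; larger $\tau$ makes behavior less consistent
with the values.

Numerical choices worth knowing:

* The posterior depends only on the color counts, so the value function is
  computed on the $(n, k)$ count lattice (66 states for a 10-bead horizon);
  the same backward pass anchored at an arbitrary belief serves
  `action_values()`. Tests verify exact agreement with exhaustive
  expectimax enumeration of all bead continuations for horizons up to 5.
* At $\tau = 0$ the policy is a deterministic argmax. Ties among declare
  actions split uniformly. An exact tie between drawing and the best
  declare action resolves toward drawing: such ties arise systematically
  when $c_s = 0$ (in belief states where no remaining evidence can change
  the decision, drawing is exactly value-neutral), and a cost-free optimal
  agent that samples freely is the sensible deterministic limit. At
  $\tau > 0$ the pure softmax applies.
* The first bead is always shown: decision points run from one draw onward,
  so DTD is at least 1 (configurable via `min_draws`).
* Observed actions with probability zero under a degenerate softmax
  contribute a large finite log-likelihood penalty rather than $-\infty$,
  keeping the objective finite for the optimizer.

`fit_dtd()` returns maximum a posteriori estimates on log scales via
multi-start L-BFGS-B from a fixed 4-point lattice. Five decisions per
subject is sparse data, so weakly informative log-normal priors (medians
0.1 and 0.2, log-scale sd 1.5) regularize the estimates; standard errors
come from the numerical Hessian by the delta method. Whether one shared
temperature governs both the stop decision and the jar choice is not
observable from these data; the package uses a single shared $\tau$.

## The retrospective-inference hidden Markov model

The probability-estimation task is both an inference problem (which jar is
the source now?) and a learning problem (how often does the jar switch?).
Five parameters govern the model (`hmm_params()`):

| parameter | role | domain | default fitting bounds |
|---|---|---|---|
| $r_0$ | initial subjective reversal probability per trial | $[0, 1)$ | 0.002–0.9 |
| $a$ | adjustment rate: emission likelihoods enter as $P(\text{bead}\mid\text{jar})^a$ | $(0, 1]$ | 0.05–0.999 |
| $\kappa$ | confidence in $r_0$: Beta prior concentration | $> 0$ | 0.1–200 |
| $L$ | window length for online re-estimation of $r$ | $\ge 1$ | grid 1–15 |
| $\nu$ | response precision (noise reported as $1/\nu$) | $> 0$ | 1.05–500 |

Each trial the filter mixes the prior belief through the current reversal
estimate, $b^- = (1 - r_t)\,b + r_t\,(1 - b)$, then applies the tempered
Bayes update (`hmm_filter_step()`). $a = 1$ is full Bayesian adjustment;
$a < 1$ under-weights each bead.

After each trial the reversal probability is re-estimated as a Beta
posterior mean over a trailing window of $\min(L, t-1)$ transitions:

$$ r_{t+1} = \frac{\kappa\, r_0 + \sum_{\text{window}} s_t}{\kappa + w}, $$

where $s_t$ is the **two-slice transition posterior** — the retrospective
probability that the jar switched at transition $t$ given the previous
belief and the bead just seen:

$$ s_t = \frac{r_t\,[b\,\ell_B + (1-b)\,\ell_A]}
      {(1-r_t)\,[b\,\ell_A + (1-b)\,\ell_B] + r_t\,[b\,\ell_B + (1-b)\,\ell_A]} $$

with tempered likelihoods $\ell_\cdot = P(\text{bead}\mid\cdot)^a$
(`switch_probability()`). This choice matters. The simpler product of
consecutive filtered marginals, $b_t(1-b_{t-1}) + (1-b_t)b_{t-1}$, counts
roughly half a "switch" on every uncertain transition, so the window
estimate is dragged toward 0.3–0.5 for every subject regardless of $r_0$ —
which contradicts the intended role of $\kappa$ as the subject's resistance
to revising $r_0$, and empirically destroys the identifiability of $r_0$
(simulate-then-refit rank correlations plateau near 0.8 even for an
idealized grid-marginalization estimator). The two-slice posterior instead
equals $r_t$ exactly when the evidence is uninformative, so the reversal
estimate moves only when the data actually indicate a reversal; with it,
$r_0$ and $\nu$ are recovered with rank correlations above 0.9 (see below).

The predicted rating is the filtered belief itself, clipped to
$[10^{-4}, 1 - 10^{-4}]$; observed ratings follow a Beta distribution with
mean equal to the prediction and precision $\nu$ (`response_loglik()`).
$\nu = 2$ at a prediction of 0.5 is exactly uniform; the reporting
convention in this literature is response *noise*, $1/\nu$. Ratings exactly at the
slider ends are clipped into the interior with a warning before the Beta
likelihood is evaluated, and the simulator emits interior-clipped ratings
for the same reason. The slider's numeric range is taken as $[0, 1]$ with
no per-trial re-anchoring.

`fit_hmm()` performs MAP estimation: logit/log transforms for the four
continuous parameters, multi-start L-BFGS-B from a fixed 3-point start set,
and a profile over the integer window length $L \in \{1, \dots, 15\}$. The
priors are normal on the transformed scales with sd 1, centered at the
midpoints of the typical simulation ranges (arithmetic midpoints for the
uniformly drawn $r_0$ and $a$, geometric midpoints for the log-uniformly
drawn $\kappa$ and $\nu$: 0.2, 0.7, 7 and 14). This is an empirical-Bayes
choice: the prior matches the population the recovery harness actually
simulates, which stabilizes the ridge between $r_0$, $\kappa$ and $a$ for
weakly informative subjects without moving well-identified estimates. Both
Spearman and Pearson correlations are reported by the recovery harness;
the headline gate uses Spearman, which is invariant to the monotone
transforms involved.

## Parameter recovery

`run_recovery()` draws each subject's parameters from documented "typical
ranges" spanning near-ideal to highly noisy behavior ($r_0 \in [0.01,
0.5]$, $a \in [0.3, 1]$, $\kappa \in [1, 50]$ log-uniform, $L \in \{1,
\dots, 10\}$, $\nu \in [2, 100]$ log-uniform; for the DTD model $c_s \in
[0, 0.5]$ and $\tau \in [0.01, 1]$ log-uniform), simulates one subject's
task data (a fresh 30-bead sequence with reversal after bead 15, or five
DTD blocks sampled without replacement from a 16-sequence pool), refits,
and reports per-parameter correlations, bias and RMSE. The default study
size is 200 subjects; everything is reproducible from the design seed.

With the default design the reversal probability and response precision are
recovered with rank correlations above 0.9 (the package's acceptance run
computes these numbers; `scripts/acceptance.R` reproduces them from
scratch). The remaining parameters are less identifiable from a single
30-bead trajectory — $\kappa$ and $L$ in particular — which is expected:
they shape the trajectory only through the occasional reversal evidence.
Five blocks per subject were likely sampled from the real task's pool
without replacement; that is the default, controlled by a flag.

## The synthetic cohort and the epidemiological stage

`simulate_cohort()` emulates the cohort structure the association analyses
assume, not any real cohort's covariate distributions. Trauma dose
(number of trauma types: 0, 1, 2, 3-or-more, coded 0..3 with 3+ entered as
3 in linear-trend terms) is drawn with marginals 33.5/22.0/20.8/23.7%, so
that 66.5% report at least one type and 23.7% report three or more. Three
confounders stand in for a real analysis's larger adjustment set: sex
(Bernoulli 0.5), a continuous cognition score (Normal(100, 15)), and an
ordinal socioeconomic indicator (1..3). Each belief-updating parameter is a
linear function of dose and confounders plus Gaussian noise; the binary
outcome follows a logistic model. The default planted system produces a
3+-vs-none trauma odds ratio of 3.6 on the outcome with a small mediated
component through decision noise (indirect-effect OR about 1.03, a few
percent mediated) at roughly 4–5% outcome prevalence — the effect scale a
large population cohort in this literature reports. All planted
coefficients ride along as an attribute, so estimator tests compare
against the truth rather than against other estimates.

What passing tests on these cohorts shows: the regression and mediation
estimators recover planted effects with near-nominal CI coverage under a
correctly specified generating model. What it does not show: robustness to
missing data (multiple imputation is out of scope), selection, measurement
error in the exposure, or real covariate distributions.

`fit_exposure_outcome()` wraps logistic, ordinal (proportional-odds),
multinomial and linear regression with Wald intervals, optional quadratic
exposure terms, and effect scales (OR, RRR, beta) matching each family.
`categorize()` implements the outcome transformations: tertiles with the
middle tertile as reference, binary flags strictly above the 85th or 95th
empirical percentile (linear-interpolation quantiles; strictness matters
with ties and is therefore documented), or log/logit transforms.

## Counterfactual mediation

`mediate_counterfactual()` implements the natural-effects decomposition for
a rare binary outcome: a linear (or, for a binary mediator, logistic)
mediator model and a logistic outcome model are fitted, and the natural
direct and indirect effect odds ratios are composed in closed form for a
stated exposure contrast (default 3 vs 0, the 3+-types-vs-none contrast)
at covariate means. Without exposure-mediator interaction the forms reduce
to $\text{NDE} = e^{\theta_1 d}$ and $\text{NIE} = e^{\theta_2 \beta_1 d}$;
with interaction the standard extended forms are used. Percent mediated is
defined on the log-OR scale, $100 \cdot \log \text{NIE} / \log(\text{NDE}
\cdot \text{NIE})$, which is invariant to linear rescaling of the mediator.
CIs come from the delta method in the no-interaction continuous case and
from a seeded nonparametric bootstrap otherwise. The rare-outcome
approximation degrades with common outcomes; the function warns above 10%
prevalence. Whether the original analyses included an exposure-mediator
interaction is unknown; both modes are provided and neither is asserted as
canonical. Tests check the estimator against a brute-force counterfactual
oracle that simulates both potential mediator values per subject from the
generating truth at $n = 10^6$.

## Problem sizes and reproducibility

The shipped test suite and the acceptance script use the study sizes the
models are designed around: 200 subjects for the headline recovery study,
1000 simulated agents per cost grid point for the DTD monotonicity check,
100 cohorts of 10^4 subjects for regression calibration, and 10^6
counterfactual draws for the mediation oracle. Every stochastic step is
seeded; identical configurations reproduce outputs bitwise. Interfaces are
plain data frames and CSV/JSON writers (`write_cohort()`,
`write_sequence_pool()`, `recovery_report()`), so the package's functions
— rather than a shell wrapper — are the intended entry points.

## Known limitations

* The retrospective-inference scheme (the two-slice switch bookkeeping and
  Beta-posterior-mean window rule) is this package's concrete realization
  of the model family it implements; alternatives exist (full
  forward-backward smoothing is deliberately not used, matching the online
  character of the task).
* Hierarchical (group-level) fitting is not provided; each subject is fit
  independently, which is honest about the sparse DTD data but leaves
  shrinkage to the priors.
* The cohort simulator's confounder set is minimal by design; it preserves
  the adjustment structure, not any real cohort's marginals.
* Model comparison across alternative model families (e.g., threshold
  stopping heuristics) is out of scope.
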