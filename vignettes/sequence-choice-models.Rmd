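---
title: "Modeling choices between sequences of delayed monetary gains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling choices between sequences of delayed monetary gains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqchoice)
```

This vignette is the package's account of its science: the candidate
models and their assumptions, the stimulus machinery, the Bayesian
estimation pipeline, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not show.

## The choice setting

An option is a set of monetary amounts on a grid of future periods — a
*single dated outcome* ("£800 in two years") or a *sequence* ("£400 in one
year and £400 in three years"). In the packaged stimuli both options of a
pair pay the same total, so net present value (NPV) prefers one option at
*every* positive interest rate; that option is the designated *high-NPV*
option, and a participant's choice is coded 1 when they take it. Cells of
the delay-by-payoff matrix can be *stated* (including a stated £0, a
"revealed zero") or *blank* (a concealed zero). The distinction is the
crux of the model contest: the models disagree about whether a zero that
is merely implicit should affect preference.

## Candidate models

All models value options through the power utility `u(x) = x^gamma` with
`u(0) = 0` stipulated for every `gamma` (including `gamma = 0`, avoiding
`0^0`), and convert the value difference of a pair into a choice
probability with the logistic rule `P = plogis(epsilon * (U_H - U_L))`.
`epsilon = 0` is pure guessing. On the five pairs with a cumulative-payout
dominance relation, a dominance-detection parameter intervenes:
`P <- theta + (1 - theta) * P` applied to the dominant option, so
`theta = 1` means dominance is always detected and acted on.

**Tradeoff model (TM).** The accumulated utility of a sequence is traded
off against the *duration of utility accumulation*: a weighted average of
the delays in which each delay is weighted by the utility accumulated up
to its period, normalized across periods (`duration()`). The value
difference is `(sum u_H - sum u_L) / (1 + kappa) - kappa* (t_hat_H -
t_hat_L)`, with the relative weight `kappa* = kappa / (1 + kappa)`; the
time-weighing function is the identity (a concave alternative is an
extension hook in `duration()`'s `weighting` argument, alongside uniform
and outcome-proportional weighting). Only stated cells enter: a revealed
zero occupies a period and therefore shifts the duration even though its
own utility is zero, a blank does not. This single mechanism produces the
asymmetric hidden-zero effect: appending a stated later zero to a
smaller-sooner outcome lengthens its duration (0 to 1/2), while a stated
sooner zero leaves a larger-later outcome's duration at its delay.

**Discounted instantaneous utility model (DIUM).** `sum_i delta^{t_i}
u(x_i)` over stated cells. Zeros carry zero utility, so the model is
exactly indifferent to revealing or concealing them.

**Sequences model (SMNZ, SMZ).** Accumulated utility plus an improvement
component `beta * sum d_i` and a spreading component `-sigma * sum |d_i|`,
where `d_i = (i/n) sum u - sum_{j<=i} u` measures how far the cumulative
utility stream lags a uniform stream of the same total
(`deviation_scores()`). The no-zero variant (SMNZ) re-indexes the stated
cells 1..n in temporal order; the zero variant (SMZ) fills concealed zeros
in and evaluates the full grid. Delays enter only through period order —
the sequences model applies to contiguous periods without discounting,
matching the contiguous-future design of the stimuli.

**Random baseline (RM).** `P = 0.5` everywhere, optionally
dominance-adjusted. The `epsilon = 0` reductions of the substantive models
are behaviorally identical to RM, so the parallel contest canonicalizes
them to RM rather than carrying duplicates.

**Relative weights.** TM and SM weights are reported in relative form
(`kappa_star()`, `beta_star()`, `sigma_star()`), which decouples them from
the sensitivity `epsilon`. When utility curvature gives no leverage
(equal-total pairs near `gamma = 1`), TM's probabilities depend on
`epsilon` and `kappa` only through `epsilon * kappa*`, so a higher
impatience weight can be compensated by lower sensitivity
(`compensating_epsilon()`); this redundancy is why group-level HDIs for
`kappa` are wide while `kappa*` is tightly determined.

## Stimuli: screening and search

`screen_pair()` implements the two-stage screen for equal-total pairs:

1. *NPV consistency.* The sign of the NPV difference must be constant over
   a grid of per-period discount factors, `delta` in {0.01, ..., 0.99} —
   positive interest rates only. The range was an open design point; the
   positive-only choice is forced by the packaged dominance pair (blank
   middle sequence vs. decreasing sequence), whose NPV ordering reverses
   for negative rates yet which belongs in the set.
2. *Duration contrast.* Pairs where linear-outcome duration strictly
   favors the same option as NPV are discarded — they cannot separate a
   duration-weigher from an NPV-follower. Equal durations are kept: ties
   do not constitute "the same preference order".

`search_pairs()` enumerates the full two-option, three-period space
(amounts {200, 400, 600, 800} plus blank) under the prior criteria:
distinct options, at least one sequence, every period covered by a nonzero
outcome, at least one blank overall, equal totals, and no common
consequences. Exhaustive enumeration yields exactly 28 nondominance tasks,
including all 21 nondominance pairs of the packaged 26-pair set. The
dominance search relaxes the common-consequence criterion — the one
surviving dominance task has identical 800s in its third period, so it
cannot have been subject to that criterion — after which the dominance
partition contains exactly that task. Three packaged pairs (the blank
middle dominance pair and two nondominance pairs) have exactly tied
linear-utility durations; the tie-keeping rule retains all three.

The scaled incentivized variant (`exp4_scaled`) stores amounts divided by
20 and delays 2/4/6 with unit "months", exactly as administered; whether
those delays should enter the models as months or be rescaled to years is
ambiguous in the design, so the package stores printed units and applies
no conversion (with `w` the identity, rescaling delays is equivalent to
rescaling `kappa`, so the contest is unaffected).

## Priors and the individual-level contest

Every parameter has an independent uniform prior over its full range:
`gamma` in [0, 5] (dimensionless curvature), `delta` and `theta` in
[0, 1], `epsilon` and `kappa` in [0, 100] (inverse value units / value
units per time unit), `beta` and `sigma` in [-100, 100]. The marginal
likelihood `p(D | M)` is the prior-sample mean of the data likelihood,
computed by log-sum-exp (`marginal_likelihood()`); this simple Monte-Carlo
estimator is adequate precisely because individual posteriors are broad
relative to these priors. Posterior model probabilities assume equal model
priors; support tiers require *all* pairwise Bayes factors against the
competitors to exceed 1 / 3 / 10 / 30 / 100.

The default draw count is 100,000 per candidate per run. At that setting a
two-seed rerun of the main contest on a 100-participant synthetic cohort
reproduces the winner for at least 99% of participants with a mean
absolute posterior-probability deviation of about 0.004 (the acceptance
suite checks both), matching the stability the analysis requires.

Two engineering choices speed the contest without changing its
statistics. One prior-draw stream per candidate is shared across
participants within a run, which turns cohort scoring into one vectorized
pass; each participant's estimate is unchanged in distribution, and
stability checks use independent streams. `model_recovery()` similarly
shares scoring streams across the replications of a generating model.
The per-draw likelihood stream is shared between the marginal likelihood
and the posterior-predictive check, matching their coupled definitions and
halving cost.

## Group-level estimation

Participants are grouped by their winning model, each group's choices are
pooled (all members treated as draws from one group-level parameter set),
and the posterior — uniform prior times pooled Bernoulli likelihood — is
sampled by adaptive Metropolis-Hastings (`mh_sample()`). Defaults follow
the headline configuration where it is stated (half the chain discarded as
burn-in; desk-scale default 1e5 states, full-scale 1e6 behind the
`n_states` argument) and make engineering choices where it is not:

* Proposal: Gaussian, covariance `2.38^2/d` times the sample covariance of
  a recent window of states plus an additive diagonal `1e-6 * range^2`
  (the collapse guard), recalibrated only during burn-in — retained
  samples carry no adaptation bias. The recalibration cadence defaults to
  every `min(5000, n_burn/20)` states with a window of four spans: the
  5000/20000 schedule suits million-state chains, and shorter chains need
  proportionally faster adaptation so the start-up transient washes out of
  the covariance estimate. A global step multiplier is nudged toward a 23%
  acceptance rate at each recalibration.
* Start state: the best-scoring of 256 prior draws (`n_init`). A single
  prior draw can land in a region whose pooled log-likelihood is worse
  than the mode's by hundreds of thousands; a million-state chain absorbs
  the crawl back, a 1e5-state chain may not. Set `n_init = 1` for the
  plain prior start.
* Out-of-bounds proposals are rejected, preserving detailed balance for
  the truncated target.

Summaries are the median and the 95% highest density interval — the
single shortest contiguous window of sorted samples holding
`ceiling(0.95 N)` states (`hdi()`, verified against exhaustive
shortest-window search). On a 200-participant synthetic tradeoff-model
cohort (gamma 0.95, kappa 10, epsilon 4, theta 0.2) a 1e5-state chain
covers all generating values in its 95% HDIs; `parameter_recovery()`
automates that check.

## Posterior-predictive checking

`bayesian_p_value()` measures absolute fit: the probability that data
replicated from the model are more discrepant than the observed data,
under the sum-of-squares discrepancy `sum_i (d_i - p_i)^2` (the Pearson
chi-square is unusable here because predicted probabilities are routinely
within machine precision of 0 or 1). One replicate is drawn per prior
draw, and draws with `T(D_rep) > T(D)` contribute their self-normalized
importance weight. Replicate uniforms are attached to pairs in canonical
id order, so the p-value is exactly invariant to permuting the pair order.
The guess-only baseline has `T(D) = T(D_rep) = m/4` identically and hence
a p-value of exactly zero — by definition, not by underflow.

## Synthetic data: what it does and does not emulate

`simulate_cohort()` generates exactly what the analysis assumes: each
participant's choices are independent Bernoulli draws from one candidate
model at parameters drawn from (or fixed within) the uniform priors, with
truth labels kept in a separate table. The default acceptance-scale
conditions are a 100-participant cohort mixing TM/DIUM/SMNZ/SMZ at
.60/.15/.15/.10 — the approximate winner shares observed in this paradigm
— and hidden-zero cohorts of 200 per framing condition. All randomness
descends from one master seed through named substreams, so cohorts are
bit-reproducible.

Because generator and analysis share the same model class, passing tests
demonstrate *internal* consistency — correct likelihoods, unbiased
marginal-likelihood estimation, calibrated recovery — not that real
participants behave this way. Real data bring response noise that is not
Bernoulli-stationary, order and fatigue effects, and heterogeneity outside
the model class; none of these are simulated.

The hidden-zero generator applies the framing conventions at pair level:
a stated zero anywhere in a task triggers, under the zero-inferring
sequences model, the inference of the complementary zero in the other
option; under TM and SMNZ only stated cells ever count. The resulting
analytic predictions — TM: later zero raises expected patience, sooner
zero leaves it exactly unchanged; DIUM: no effect of either; SMZ: both
zeros equivalent — hold in expected probabilities before any sampling,
and `hidden_zero_asymmetry()` tests them statistically in simulated
cohorts with unpooled Wald intervals on condition differences (conditions
are independent groups; z = 1.96 matches the package's proportion-CI
convention, which reproduces the printed interval arithmetic that
exact and score intervals do not).

## Numerical choices

* Probabilities are clamped to [1e-300, 1 - 1e-15] *inside log terms
  only*; simulation uses raw probabilities. Log-likelihoods are therefore
  always finite even when `epsilon * Delta` saturates the logistic.
* The guess-only baseline's marginal likelihood is returned as `0.5^m`
  exactly (the Monte-Carlo mean of a constant), so Bayes factors against
  it are exact.
* `u(0) = 0` is enforced identically, never `0^gamma`.
* Degenerate options (all included utilities zero) make duration undefined
  and raise an error rather than returning a silent value.
* Winner selection breaks exact marginal-likelihood ties by candidate
  order; ties occur with probability zero under continuous draws.
* A dominance flag on a pair whose high-NPV option is not the dominant one
  raises an error rather than silently reorienting the adjustment.

## Scales used by the packaged checks

Test and acceptance runs use desk scales chosen as the package's own
defaults: model recovery at 250 replications per generating model with
10,000 scoring draws (the full 1,000-replication exercise is the same call
with `reps_per_model = 1000`); contests at 100,000 draws per candidate;
group-level chains at 1e5 states (1e6 behind `n_states`); quadrature
cross-checks on two-parameter model reductions at 201-point trapezoid
grids.

## Known limitations

* Gains only: loss and mixed-sign sequences are out of scope, as are
  similarity-modulated impatience weights (retained only as the concave
  `w` extension hook).
* The sequences model is implemented for contiguous-period designs; no
  within-sequence discounting.
* Group-level inference pools choices as if group members shared one
  parameter set; no hierarchical individual-level shrinkage.
* Convergence diagnostics are limited to two-seed agreement plus the
  acceptance-rate band, in keeping with the estimation design this
  package implements.
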