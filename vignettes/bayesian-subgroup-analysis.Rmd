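---
title: "Bayesian subgroup analysis of survival trials with elicited expert priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian subgroup analysis of survival trials with elicited expert priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survprior)
```

## The problem

Randomised trials are rarely powered for subgroup analyses: the usual
frequentist interaction test has low power, so clinically important
differences in treatment effect between subgroups go undetected, while
reporting per-subgroup estimates alone invites chance findings. When more
patients cannot be recruited, the remaining source of information is
expert opinion. This package implements a Bayesian subgroup analysis in
which expert beliefs — elicited before unblinding — are converted to a
bivariate normal prior on the two subgroup-specific treatment effects
and combined with the trial's time-to-event data in a Bayesian Cox
proportional-hazards model. Robustness is assessed over a *community of
priors* built by re-parameterising the elicited prior.

The motivating setting is a two-arm trial of a preoperative intervention
in diabetic patients undergoing cardiac surgery, outcome time until fit
for hospital discharge, with two binary subgroup factors of interest
(preoperative renal risk; oral-only versus insulin-based glucose
management). Throughout, `theta1` and `theta2` denote the treatment
effects (log hazard ratios) in the less-severe and more-severe subgroup,
and HR > 1 favours treatment (faster recovery).

## From elicited counts to log-hazard-ratio normals

Hazards are hard to elicit, so experts are instead asked: *of 100
treated patients, how many would be fit for discharge by day 6?* (the
registry median length of stay), giving a median and 2.5th/97.5th
percentiles, plus the same quantity under usual care. If `p1` and `p2`
are the treated and usual-care probabilities, proportional hazards gives

```
log(HR) = log( log(1 - p1) / log(1 - p2) )
```

implemented in `prob_pair_to_loghr()`. Each expert's three transformed
quantiles are fitted with a normal by least squares on the CDF
(`fit_normal_from_quantiles()`): the fitted normal minimises the sum of
squared differences between its CDF at the three points and
(0.025, 0.5, 0.975). For symmetric triples this is the closed form
`mean = q50`, `sd = (q975 - q025)/3.92`, which also starts the bounded
search (`sd` in `[1e-6, 10]` on the log-HR scale; Nelder–Mead plus an
L-BFGS-B polish, deterministic). Counts of 0 or 100 are clamped to
0.5/99.5 with a warning: the transform is undefined at the boundary and
a half-patient nudge is the smallest faithful perturbation of a count
questionnaire.

Experts are aggregated by linear opinion pooling: the equal-weight
mixture of their normals, summarised by moment matching
(`pool_experts()`). A moment-matched normal is used because the
bivariate prior construction below needs normal parameters; the raw
mixture is kept in an attribute for plotting. The comparator probability
is stored as a fixed point value, not a distribution — uncertainty is
carried entirely by the treated-arm quantiles.

## The bivariate prior and the community

Two unconditional questions give `theta1 ~ N(p1, s1^2)` and
`theta2 ~ N(p2, s2^2)`. Two further *conditional* questions ask about
the more-severe subgroup supposing the less-severe effect were (a) null
and (b) beneficial by a stated amount `d` (for the renal factor,
`d = log(log(0.3)/log(0.4)) ≈ 0.273`, i.e. 70 rather than 60 of 100
usual-care patients recovering). Writing `p20, s20` and `p2d, s2d` for
the two conditional normals, the clinical prior is
`N2(m, V)` with `m = (p1, p2)` and

```
V11 = s1^2
b12 = (p2d - p20) / d        # regression slope of theta2 on theta1
V12 = b12 * V11
V22 = (s20^2 + s2d^2)/2 + b12^2 * V11
```

Two sensitivity derivations are exposed as flags on
`build_clinical_prior()` rather than as community members, mirroring
their role as sensitivity analyses: `v22_mode = "unconditional"` uses
`V22 = s2^2` directly (accepted only when the resulting matrix is
positive definite — otherwise the construction stops with a
"sensitivity derivation rejected" error), and `mean_mode = "regression"`
replaces the theta2 mean by `p20 + b12 * p1`.

The community (`build_community()`) contains five specifications:

| label | mean | covariance | informative about |
|---|---|---|---|
| clinical | m | V | mean effect and interaction |
| sceptical | 0 | V | uncertainty only |
| interaction | m | V\* | interaction only (primary analysis) |
| interaction_variance | 0 | V\* | interaction only, null-centred |
| vague | 0 | L·I | nothing |

`V*` comes from re-parameterising with `C = [[1/2, 1/2], [-1, 1]]`, so
`psi = C theta` is (mean effect, interaction). `W = C V C'` is replaced
by `W* = diag(L, W22)` — vague about the average effect, elicited
variance `W22 = V11 + V22 - 2 V12` for the interaction `theta2 -
theta1`, zero covariance belief between them — and back-transformed:
`V* = C^-1 W* C^-T`. `L = 1e4` by default (prior SD 100 on a log hazard
ratio — flat beyond any plausible survival effect); it is configurable
because "arbitrarily large" is all that is required, and the invariants
`var(theta2 - theta1) = W22` (fixed in `L`) and `var(psi1) = L` are
tested at `L` in {1e2, 1e4, 1e6}.

## The Bayesian Cox model

The likelihood is the Cox partial likelihood with Efron's tie
correction, used directly as the Bayesian likelihood — the standard
fully-Bayesian Cox construction when the baseline hazard is a nuisance.
(The normal–normal conjugate shortcut that approximates the
log-likelihood by a quadratic is deliberately not taken; it fails at low
event counts, and the whole point here is small subgroups. It survives
as a test oracle.) The linear predictor contains
`theta1 * arm * (1 - subgroup)`, `theta2 * arm * subgroup`, a subgroup
main effect, and the five binary minimisation covariates. The subgroup
main effect is included (with a vague prior) so that the thetas are
interpretable as within-subgroup treatment effects; this is an
assumption, not something the source analysis states. Only
`(theta1, theta2)` receive the informative bivariate prior; every other
coefficient gets an independent `N(0, 1e4)`. Patients with a missing
subgroup are excluded from that factor's analysis with a logged count.

Sampling is by independence Metropolis–Hastings: the posterior mode and
Hessian are found by quasi-Newton optimisation (the Laplace
approximation), and a multivariate-t proposal (df 10, covariance 1.05²
times the Laplace covariance) is accepted/rejected against the exact
log posterior. Because the partial likelihood is smooth and concave and
the priors are normal, the posterior is near-Gaussian and acceptance
rates run at 0.75–0.9, giving effective sample sizes of more than half
the retained draws. This was chosen over hand-rolled HMC as the simplest
sampler whose correctness is easy to verify; Stan is not a dependency of
this package. Defaults are 4 chains × 2000 iterations (half warmup) with
a fixed, recorded seed; runs are reproducible bit-for-bit. The fit
*fails loudly* if split-Rhat on a theta exceeds 1.01; `run_analysis()`
records such a failure per prior and continues with the rest of the
community.

`fit_mle()` maximises the same Efron partial likelihood and reports Wald
95% intervals from the observed information, so every posterior is
interpretable against the frequentist baseline computed by the same
likelihood code (cross-checked against an independent Cox implementation
in the test suite to 1e-4). Separation (|beta| > 10) raises a warning.

## What the synthetic data emulate — and what they do not

No patient-level data or raw expert answers are published, so the
package carries generators with known ground truth.

`generate_trial()` emulates the 121-patient UK trial: 61/60 allocation,
subgroup prevalence 75/120 less-severe (renal) or 65/121 (glucose), one
missing subgroup value for the renal factor, covariate prevalences from
the published baseline table, and Weibull proportional-hazards event
times. Choices made once, on clinical plausibility: Weibull shape 1.5
(a fit-for-discharge hazard that rises with time) with scale set so the
baseline median is 6 days; administrative censoring at 30 days; times
recorded in whole days, producing the heavy ties a discharge-day
outcome really has (handled by the Efron correction); covariate effects
default to zero (pure nuisance adjustment) since no effect sizes are
published. The generator does *not* emulate minimisation-based
randomisation (simple 1:1 suffices for the statistical structure),
informative censoring, or any real correlation between covariates and
subgroups — a green end-to-end test establishes that the machinery
recovers known truths under proportional hazards, not that the original
trial's numbers are reproduced.

`generate_expert_answers()` emulates a 7-member panel with one sceptic
(expert A) and two enthusiasts (E, F), centred on a modest benefit that
is larger in the more-severe subgroup (pooled more-severe prior HR
≈ 1.27 in the shipped fixture), with per-expert SD 0.25 and conditional
slope `b12 = 0.5` decomposed self-consistently so that rebuilding the
prior from the generated counts recovers the configured parameters up to
count quantisation (±0.05 on the log-HR scale, the tested tolerance).

The scenario pack (`trial_scenarios()`) fixes three worlds: null and
common-benefit (HR 1.2) at the trial's n = 121, and a
qualitative-interaction scenario (theta1 = +0.35, theta2 = −0.35,
mimicking the observed pattern of a lower hazard ratio in the
more-severe subgroup) at n = 484 — four times the trial — chosen a
priori so each arm-by-subgroup cell has enough events for stable
subgroup MLEs in direction checks.

## Numerical choices and degenerate inputs

* Positive definiteness is declared when the smallest eigenvalue exceeds
  1e-10; every constructed `V` is symmetrised before the check.
* Quantile triples must be strictly increasing after transformation;
  equal quantiles are a validation error, not a zero-variance normal.
* The partial likelihood centres the linear predictor by its maximum
  before exponentiating; it is invariant to time shifts (rank-based) and
  to constant shifts of the predictor, both tested.
* Constant design columns (e.g. a single-subgroup dataset) are dropped
  with a message, and a lone theta then receives its marginal prior
  `N(m_i, V_ii)` — the exact marginal of the bivariate prior.
* Ties between events and censorings at the same time keep the censored
  subjects in the risk set.
* MCMC summaries require at least 1000 retained draws; `P(HR > 1)` is
  the fraction of draws with a positive coefficient.

## Known limitations

* The sampler's proposal is calibrated once at the mode; a severely
  multimodal or heavy-tailed posterior (not reachable with these
  concave likelihoods and normal priors) would mix poorly — the Rhat
  gate, not silent degradation, is the failure mode.
* One subgroup factor is analysed per run, matching the separate
  published analyses; the two factors are never modelled jointly.
* No frequentist multiplicity adjustment is applied: the joint Bayesian
  model is itself the multiplicity treatment, a documented position
  rather than a silent default.
* The published posterior estimates cannot be reproduced exactly —
  fixtures emulate the stated world, they do not replicate unpublished
  data. All empirical claims in this vignette are computed by the test
  suite or the examples, nothing more.
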