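---
title: "Methods: simulating and analysing cluster micro-randomized trials of team competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing cluster micro-randomized trials of team competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterMRT)
```

This vignette documents the models, the design choices behind them, and
what the package's simulations do and do not establish.

## The design being emulated

A cluster micro-randomized trial re-randomizes *groups* at many decision
points. Here the groups are teams of medical interns (minimum five members,
built from residency programs, with leftover interns pooled into
institution-based teams), and the decision points are the Mondays of a
12-week study. The weekly randomization has three factors:

1. **Competition coin.** Each team independently enters the competition arm
   with probability 1/2.
2. **Pairing rule.** One of three opponent-assignment rules is drawn with
   probability 1/3 each: total (any opponent), intra-institution, or
   intra-specialty. Competition-arm teams are shuffled uniformly and paired
   greedily under the rule's constraint. An odd leftover — or any team
   unpairable under a constrained rule — returns to the non-competition arm,
   flagged (`leftover`). The uniform shuffle makes the choice of which team
   is left over exchangeable; the greedy matching is a design decision, as
   no matching algorithm is canonical for this scheme.
3. **Type coin.** Each realized pair competes on average daily step count
   or average daily sleep minutes with probability 1/2 each.

`randomize_week()` implements exactly this. One pairing rule is drawn per
week and applied globally; a per-pair variant exists behind
`rule_scope = "pair"` because the design description admits either reading.
A consequence of the leftover rule is that the *realized* probability of
being in a competition is strictly below 1/2 (`realized_treatment_probability()`
quantifies it; it approaches 1/2 from below as the roster grows, and
is about 0.40 for 20 teams under mixed rules because constrained rules
strand unpairable teams).

## The generative model

`simulate_outcomes()` generates daily outcomes under a linear causal
excursion model. For intern $i$ of team $j$ on day $d$ of week $w$:

$$ y_{ijd} = b_i + \delta + \gamma w + u_j + e_i
  + A_{jw}\,\big(\beta_0 + \beta_w w + \beta_{II}\,II_{jw} + \beta_{IS}\,IS_{jw}\big)
  + \varepsilon_{ijd}, $$

where $b_i$ is the intern's pre-internship baseline, $\delta$ an
internship-onset shift, $\gamma$ a secular weekly trend, $u_j$ and $e_i$
Gaussian team- and intern-level intercepts, and $A_{jw}$ the indicator that
team $j$ competes *on the matching outcome type* in week $w$ ($II$/$IS$
flag intra-institution and intra-specialty pairings). Day-level noise
$\varepsilon$ is a stationary AR(1) process within intern
(default $\rho = 0.3$) so that lag-based imputation has real
autocorrelation to exploit. Mood is generated on a latent Gaussian scale
(intern anchor = a pre-internship mood value), shifted by a small amount
under any competition, and clipped to the 1–10 scale.

Default parameters are the study conditions: 191 teams with shifted-Poisson
sizes (minimum 5, mean 1779/191, so the expected cohort is ~1779 interns),
90 institutions, 12 specialties at the published marginal frequencies,
baseline steps $N(8121, 3229)$, baseline sleep $N(420.6, 107.5)$, week-0
effects 185.3 steps/day and 9.8 sleep-min/day with per-week changes −14.5
and −1.9, pairing moderation −90.3/+26.4 (steps) and 0.1/−1.5 (sleep),
secular trends −11.0 steps and 0.6 min per week, participation uplifts
0.003 (steps) and 0.009 (sleep), and a mood effect of 0.02. Values that no
source states — the noise SDs (team 300/10/0.3, intern 800/25/1.0, day
2500/60/1.5 for steps/sleep/mood), $\rho$, and the internship-onset shifts
— were chosen once as realistic for wearable step and sleep data, and the
within-team correlation is explicitly a free knob: nothing calibrates it.

Physical bounds (steps ≥ 0, sleep in [0, 1440]) are enforced by clipping.
Clipping censors a few percent of low-step person-days, which attenuates
the realized causal effect slightly relative to the nominal coefficient; the
`clip_outcomes = FALSE` switch removes the bounds so that
estimator-validation simulations have a generating coefficient that *is*
the estimand. Validation scenarios in the tests also zero the pairing
moderation so the fitted model matches the generating model.

**Missingness.** Each outcome is missing at random daily with a base
probability (defaults 0.31 steps / 0.52 sleep / 0.55 mood), shifted on the
logit scale by the standardized *most recent observed* value of that
outcome (so the mechanism depends only on observed data, i.e. genuinely
MAR), reduced while the team is in a competition week (the
participation-rate effect), and overridden by a weekly dropout hazard that
grows geometrically over the study (missingness rises as the study goes
on). Together these reproduce "above 30% / above 50%" individual-day
missingness for steps and sleep.

## Aggregation

All inference is at the team-week level. "Average of members' measurements"
is ambiguous under missingness between the pooled person-day mean and the
mean of member means; the default is the **mean of per-member weekly means
over members with at least one observed day** (each intern counts equally),
with the pooled mean as `method = "pooled"`. The two coincide on complete
or imputed data. Participation rates use the full denominator
`7 × all randomized members`, so dropouts count as non-participating days.
Week-0 previous-week controls use the pre-internship baseline team averages
rather than dropping the first week.

## Estimation

`wcls()` fits, by weighted least squares, a control working model plus a
causal part built from the centered treatment:
regressors $[Z, (A-\tilde p)(1, S)]$, row weights $\tilde p/p$ for treated
rows and $(1-\tilde p)/(1-p)$ otherwise, and a cluster-robust sandwich
variance over teams (equivalently, a GEE with independence working
correlation and robust SEs; on one row per cluster the sandwich is exactly
HC0, a tested identity). Defaults: $p = \tilde p = 0.5$, the *nominal*
coin, under which all weights are 1 and the fit is centered OLS. The
realized competition probability is below 0.5, but for a randomized
treatment the centering constant only shifts control coefficients, not the
causal terms — the package still exposes `prob`/`prob_tilde` so the
realized probability (from `realized_treatment_probability()`) can be used.

Two numerical points matter:

* **The controls must span the moderator basis.** If the centering constant
  differs from the realized treatment probability, any function of week in
  the moderator set but missing from the controls leaks a spurious shape
  into the effect curve. The standard templates include `week` among the
  controls; the spline fit adds its own basis to the controls for the same
  reason.
* **No small-sample sandwich correction by default.** The robust SE is the
  plain HC0-type cluster sandwich with a normal 1.96 multiplier; the
  Mancl–DeRouen bias-corrected meat is available via
  `vcov_type = "mancl-derouen"`. At 150+ clusters the default's empirical
  coverage in the package's own simulations is ~0.93–0.95.

Wald tests are two-sided and normal-based for single fits; after multiple
imputation, `pool_rubin()` uses the $t$ distribution with Rubin's
small-sample degrees of freedom $(M-1)(1 + W/((1+1/M)B))^2$.

Singular causal terms (e.g. a pairing-moderation column that never varies)
are an error by default; `drop_aliased = TRUE` — used by the pipeline and
the pairing template — drops them with a message and records them in the
fit, because degenerate weeks are routine in small simulated rosters.

## Multiple imputation

`impute_pmm()` is chained-equation predictive mean matching at the daily
level, sweeping steps → sleep → mood (a fixed order; the source does not
state one). Per target: a linear regression on three-day lags of all three
outcomes, previous-week intern means, sex, PHQ-9, neuroticism, early family
environment, and institution and specialty — the latter two as grouped
mean-encoded predictors, because indicator coding of ~90 institutions would
destabilize a within-trial regression. Parameters are drawn from the
Bayesian posterior per imputation (proper MI; a bootstrap variant by flag),
`k_donors = 5` nearest predicted means form the donor pool (the
conventional default; not stated in the source), 10 sweeps per dataset, and
$M = 20$ datasets by default. Lags before the study start use baseline
values; lags crossing missing cells use the sweep's current completed data.
Because imputed values are copied from observed donors, they always lie in
the observed support. The imputation model deliberately excludes the
treatment indicator (matching the stated predictor set); in simulations
with high missing-information fractions this attenuates effects, which is
visible in `compare_mi_vs_cc()` — under strong MAR tied to lagged outcomes
complete case is far more biased, under mild MAR the ordering can reverse.

## Post-stratification weights

`two_step_weights()` builds $w = w_1 \cdot w_2$: $w_1$ rakes on specialty;
$w_2$ rakes on sex and race within the surgical and nonsurgical specialty
groups, starting from the $w_1$-weighted sample. `rake()` is plain
iterative proportional fitting with a relative-deviation stopping rule.
Race categories outside White/Asian/underrepresented-minority are collapsed
into `urm_other` by an explicit, overridable mapping. Weights are
normalized to mean 1; trimming exists but is off by default. Whether and
how analysis weights enter the team-level fit is not dictated: `wcls()`
accepts an optional weight vector, `team_weights()` aggregates intern
weights to teams by the member mean (a decision — the source does not say),
and `run_trial()` reports weighted fits only when margins are supplied.

## Sensitivity analyses

`fit_spline_moderation()` replaces the linear effect-by-week function with
(a) a penalized thin-plate varying-coefficient smooth, REML smoothing, a
team random intercept for clustering, and Bayesian pointwise intervals
using the smoothing-uncertainty-corrected covariance; or (b) an unpenalized
natural cubic basis inside the WCLS fit with cluster-robust intervals. A
natural cubic spline with no interior knots is a straight line, so
`basis = "ns", df = 2` reproduces the linear moderation curve exactly — a
tested identity. `complete_case_dropout()` re-masks imputed values after an
intern's last observed day; `complete_case_weekly()` drops team-weeks with
more than five (configurable) missing person-days of the outcome — both
idempotent filters read "data points" as person-days, one plausible reading
of an ambiguous unit.

## Problem sizes in the test suite

The package's own validation uses: 500 replicates of a 150-team, 12-week
trial for WCLS bias, 95%-CI coverage (accepted band 0.93–0.97) and type-I
error (0.03–0.07); 60 replicates for the spline's bracketing of a linear
truth, whose estimate is compared with the 0.90 bound under a two-SE
binomial Monte-Carlo allowance; 12 replicates of a 40-team strong-MAR scenario for the MI-vs-CC
comparison; and 10,000 simulated weeks for the randomization-design
frequencies. These sizes trade Monte-Carlo resolution against runtime and
were fixed before the assertions were frozen.

## What passing tests do and do not show

The generator is Gaussian at every level with a linear effect model — the
world in which WCLS's working model is exactly right. Passing parameter
recovery therefore validates the *implementation* (algebra, weighting,
clustering, pooling), not robustness to real wearable data, which is
skewed, zero-inflated, device-censored and seasonally patterned. Likewise
the MAR missingness model matches the imputer's assumptions by
construction; nothing here tests MNAR. Within-team outcome correlation is
a free parameter, so absolute power numbers from `replicate_study()` should
not be read as the trial's power. Finally, the intra-institution /
intra-specialty moderation estimates in small rosters are frequently
inestimable (few constrained pairings); the pairing template drops such
terms explicitly rather than silently.
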