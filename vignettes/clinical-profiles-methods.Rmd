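---
title: "Modelling clinical profiles and recovery after sport-related concussion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clinical profiles and recovery after sport-related concussion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Sport-related concussion (SRC) presents heterogeneously: athletes with the
same diagnosis report very different symptom constellations and take very
different times to recover. One organizing idea in sports medicine is to
summarize the 22-item SCAT5 symptom checklist into a small set of
*clinical profiles* — vestibular, cognitive, fatigue, anxiety/mood,
headache/migraine, and ocular — and to ask whether profile presentation,
initial severity, and recovery differ by sex, and whether severity and
profile burden predict recovery and return-to-play (RTP). This package
implements that analysis end to end: checklist scoring, rule-based profile
classification, cohort assembly, a synthetic cohort generator, and the
hierarchical models that link sex, severity, profile counts, and outcomes.

```{r setup}
library(concussionprofiles)
```

## Severity scoring and the profile rule

Each SCAT5 evaluation rates 22 symptoms on a 0 (absent) to 6 (severe)
Likert scale. The *injury severity score* is the plain sum, so it ranges
from 0 to $22 \times 6 = 132$. Severities must be integers; fractional
input is rejected rather than rounded, because the instrument is ordinal.

A clinical profile is *assigned* when an athlete endorses at least half of
the symptoms that define it, where "endorse" means a rating at or above a
minimum severity (default 1 — any non-zero rating). Endorsement is binary:
once a symptom crosses the cut, its exact rating does not affect profile
membership. Two operationalizations of "at least half" are supported:

* `half_floor` (default): $\max(1, \lfloor n/2 \rfloor)$ endorsed symptoms
  out of $n$. This is the worked rule for the published definitions, which
  require 3 endorsed symptoms for a 7-symptom profile ($\lceil 7/2 \rceil$
  would give 4).
* `half_ceiling`: $\lceil n/2 \rceil$, the strict reading, selectable in
  the registry config.

Under `half_floor` the rule is monotone: raising any rating can only add
profiles, never remove them, and a zero-severity checklist always carries
zero profiles. The test suite verifies both properties against a
brute-force reference classifier on randomly generated checklists.

### The symptom-to-profile registry

Which symptoms define which profile is data, not code: the mapping ships
as an editable YAML file (`inst/extdata/profile_registry.yaml`) loaded by
`default_registry()`. The default is a mapping in the style of the
AMSSM concussion-subtype framework, constructed for this package with the
documented constraint that the cognitive, anxiety/mood, and ocular subsets
contain exactly 7 symptoms each; the loader warns when a config deviates
from that. Profiles deliberately share symptoms (e.g., headache
contributes to both the headache/migraine and ocular profiles), so
profiles are *not* mutually exclusive, and no down-weighting of shared
symptoms is applied — the classification literature that motivates the
rule specifies none. Alternative mappings drop in by editing the file.

## Cohort assembly and outcomes

An episode's trajectory starts within 48 h of injury (first evaluation at
day 0–2, with day 0 the injury day) and is evaluated daily. Outcome
definitions:

* **Time-to-recovery** — the day of the *final* daily evaluation, provided
  the athlete is asymptomatic there (total severity 0 by default). A
  trajectory that ends symptomatic — including a rebound with no clean
  final evaluation — is right-censored (`NA`). A return-to-baseline rule
  is supported through `asymptomatic_max` for settings where pre-season
  baselines are non-zero, but the self-contained zero-severity rule is the
  default.
* **Return-to-play** — the recorded clearance day after completing the
  graduated RTP protocol. It is passed through, not derived, and a
  clearance earlier than recovery is flagged as a record inconsistency
  rather than silently corrected.

Only sport-mechanism concussions are analyzed: non-sport and
uncertain-origin injuries differ systematically in severity and recovery,
so `apply_inclusion_filter()` removes them and reports counts by reason.
Free-text sports are collapsed into 11 groups
(`inst/extdata/sport_groups.yaml`, editable) so that the sport-level
random intercepts have workable cluster sizes.

## The synthetic cohort generator

Real multi-site concussion surveillance data are not redistributable, so
the package includes a generator whose *defaults are the study
conditions* the analysis assumes, and every downstream stage is exercised
against it. For athlete $i$ in sport group $g$ on day $t$:

$$\mu_{i}(t) = \beta_0 \, e^{b_g + b_i} \, e^{-\delta t}, \qquad
b_g \sim N(0, \sigma_g^2),\; b_i \sim N(0, \sigma_a^2)$$

with the observed daily total severity a zero-inflated negative-binomial
(NB2) draw around $\mu_i(t)$, capped at 132. Evaluations are emitted daily
until the first zero-severity day, which is the final evaluation and
defines recovery; athletes still symptomatic at the follow-up horizon are
censored. RTP is recovery plus a right-skewed negative-binomial clearance
lag.

Defaults, chosen once and not revisited:

| parameter | default | why |
|---|---|---|
| `baseline_mean_severity` | 35 | initial within-profile severity means of roughly 30–50 in collegiate cohorts |
| `decay_rate` | 0.18/day | calibration: $1 - e^{-0.18 \cdot 14} = 0.920$, the ~92% decline in the first 14 days; a calibration, not an estimate |
| `zi_prob` | 0.03 | occasional symptom-free days early in recovery; also sets the small mass of day-0 asymptomatic episodes |
| `nb_dispersion` | 3 | strong overdispersion typical of symptom totals |
| `sport_group_sd`, `athlete_sd` | 0.4, 0.9 | calibrated so grouping terms carry roughly half of the variance explained by the temporal severity model |
| `symptom_concentration` | 0.4 | see below |
| `non_sport_frac`, `uncertain_frac` | 82/579, 18/579 | observed exclusion rates in collegiate surveillance |
| `rtp_lag_mean` | 4 days | mean gap between asymptomatic status and full clearance |
| `max_followup_days` | 80 | symptoms occasionally persist two months or more |

Total severity is spread over the 22 symptoms by a capacity-respecting
weighted draw (each symptom holds at most 6 points), so profile
co-occurrence rises mechanically with total severity — the structural
fact the severity-to-profile-count model estimates. Two refinements make
the allocation realistic rather than uniform:

* **Base weights** (`default_symptom_weights()`) make headache and
  cognitive/ocular-adjacent symptoms common and affective symptoms rare,
  ordering the induced profile prevalences the way collegiate cohorts
  report them (ocular/cognitive highest, anxiety/mood lowest).
* **Per-athlete Dirichlet weights** (`symptom_concentration = 0.4`): each
  athlete draws an individual symptom mix around the base weights and
  keeps it across days. Without this, a moderate total spreads thinly over
  all 22 symptoms and nearly every athlete saturates all six profiles;
  with it, day-0 profile counts spread over the full 0–6 range. The
  within-day correlation structure of real symptom reports is unknown, so
  this is one defensible choice, exposed as a parameter.

Sex enters the generator only as a label by default (`sex_ratio = 0.5`):
the null of no sex effect is the generating truth, which is what makes
the pipeline's type-I error testable. For power studies,
`sex_severity_logfc` scales female severity and `sex_symptom_logw` boosts
specific symptoms for females only.

What the generator does **not** emulate: site/clinician effects beyond the
sport grouping, late symptom rebounds at 60–80 days, reporting behaviour
differences, missed daily evaluations, and multiple concussions per
athlete. Passing tests therefore demonstrate that the estimators recover
the structure they assume — not that real cohorts satisfy those
assumptions.

## The modelling layer

All models are generalized linear mixed models estimated by maximum
marginal likelihood with random intercepts integrated out by Laplace
approximation (engine: glmmTMB). The zero-inflated negative binomial is
$P(y) = \pi \cdot 1[y=0] + (1-\pi)\,\mathrm{NB2}(y;\mu,\theta)$ with a log
link on $\mu$, variance $\mu + \mu^2/\theta$, and an intercept-only logit
zero-inflation component — whether zero inflation varies with covariates
is not identifiable from the data structure assumed here, so covariates
are not placed on $\pi$ by default.

Model-by-question:

* **Temporal trends**: daily severity and daily profile count, ZINB with a
  natural-spline day effect and random intercepts for sport group and
  athlete-within-sport-group (two terms: `(1|group)` and
  `(1|group:athlete)`). The headline diagnostic is the percent decline of
  the population-level predicted mean from day 0 to day 14, plus a
  linear-time (df = 1) comparison fit.
* **Q1**: per profile, Bernoulli (profile present ~ sex + sport-group
  intercept).
* **Q2/Q3**: per profile, NB2 (initial severity, or recovery days among
  observed recoveries, ~ sex + sport-group intercept). NB2 accommodates
  the strong right skew of recovery times; a Gamma alternative would be
  defensible but adds nothing on count-valued days.
* **Q4**: binomial with 6 trials (profile count out of 6) on a natural
  spline of initial severity interacted with sex. The 6-trial binomial
  logit reproduces the saturating, logistic-growth-like shape of the
  severity-to-profile-count relationship; the fitted curve is summarized
  by a band table giving the severity ranges whose rounded predicted
  counts are 0–1, 2–5, and 6.
* **Q5**: NB2 models of recovery and RTP days on a natural spline of
  profile count interacted with sex, with sex contrasts at each observed
  integer count and per-sex marginal means averaged over the observed
  count distribution.

### Splines, contrasts, uncertainty, and $R^2$

Nonlinear effects use natural cubic splines with knots at quantiles,
default df 3. The basis is built once from the estimation data and
re-evaluated on prediction grids, so knots never shift between fitting
and prediction; grids beyond the boundary knots trigger an extrapolation
warning. Heavily tied covariates can collapse quantile knots; the basis
then drops the duplicates and reduces the effective df with a warning.
The profile-count splines (Q5) default to df 2 because the predictor
takes only seven distinct values, massed at the top of the range.

Conditional effects are population-level (random effects at zero):
inverse-link of the fixed linear predictor, with 95% Wald intervals
formed on the linear-predictor scale and transformed, so the bounds
always bracket the estimate. For ZINB the conditional mean is scaled by
$1-\hat\pi$; the zero-inflation intercept's uncertainty is not propagated
(it is a single well-estimated nuisance parameter in these designs).

Sex contrasts are tested on the link scale (Wald test of the
linear-predictor difference, the standard GLMM practice) while the
estimate, CI, and effect size are reported on the response scale via the
delta method. Cohen's $d$ for a contrast is the response-scale difference
divided by the pooled family standard deviation at the average predicted
mean ($\sqrt{p(1-p)}$-type for binomial, $\sqrt{\mu + \mu^2/\theta}$ for
NB2); magnitudes use lower-inclusive bands at 0.2/0.5/0.8 for $d$ and
0.7/0.8/0.9 for $|r|$. Per-count contrasts are *not* multiplicity
adjusted — they are reported as a coherent family alongside effect sizes,
and an adjustment can be applied downstream if a strict error rate is
needed.

Variance explained is Nakagawa-style: latent-scale variance is decomposed
into the variance of the fixed linear predictor, the summed
random-intercept variances, and a distribution-specific residual
($\pi^2/3$ for logit models; the lognormal approximations
$\ln(1 + 1/\lambda)$ and $\ln(1 + 1/\lambda + 1/\theta)$ for Poisson and
NB2/ZINB, with $\lambda$ the mean fitted value). Marginal $R^2$ uses
fixed effects only, conditional $R^2$ adds random terms, and
`random_share` — the random fraction of explained variance — is the
statistic that describes how much of the model's explanatory power sits
in the athlete/sport hierarchy.

### Numerical choices

The optimizer is nlminb via TMB; when it reports false convergence or a
non-positive-definite Hessian, the fit restarts deterministically with
BFGS and the better-converged result is kept. Non-convergence is never
silent: fits carry a `converged` flag, emit a warning, and
`variance_explained()` refuses non-converged input. Factors with a
single level are rejected for fixed effects (inestimable) and dropped
with a warning for random terms, which also makes single-group data
reduce exactly to the GLM solution — a property the tests exploit as an
independent oracle (`stats::glm`, `MASS::glm.nb`).

## Problem sizes and what the tests show

The study-scale checks run on a 500-athlete default cohort (seed 1) for
the temporal decline and severity-to-profile-count shape; estimator
calibration uses 200 simulated ZINB mixed-model datasets of 300
observations in 30 groups (95% Wald coverage of both fixed effects within
95% ± 4 points); and composed-pipeline error control uses 100 null-cohort
replicates of 250 athletes, checking that the per-profile sex tests
reject near the nominal 5% (the six p-values per cohort are positively
correlated because profiles share symptoms, so the acceptance band uses
correlation-inflated binomial error). These sizes were chosen as the
smallest that make the statistical checks sharp.

## Known limitations

* The default symptom-to-profile mapping is a constructed, documented
  approximation of the published subtype framework, not a transcription
  of any single source; substantive use should supply the mapping under
  study via the registry config.
* Recovery is defined by the final evaluation being asymptomatic;
  alternative clinical definitions (e.g., first of N consecutive
  asymptomatic days) would need a different rule.
* Per-profile models treat overlapping athletes independently (an athlete
  with three profiles enters three models), matching the
  non-mutually-exclusive design but inflating cross-model dependence.
* No random slopes, crossed random effects, or Bayesian estimation; the
  zero-inflation component is intercept-only.
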