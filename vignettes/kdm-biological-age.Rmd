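---
title: "Biological age, age acceleration and mortality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biological age, age acceleration and mortality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`kdmage` estimates biological age (BA) from clinical markers with Klemera
and Doubal's weighted estimator, derives age acceleration (AA), and relates
AA to all-cause mortality in a four-group cardiovascular-continuum cohort.
This vignette is the package's account of the underlying models, the
numerical choices, and what the synthetic cohorts do and do not establish.

## The marker model and the estimator

Each marker (on its analysis scale — natural log for biochemical markers
except albumin, raw for physical measurements) is assumed linear in true
biological age `BA`:

    x_j = q_j + k_j * BA + e_j,   e_j ~ N(0, s_j^2), independent across j.

Since `BA` is latent, the regressions are run against chronological age
(CA). Candidate markers are screened per sex: retained when the absolute
Pearson correlation with CA exceeds 0.10 and the age relation is monotone.
The absolute value matters — markers falling with age (FEV1, albumin) are
as informative as rising ones. Monotonicity is judged by a deterministic
half-split test: separate least-squares slopes above and below the median
CA, flagged non-monotone when the slopes differ in sign and each is
significant at the two-sided 0.05 level. Retained markers are standardized
and rotated to correlation-matrix principal components; all full-rank
components enter the estimator (no retention cut; components are not
re-screened against CA, because weakly age-correlated components receive
nearly zero weight automatically).

With per-component parameters `(q_j, k_j, s_j)` from regressing scores on
CA, the uncorrected estimate is the inverse-variance weighted combination

    BA_E = sum_j (x_j - q_j) k_j / s_j^2 / sum_j k_j^2 / s_j^2,

and the corrected estimate adds CA as one more composite marker, weighted
by the inverse of `s_BA^2 = Var(BA - CA)`:

    BA_EC = [ sum_j (x_j - q_j) k_j / s_j^2 + CA / s_BA^2 ]
            / [ sum_j k_j^2 / s_j^2 + 1 / s_BA^2 ].

As `s_BA^2` grows, `BA_EC` tends to `BA_E`; as it shrinks, to CA. AA is the
residual of `BA_EC` regressed on CA; by least-squares construction it has
mean zero and zero correlation with CA in the regression pool. The primary
pipeline fits that regression on the whole analysis cohort; the sensitivity
pipeline fits everything — screening, standardization, loadings, weights
and the AA regression — in the control group only and projects the case
groups through the frozen construction.

## Separating the latent variance from estimator noise

`s_BA^2` is the delicate quantity. The observed `Var(BA_E - CA)` is the sum
of the latent spread `s_BA^2` and the estimator's own sampling noise; but
each marker's residual variance on CA is itself inflated by the latent
spread (`s_j,CA^2 = noise_j^2 + k_j^2 s_BA^2`), because the residual
absorbs it. The textbook correction expresses the noise through a
characteristic correlation `r_char` and assumes all inputs comparably
informative. After a principal-component rotation that assumption fails
badly: the age signal concentrates in the first component and the
remaining, nearly age-uncorrelated components drive `r_char` toward zero,
making the correction diverge (the estimate floors and BA collapses onto
CA). The same degeneration occurs with heterogeneous marker panels.

The package therefore solves the separation self-consistently at the
marker level. With weights `w_j = k_j / s_j^2` held fixed, the noise
variance of `BA_E` given a latent variance `v` is

    N(v) = sum_j w_j^2 (s_j^2 - k_j^2 v) / (sum_j w_j k_j)^2,

and `s_BA^2` solves the fixed point `v = Var(BA_E - CA) - N(v)`, a
one-dimensional root bracketed on `[0, Var(BA_E - CA)]` (the left side is
increasing, the right side non-increasing in `v`). This is exact under the
linear-marker model for arbitrarily heterogeneous panels; weak markers have
small weights and correspondingly small influence. The classical
`r_char`-based form remains available in `fit_kdm(s_ba2_method = "rchar")`,
and the root-mean-square marker–age correlation is always reported as a
diagnostic. Before the component stage, each component's residual variance
is *deconflated* by subtracting `k_j^2 s_BA^2` (bounded below at 5% of the
raw residual SD), so the weights reflect measurement noise only; without
this the CA anchor over-shrinks the estimate and group contrasts in AA
attenuate by roughly half.

Numerical floors: per-component residual SDs at `1e-6` (so exactly
noiseless components remain usable — in the noiseless limit `BA_EC` equals
CA to machine precision, end-to-end through PCA); `s_BA^2` at
`0.01 yr^2` (flag `s_ba2_floored` records when the correction overshot).

## Preprocessing rules

The exclusion cascade runs in a fixed order — sample-quality flags,
under-LOD flags, missing marker values, then marker outliers — with the
outlier mean and SD computed per marker on the records surviving the first
three filters, pooled across sexes (a configurable choice; the pooled form
is the default because the outlier screen predates the sex-stratified
construction). "Outside 4 SD" is strict inequality: a value at exactly
`mean + 4*SD` stays. Flags are treated as mutually exclusive with
first-match precedence in the printed order, which makes the per-category
counts of a cascade unambiguous; LOD and sample-quality problems are
treated as sample-wide rather than marker-specific. Harmonization adds
15/10 mmHg to systolic/diastolic pressure of antihypertensive users (an
applied-flag guard prevents double adjustment), prefers fasting over random
plasma glucose, and log-transforms with the natural logarithm. The dietary
score (0–5) and lifestyle score (0–4, risky = 3–4) follow fixed frequency
criteria; the activity split uses strictly-below the age-band (<50, 50–59,
>=60) by sex median, ties landing on the non-risky side.

## Survival models

The mortality association uses Cox partial likelihood on the attained-age
time scale — delayed entry at baseline CA, exit at age of death or
censoring — so age itself never appears as a covariate; baseline hazards
are stratified jointly by 5-year age band, ten study areas and the four
sampling groups, with sex, fasting status (>= 8 h) and three-level
education as covariates. Ties use the Efron approximation. Effect
modification is tested by likelihood-ratio comparison of models with and
without exposure-by-factor product terms (`chi^2`, levels − 1 degrees of
freedom); the age split for subgroups is <60 vs >=60. Subgroup models reuse
the whole-sample AA rather than re-deriving it within subgroup. A scaled
Schoenfeld-residual trend test is reported for the exposure but never acted
on automatically. Per-SD estimates divide AA by its regression-pool SD, so
per-SD and per-year log hazards are related exactly by that SD.

Prediction models for the discrimination analysis instead use time-on-study
with strata by area and group, Breslow tie handling (so the baseline
cumulative hazard is the plain Breslow estimator), and the basic covariate
set plus urban/rural and lifestyle factors. Ten-year risk is
`1 - exp(-H_0s(10) exp(x'b))` with the stratum-specific baseline evaluated
at covariate value zero and an uncentered linear predictor — the two
reference points must match, which is easy to get silently wrong with
centered defaults. Strata whose follow-up never reaches the horizon yield
missing risks. Harrell's C uses the original pairwise definition over the
full follow-up (a death forms a usable pair with anyone still at risk at
that time; risk-score ties count one half); the two-category NRI at the
50% threshold drops subjects censored alive before ten years, the
transparent classical choice (an inverse-probability-weighted NRI would
retain them but is not implemented). Confidence intervals are percentile
bootstrap over subject resamples, stratified by sampling group to preserve
the design, 200 replicates by default.

## What the synthetic cohorts emulate

The generator draws, per subject, a latent AA `Delta ~ N(group mean,
aa_sd^2)` defining `BA = CA + Delta`, markers linear in `BA` on their
analysis scale, and a death time with hazard `h_g(t) exp(0.182 * Delta +
covariate effects)` (exponential baseline by default, Gompertz optional),
censored administratively at 13 years. Its defaults are the study
conditions the analysis assumes: group sizes 4197/876/3837/3467, group AA
means −0.3/0.1/0.0/0.3 years with SD 1.4, ages uniform on 30–79 across ten
areas, marginal mortality near 13/103/16/85 per 1000 person-years (the
baseline rates are those targets deflated by the mean hazard multiplier of
the default covariate and AA effects, ~1.33), and a hazard ratio of 1.20
per year of AA. Covariates are drawn as independent categoricals with
realistic marginals (e.g. smoking 70% in men, 4% in women); their joint
dependence is not modelled.

The 25-marker panel (8 physical, 17 biochemical; 16 retained after
screening, with deliberately weak and one non-monotone marker to exercise
the screens) is synthetic: names and typical values are realistic, but the
noise SDs are calibrated once so that the *cohort-level* diagnostics match
the intended conditions under `aa_sd = 1.4` — observed AA SD ≈ 1.4 years,
`r(BA, CA)` ≈ 0.99, RMSE ≈ 1.4 years. That calibration implies individual
marker–age correlations far stronger than any real single clinical marker;
a real panel reaches the same cohort-level precision only through many
weakly informative markers. Consequently, passing recovery tests shows the
estimator chain is correct and well calibrated under its own model — not
that a particular real marker panel would achieve these diagnostics.

Also not emulated: the case-control selection mechanics of the source
design (controls selected to be event-free for years enjoy immortal time
that shifts their time-to-death distribution late; the generator's control
deaths occur earlier), registry-based outcome ascertainment, and any
dependence of marker noise on covariates. The exclusion fixture plants
category counts with bounded-uniform marker noise so that exactly the
requested records fail each filter, which is what makes the cascade's
arithmetic testable to the single record.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| screening threshold | 0.10 | abs. correlation | applied per sex |
| outlier cut | 4 | SD | strict inequality |
| s_BA^2 floor | 0.01 | yr^2 | logged when hit |
| component residual floor | 1e-6 (fit), 5% of raw SD (deconflation) | score units | keeps noiseless limits defined |
| admin. censoring | 13 | years | enrolment-to-censor window |
| hazard slope | 0.182 | log HR per year AA | generator truth |
| NRI threshold | 0.50 | probability | 10-year horizon |
| bootstrap | 200 | replicates | percentile, group-stratified |

## Problem sizes

The default pipeline runs at the full analysis-set size (12,377 simulated
participants). The test suite uses scaled-down cohorts — roughly 500–2,500
subjects for construction properties, 10,000 for the hazard-slope recovery,
500 replicates of n = 2,000 for the interaction-test calibration — sizes
chosen so each check retains the power it needs while the whole suite stays
a desk-scale run. The acceptance script regenerates everything it reports
from scratch at these sizes.

## Known limitations

- `s_BA^2` separation relies on second moments; with a single effective
  component and no marker-level heterogeneity it is unidentifiable, and at
  moderate n its sampling error puts a floor on how precisely the CA-anchor
  weight is estimated (a few percent attenuation of AA contrasts at
  n ≈ 500 per sex).
- The monotonicity screen tests a sign reversal between age halves; a
  marker plateauing without reversal passes.
- The NRI drops early-censored subjects rather than reweighting them.
- The generator's exponential baseline has no age trend within strata;
  stratification on the attained-age scale absorbs this in analysis, but
  absolute survival curves are not age-realistic.
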