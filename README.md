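# kdmage

Klemera–Doubal biological age, age acceleration, and all-cause mortality in
a cardiovascular-continuum cohort.

## The problem

People of the same chronological age (CA) age at different paces. A
*biological age* (BA) built from routine clinical markers summarises that
pace, and the *age acceleration* (AA) — how much a person's BA exceeds what
is expected at their CA — is a candidate risk marker. `kdmage` implements a
complete, tested pipeline for this analysis in a cohort of four groups
along the cardiovascular-disease continuum (controls and participants who
later developed a major coronary event, ischemic stroke, or hemorrhagic
stroke): cohort preprocessing, sex-stratified BA construction, mortality
association, and discrimination analysis, together with a seeded
synthetic-cohort generator that emulates the statistical structure such a
study assumes (the real cohort data are access-restricted), with latent
ground truth for recovery tests.

## The estimator

Within each sex, candidate markers are screened (|Pearson r| with CA >
0.10, and a monotone age relation), standardized, and rotated to
correlation-matrix principal components. Each retained component `j` is
regressed on CA, giving an intercept `q_j`, slope `k_j`, residual SD `s_j`
and correlation `r_j`. Klemera and Doubal's weighted estimator combines the
per-component age estimates,

    BA_E = sum_j (x_j - q_j) k_j / s_j^2  /  sum_j k_j^2 / s_j^2 ,

and the corrected form treats CA itself as one more composite marker
weighted by the inverse of `s_BA^2`, the population variance of true BA
around CA:

    BA_EC = [ sum_j (x_j - q_j) k_j / s_j^2 + CA / s_BA^2 ]
            / [ sum_j k_j^2 / s_j^2 + 1 / s_BA^2 ] .

`s_BA^2` is estimated at the marker level by a self-consistent variance
separation (see the methods vignette in `vignettes/`), and component
residuals are deconflated of the latent spread before weighting. AA is the
residual of `BA_EC` regressed on CA; the association with all-cause
mortality is a Cox model on the attained-age time scale, stratified jointly
by 5-year age band, study area and sampling group, adjusted for sex,
fasting status and education. Discrimination of 10-year mortality is
compared between prediction models with and without AA by Harrell's C-index
and the two-category net reclassification improvement at the 50% risk
threshold.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(`01_simulate.R` … `06_sensitivity.R`); each stage reads the previous
stage's files, prints what it found and writes tables under `results/`
(participant-level intermediates go to `scratch/`). Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_fit_ba.R
Rscript analysis/04_associate.R
```

prints, at the default seed:

```
simulated 12377 participants (control: 4197, MCE: 876, IS: 3837, ICH_SAH: 3467)
...
  12295 of 12377 participants retained
...
female: 17 markers retained, 17 components, s_BA^2 = 2.02 yr^2
male: 16 markers retained, 16 components, s_BA^2 = 1.98 yr^2
population  n      AA mean (SD)    RMSE   r(BA,CA)
all        12295    0.00 (1.39)   1.38    0.995
control     4177   -0.27 (1.37)   1.37    0.995
MCE          871    0.05 (1.42)   1.42    0.995
IS          3815    0.02 (1.37)   1.36    0.995
ICH_SAH     3432    0.29 (1.36)   1.35    0.995
...
overall: HR 1.22 (1.19, 1.25) per year of AA; 1.32 per SD
```

Read: the exclusion cascade kept 12,295 of 12,377 simulated participants
(82 marker outliers beyond 4 SD); BA tracks CA closely (r = 0.995, RMSE
1.38 years) while the groups differ in mean AA exactly as generated
(controls decelerated by ~0.3 years, hemorrhagic-stroke cases accelerated
by ~0.3 years); and each additional year of AA multiplies the all-cause
mortality hazard by about 1.2, recovering the generating log-hazard slope.
The same computations are available programmatically via `run_pipeline()`.

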