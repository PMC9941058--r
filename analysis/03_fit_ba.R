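#!/usr/bin/env Rscript
# Stage 3: sex-stratified Klemera-Doubal biological age and age acceleration.
#
# Per sex: markers screened at |r| > 0.10 against chronological age with a
# monotonicity check, transformed to correlation-matrix principal
# components, and combined by the corrected Klemera-Doubal estimator with
# chronological age as an additional composite marker weighted by 1/s_BA^2.
# Age acceleration is the residual of biological age regressed on
# chronological age across the whole analysis cohort.

library(kdmage)

analysis <- read_cohort("scratch/data/cohort_analysis.tsv")
# measurement rules were applied in stage 2; flag the table accordingly
attr(analysis, "harmonized") <- TRUE

fit <- fit_ba(analysis)
analysis$ba <- fit$ba$ba
analysis$aa <- fit$ba$aa
analysis$aa_standardized <- fit$ba$aa_standardized

for (m in fit$models) {
  cat(sprintf("%s: %d markers retained, %d components, s_BA^2 = %.2f yr^2\n",
              m$sex, length(m$markers), m$model$m, m$model$s_ba2))
}
tab <- ba_summary_table(analysis)
cat("population  n      AA mean (SD)    RMSE   r(BA,CA)\n")
for (i in seq_len(nrow(tab))) {
  cat(sprintf("%-10s %5d  %6.2f (%.2f)   %.2f    %.3f\n",
              tab$population[i], tab$n[i], tab$aa_mean[i], tab$aa_sd[i],
              tab$rmse[i], tab$pearson_r[i]))
}

write_cohort(analysis, "scratch/data/cohort_ba.tsv")
write.table(tab, "results/ba_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_kdm_fit(fit, "results/kdm_fit_primary.json")
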