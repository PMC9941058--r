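#' Predicted 10-year mortality risk from a stratified Cox model
#'
#' Fits a time-on-study Cox model stratified by the given factors (Breslow
#' ties, so the baseline cumulative hazard is the Breslow estimator) and
#' returns each subject's predicted probability of death within `horizon`
#' years: `1 - S0_stratum(horizon)^exp(lp)`. Subjects in strata whose
#' follow-up never reaches the horizon get a missing risk.
#'
#' @param cohort analysis cohort.
#' @param covariates model covariates (e.g. the basic set plus `"ca"` or
#'   `c("ca", "aa")`).
#' @param strata stratum factors (default study area and sampling group).
#' @param horizon prediction horizon in years.
#' @param label model label attached to the result.
#' @return data.frame with `id`, `risk`, and attributes `label` and `fit`.
#' @export
predict_risk_10yr <- function(cohort, covariates,
                              strata = c("area", "group"), horizon = 10,
                              label = paste(covariates, collapse = "+")) {
  cohort <- prepare_cox_columns(cohort)
  cohort$.stratum <- if (length(strata)) {
    interaction(cohort[strata], drop = TRUE)
  } else factor(rep("all", nrow(cohort)))
  f <- as.formula(paste("survival::Surv(followup_years, died) ~",
                        paste(c(covariates, "survival::strata(.stratum)"),
                              collapse = " + ")))
  fit <- survival::coxph(f, data = cohort, ties = "breslow")
  # uncentered pair: baseline at covariate value zero, lp = X %*% beta
  bh <- survival::basehaz(fit, centered = FALSE)
  lp <- predict(fit, type = "lp", reference = "zero")
  if (is.null(bh$strata)) bh$strata <- factor(rep(levels(cohort$.stratum)[1],
                                                  nrow(bh)))
  strat_lab <- sub("^\\.stratum=", "", as.character(bh$strata))
  risk <- rep(NA_real_, nrow(cohort))
  for (s in levels(cohort$.stratum)) {
    rows <- cohort$.stratum == s
    if (max(cohort$followup_years[rows]) < horizon) next
    hs <- bh[strat_lab == s, , drop = FALSE]
    h0 <- if (any(hs$time <= horizon)) max(hs$hazard[hs$time <= horizon]) else 0
    risk[rows] <- 1 - exp(-h0 * exp(lp[rows]))
  }
  out <- data.frame(id = cohort$id, risk = risk, stringsAsFactors = FALSE)
  attr(out, "label") <- label
  attr(out, "fit") <- fit
  out
}

#' Harrell's concordance index for censored survival data
#'
#' Probability of concordance over usable pairs: for a subject dying at time
#' `t` and another still at risk at `t`, the pair is concordant when the
#' death carries the higher risk score; risk ties count one half.
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param risk risk scores (higher = worse prognosis).
#' @return the concordance index in [0, 1].
#' @export
harrell_c <- function(time, event, risk) {
  if (length(time) < 2) stop_kdm("need at least two subjects")
  if (sum(event) == 0) stop_kdm("no events: concordance undefined")
  ok <- !is.na(risk)
  cfit <- survival::concordance(survival::Surv(time[ok], event[ok]) ~ risk[ok],
                                reverse = TRUE)
  unname(cfit$concordance)
}

#' 10-year vital status for reclassification analysis
#'
#' `1` for death within the horizon, `0` for subjects under observation at
#' the horizon (or dying later), `NA` for subjects censored alive before the
#' horizon — the latter are dropped from the reclassification table.
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param horizon years.
#' @return integer vector with NAs.
#' @export
status_10yr <- function(time, event, horizon = 10) {
  ifelse(event & time <= horizon, 1L, ifelse(time >= horizon, 0L, NA_integer_))
}

#' Two-category net reclassification improvement
#'
#' With risk categories split at `threshold`, the NRI is
#' `[P(up | event) - P(down | event)] - [P(up | non-event) - P(down |
#' non-event)]`, where up/down means crossing the threshold from the
#' reference to the new model. Subjects with missing status or risk are
#' excluded.
#'
#' @param risk_ref,risk_new predicted probabilities under the two models.
#' @param status_10yr 0/1/NA vital status at the horizon.
#' @param threshold risk threshold (default 0.50).
#' @return the NRI (in [-2, 2]).
#' @export
nri_binary <- function(risk_ref, risk_new, status_10yr, threshold = 0.50) {
  ok <- !is.na(status_10yr) & !is.na(risk_ref) & !is.na(risk_new)
  s <- status_10yr[ok]
  hi_ref <- risk_ref[ok] >= threshold
  hi_new <- risk_new[ok] >= threshold
  if (sum(s == 1) == 0 || sum(s == 0) == 0) {
    stop_kdm("need both events and non-events for the NRI")
  }
  up <- !hi_ref & hi_new
  down <- hi_ref & !hi_new
  (mean(up[s == 1]) - mean(down[s == 1])) -
    (mean(up[s == 0]) - mean(down[s == 0]))
}

#' Percentile bootstrap confidence interval over subject resamples
#'
#' Nonparametric bootstrap at the subject level, optionally stratified so
#' each stratum keeps its size in every resample. The statistic may return a
#' named numeric vector; an interval is returned per element. Fails when
#' more than 10% of resamples error out or return missing values.
#'
#' @param statistic function(cohort) -> numeric (possibly vector).
#' @param cohort data.frame resampled by rows.
#' @param reps bootstrap replicates (>= 50).
#' @param seed RNG seed.
#' @param strata optional column name preserving design strata.
#' @param conf confidence level.
#' @return matrix with rows `low`/`high`, one column per statistic element.
#' @export
bootstrap_ci <- function(statistic, cohort, reps = 200, seed = 1L,
                         strata = NULL, conf = 0.95) {
  if (reps < 50) stop_kdm("need at least 50 bootstrap replicates")
  idx_pool <- if (is.null(strata)) list(seq_len(nrow(cohort))) else
    split(seq_len(nrow(cohort)), cohort[[strata]])
  draws <- with_seed(seed, {
    lapply(seq_len(reps), function(i) {
      idx <- unlist(lapply(idx_pool, function(p) {
        sample(p, length(p), replace = TRUE)
      }), use.names = FALSE)
      tryCatch(statistic(cohort[idx, , drop = FALSE]),
               error = function(e) NULL)
    })
  })
  ok <- !vapply(draws, is.null, logical(1))
  vals <- do.call(rbind, draws[ok])
  ok_rows <- complete.cases(vals)
  if (sum(ok_rows) < 0.9 * reps) {
    stop_kdm("statistic undefined on more than 10%% of bootstrap resamples")
  }
  apply(vals[ok_rows, , drop = FALSE], 2, quantile,
        probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE) |>
    (\(m) {rownames(m) <- c("low", "high"); m})()
}

basic_risk_covariates <- c("sex", "fasting8", "education", "urban",
                           "current_smoker", "excessive_alcohol",
                           "dietary_score", "total_activity")

# C-indexes of the two prediction models and their NRI on one cohort.
discrimination_stat <- function(cohort, strata, threshold, horizon,
                                basic = basic_risk_covariates) {
  r_ref <- predict_risk_10yr(cohort, c(basic, "ca"), strata, horizon)
  r_new <- predict_risk_10yr(cohort, c(basic, "ca", "aa"), strata, horizon)
  st <- status_10yr(cohort$followup_years, cohort$died, horizon)
  c(c_ca = harrell_c(cohort$followup_years, cohort$died, r_ref$risk),
    c_ca_aa = harrell_c(cohort$followup_years, cohort$died, r_new$risk),
    nri = nri_binary(r_ref$risk, r_new$risk, st, threshold))
}

#' Discrimination comparison of prediction models with and without AA
#'
#' For all participants and each sampling group: Harrell's C-index of the
#' basic prediction model plus chronological age, of the same model with age
#' acceleration added, and the two-category NRI at the risk threshold, each
#' with percentile-bootstrap confidence intervals (resampling subjects,
#' stratified by group).
#'
#' @param cohort analysis cohort with lifestyle columns
#'   (see [add_lifestyle_columns()]) and an `aa` column.
#' @param reps bootstrap replicates.
#' @param seed RNG seed.
#' @param threshold NRI risk threshold.
#' @param horizon prediction horizon (years).
#' @return data.frame, one row per population, with point estimates and CIs.
#' @export
discrimination_table <- function(cohort, reps = 200, seed = 1L,
                                 threshold = 0.50, horizon = 10) {
  groups <- levels(factor(cohort$group))
  rows <- lapply(c("all", groups), function(g) {
    sub <- if (g == "all") cohort else cohort[cohort$group == g, , drop = FALSE]
    strata <- if (g == "all") c("area", "group") else "area"
    est <- discrimination_stat(sub, strata, threshold, horizon)
    ci <- bootstrap_ci(function(d) {
      discrimination_stat(d, strata, threshold, horizon)
    }, sub, reps = reps, seed = seed, strata = if (g == "all") "group" else NULL)
    data.frame(population = g, n = nrow(sub), events = sum(sub$died),
               c_ca = est["c_ca"], c_ca_low = ci["low", "c_ca"],
               c_ca_high = ci["high", "c_ca"],
               c_ca_aa = est["c_ca_aa"], c_ca_aa_low = ci["low", "c_ca_aa"],
               c_ca_aa_high = ci["high", "c_ca_aa"],
               nri = est["nri"], nri_low = ci["low", "nri"],
               nri_high = ci["high", "nri"], row.names = NULL)
  })
  do.call(rbind, rows)
}
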