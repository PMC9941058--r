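#' Specification of a stratified Cox model
#'
#' @param time_scale `"attained-age"` (delayed entry at baseline age, exit
#'   at age of death/censoring) or `"time-on-study"`.
#' @param strata stratum factors; `"age_band"` (5-year bands of baseline
#'   age) and `"fasting8"` (fasting >= 8 h) are derived on the fly when
#'   absent from the data.
#' @param covariates adjustment covariates.
#' @param exposure exposure column, reported per 1 unit (`"aa"` = years of
#'   age acceleration, `"aa_standardized"` = SD units).
#' @param ties tie handling passed to [survival::coxph()].
#' @return list of class `cox_spec`.
#' @export
cox_spec <- function(time_scale = c("attained-age", "time-on-study"),
                     strata = c("age_band", "area", "group"),
                     covariates = c("sex", "fasting8", "education"),
                     exposure = "aa", ties = "efron") {
  structure(list(time_scale = match.arg(time_scale), strata = strata,
                 covariates = covariates, exposure = exposure, ties = ties),
            class = "cox_spec")
}

# Derived analysis columns used by model specs.
prepare_cox_columns <- function(cohort) {
  if (!"age_band" %in% names(cohort) && "ca" %in% names(cohort)) {
    cohort$age_band <- cut(cohort$ca, breaks = seq(25, 85, by = 5),
                           right = FALSE)
  }
  if (!"fasting8" %in% names(cohort) && "fasting_hours" %in% names(cohort)) {
    cohort$fasting8 <- cohort$fasting_hours >= 8
  }
  if (!"age60" %in% names(cohort) && "ca" %in% names(cohort)) {
    cohort$age60 <- factor(ifelse(cohort$ca < 60, "<60", ">=60"),
                           levels = c("<60", ">=60"))
  }
  cohort
}

cox_formula <- function(cohort, spec, extra_terms = character(0)) {
  resp <- if (spec$time_scale == "attained-age") {
    "survival::Surv(ca, ca + followup_years, died)"
  } else {
    "survival::Surv(followup_years, died)"
  }
  covs <- setdiff(spec$covariates, extra_terms)
  rhs <- c(spec$exposure, extra_terms, covs,
           if (length(spec$strata)) {
             sprintf("survival::strata(%s)",
                     paste(spec$strata, collapse = ", "))
           })
  as.formula(paste(resp, "~", paste(rhs, collapse = " + ")))
}

#' Fit a stratified proportional-hazards model for age acceleration
#'
#' Partial-likelihood fit with stratum-specific baseline hazards. On the
#' attained-age scale, subjects enter the risk set at their baseline
#' chronological age and exit at age of death or censoring (delayed entry),
#' so chronological age is the underlying time variable and 5-year age
#' bands, study areas and sampling groups stratify the baseline hazard.
#' Efron tie handling by default.
#'
#' @param cohort analysis cohort with follow-up, exposure and covariates.
#' @param spec a [cox_spec()].
#' @return list of class `cox_result`: `log_hr`, `se`, `hr`, `ci95`,
#'   `loglik`, `n`, `events`, `p`, and the fitted `coxph` object.
#' @export
fit_stratified_cox <- function(cohort, spec = cox_spec()) {
  cohort <- prepare_cox_columns(cohort)
  x <- cohort[[spec$exposure]]
  if (is.null(x)) stop_kdm("exposure column %s absent", spec$exposure)
  if (!all(is.finite(x))) stop_kdm("non-finite exposure values")
  if (sd(x) == 0) stop_kdm("exposure is constant: association not identifiable")
  fit <- survival::coxph(cox_formula(cohort, spec), data = cohort,
                         ties = spec$ties)
  b <- coef(fit)[spec$exposure]
  se <- sqrt(diag(fit$var))[match(spec$exposure, names(coef(fit)))]
  if (is.na(b) || !is.finite(se)) {
    stop_kdm("exposure effect not identifiable within strata")
  }
  structure(list(log_hr = unname(b), se = unname(se), hr = exp(unname(b)),
                 ci95 = exp(unname(b) + c(-1, 1) * 1.96 * unname(se)),
                 loglik = fit$loglik[length(fit$loglik)],
                 n = fit$n, events = fit$nevent,
                 p = 2 * pnorm(-abs(unname(b) / unname(se))),
                 fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("HR %.3f (95%% CI %.3f, %.3f) per unit exposure; n = %d, events = %d\n",
              x$hr, x$ci95[1], x$ci95[2], x$n, x$events))
  invisible(x)
}

#' Subgroup hazard ratios
#'
#' Independent fits of the same model specification within each level of a
#' stratifying factor. Levels without events are reported as missing rows
#' rather than errors.
#'
#' @param cohort analysis cohort.
#' @param spec a [cox_spec()]; the stratifier is removed from its
#'   covariates/strata within levels.
#' @param stratifier column name of the subgroup factor.
#' @return data.frame with one row per level: `level`, `n`, `events`,
#'   `log_hr`, `se`, `hr`, `ci_low`, `ci_high`.
#' @export
subgroup_hr <- function(cohort, spec, stratifier) {
  cohort <- prepare_cox_columns(cohort)
  lev <- levels(factor(cohort[[stratifier]]))
  sub_spec <- spec
  sub_spec$covariates <- setdiff(spec$covariates, stratifier)
  sub_spec$strata <- setdiff(spec$strata, stratifier)
  rows <- lapply(lev, function(l) {
    sub <- cohort[cohort[[stratifier]] == l, , drop = FALSE]
    if (nrow(sub) == 0 || sum(sub$died) == 0) {
      return(data.frame(level = l, n = nrow(sub), events = sum(sub$died),
                        log_hr = NA_real_, se = NA_real_, hr = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    }
    r <- fit_stratified_cox(sub, sub_spec)
    data.frame(level = l, n = r$n, events = r$events, log_hr = r$log_hr,
               se = r$se, hr = r$hr, ci_low = r$ci95[1], ci_high = r$ci95[2])
  })
  do.call(rbind, rows)
}

#' Likelihood-ratio test for effect modification
#'
#' Compares the model with exposure-by-stratifier product terms against the
#' nested model without them; both include the stratifier main effect. The
#' statistic is twice the log-likelihood difference, referred to a
#' chi-square with (levels - 1) degrees of freedom.
#'
#' @param cohort analysis cohort.
#' @param spec a [cox_spec()].
#' @param stratifier column name of the candidate effect modifier.
#' @return list with `lrt_stat`, `df`, `p_value`.
#' @export
interaction_test <- function(cohort, spec, stratifier) {
  cohort <- prepare_cox_columns(cohort)
  cohort$.mod <- factor(cohort[[stratifier]])
  if (nlevels(cohort$.mod) < 2) stop_kdm("stratifier must have >= 2 levels")
  spec2 <- spec
  spec2$covariates <- setdiff(spec$covariates, stratifier)
  spec2$strata <- setdiff(spec$strata, stratifier)
  f_red <- cox_formula(cohort, spec2, extra_terms = ".mod")
  f_full <- cox_formula(cohort, spec2,
                        extra_terms = c(".mod",
                                        paste0(spec2$exposure, ":.mod")))
  fit_red <- survival::coxph(f_red, data = cohort, ties = spec$ties)
  fit_full <- survival::coxph(f_full, data = cohort, ties = spec$ties)
  stat <- 2 * (fit_full$loglik[2] - fit_red$loglik[2])
  df <- nlevels(cohort$.mod) - 1
  list(lrt_stat = max(stat, 0), df = df,
       p_value = pchisq(max(stat, 0), df = df, lower.tail = FALSE))
}

#' Proportional-hazards diagnostic
#'
#' Scaled Schoenfeld residual trend test for the exposure; reported for
#' inspection, never acted on automatically.
#'
#' @param result a `cox_result`.
#' @return the [survival::cox.zph()] table row for the exposure.
#' @export
ph_check <- function(result) {
  z <- survival::cox.zph(result$fit)
  z$table
}

#' Per-group event summary
#'
#' Mortality rate per 1000 person-years and the median (IQR) years to event
#' among subjects with the event, by sampling group and overall.
#'
#' @param cohort analysis cohort with `group`, `followup_years`, `died`.
#' @return data.frame: `group`, `n`, `events`, `person_years`,
#'   `rate_per_1000py`, `median_time`, `iqr_time`.
#' @export
event_summary <- function(cohort) {
  if (!all(c("followup_years", "died") %in% names(cohort))) {
    stop_kdm("follow-up columns absent")
  }
  one <- function(sub, label) {
    py <- sum(sub$followup_years)
    if (py == 0) stop_kdm("zero person-years in group %s", label)
    tt <- sub$followup_years[sub$died]
    data.frame(group = label, n = nrow(sub), events = sum(sub$died),
               person_years = py,
               rate_per_1000py = 1000 * sum(sub$died) / py,
               median_time = if (length(tt)) median(tt) else NA_real_,
               iqr_time = if (length(tt)) diff(quantile(tt, c(0.25, 0.75),
                                                        names = FALSE))
                          else NA_real_)
  }
  groups <- levels(factor(cohort$group))
  do.call(rbind, c(list(one(cohort, "all")),
                   lapply(groups, function(g) {
                     one(cohort[cohort$group == g, , drop = FALSE], g)
                   })))
}
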