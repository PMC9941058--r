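#' Apply the exclusion cascade to a raw cohort
#'
#' Removes records in four sequential stages, in this fixed order:
#' sample-quality problems (lipemic / icteric / haemolysed / turbid flag),
#' values under the limit of detection (flag), missing values on any
#' candidate marker, and marker outliers. The outlier stage removes records
#' with any marker lying strictly outside `outlier_k` standard deviations of
#' the marker mean, where mean and SD are computed per marker on the records
#' surviving the first three stages (pooled across sexes). A marker with
#' zero variance in that pool is skipped with a warning record rather than
#' failing.
#'
#' @param cohort raw cohort data.frame with an `exclusion_flag` column and
#'   raw marker columns.
#' @param outlier_k outlier cut in SD units (default 4).
#' @param marker_cols marker columns to screen; defaults to the raw columns
#'   of [default_marker_panel()].
#' @return list with `cohort` (survivors) and `log`, a data.frame of
#'   per-stage removal counts satisfying
#'   `input = output + sum(removed)`.
#' @export
apply_exclusions <- function(cohort, outlier_k = 4,
                             marker_cols = raw_marker_columns(default_marker_panel())) {
  if (nrow(cohort) == 0) stop_kdm("empty cohort")
  missing_cols <- setdiff(marker_cols, names(cohort))
  if (length(missing_cols)) stop_kdm("marker columns absent: %s",
                                     paste(missing_cols, collapse = ", "))
  n_in <- nrow(cohort)
  flag <- as.character(cohort$exclusion_flag %||% rep("", n_in))

  keep <- flag != "sample_quality"
  n_quality <- sum(!keep)
  cohort <- cohort[keep, , drop = FALSE]
  flag <- flag[keep]

  keep <- flag != "under_lod"
  n_lod <- sum(!keep)
  cohort <- cohort[keep, , drop = FALSE]

  keep <- complete.cases(cohort[, marker_cols, drop = FALSE])
  n_missing <- sum(!keep)
  cohort <- cohort[keep, , drop = FALSE]

  out <- rep(FALSE, nrow(cohort))
  warnings <- character(0)
  for (mc in marker_cols) {
    x <- cohort[[mc]]
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      warnings <- c(warnings,
                    sprintf("marker %s constant in filter pool; outlier screen skipped", mc))
      next
    }
    out <- out | (abs(x - mean(x)) / s > outlier_k)
  }
  n_outlier <- sum(out)
  cohort <- cohort[!out, , drop = FALSE]

  log <- data.frame(
    stage = c("sample_quality", "under_lod", "missing_marker",
              "outlier_4sd"),
    removed = c(n_quality, n_lod, n_missing, n_outlier))
  attr(log, "input") <- n_in
  attr(log, "output") <- nrow(cohort)
  attr(log, "warnings") <- warnings
  stopifnot(n_in == nrow(cohort) + sum(log$removed))
  list(cohort = cohort, log = log)
}

#' Harmonize measurements and apply transformation rules
#'
#' Applies, once, the fixed measurement rules used before biological-age
#' construction: adds 15 mmHg to systolic and 10 mmHg to diastolic blood
#' pressure of subjects on antihypertensive medication; resolves the glucose
#' marker as fasting plasma glucose when available, otherwise random plasma
#' glucose; and natural-log-transforms the biochemical markers except plasma
#' albumin, leaving all physical measurements on their original scale. A
#' `harmonized` attribute guards against double application.
#'
#' @param cohort cohort data.frame (typically post-exclusion).
#' @param panel marker panel describing class and log rules.
#' @return the cohort with transformed marker columns, a `glucose` column,
#'   and `attr(, "harmonized") = TRUE`.
#' @export
harmonize_measurements <- function(cohort, panel = default_marker_panel()) {
  if (isTRUE(attr(cohort, "harmonized"))) {
    stop_kdm("cohort is already harmonized; refusing to adjust blood pressure twice")
  }
  if (!all(c("sbp", "dbp") %in% names(cohort))) {
    stop_kdm("blood pressure columns absent")
  }
  trt <- cohort$antihypertensive
  cohort$sbp[trt] <- cohort$sbp[trt] + 15
  cohort$dbp[trt] <- cohort$dbp[trt] + 10

  if (!"rpg" %in% names(cohort)) stop_kdm("glucose columns absent")
  cohort$glucose <- ifelse(!is.na(cohort$fpg %||% NA), cohort$fpg, cohort$rpg)

  for (j in seq_len(nrow(panel))) {
    sp <- panel[j, ]
    if (!sp$log_transform || !sp$name %in% names(cohort)) next
    x <- cohort[[sp$name]]
    if (any(x <= 0, na.rm = TRUE)) {
      stop_kdm("non-positive value in marker %s passed to log-transform", sp$name)
    }
    cohort[[sp$name]] <- log(x)
  }
  attr(cohort, "harmonized") <- TRUE
  cohort
}

freq_lt_daily <- function(f) f != "daily"
freq_lt_weekly <- function(f) f %in% c("never_rarely", "monthly")

#' Risky dietary score (0-5)
#'
#' One point per risky dietary habit: vegetables less than daily, fruits
#' less than daily, red meat daily or less than weekly, soybean fewer than
#' 4 days/week, fish less than weekly.
#'
#' @param cohort data.frame with the five diet frequency columns
#'   (`veg_freq`, `fruit_freq`, `meat_freq`, `soybean_freq`, `fish_freq`)
#'   on the levels never_rarely / monthly / 1_3_per_week / 4_6_per_week /
#'   daily.
#' @return integer vector of scores in 0..5.
#' @export
compute_dietary_score <- function(cohort) {
  need <- c("veg_freq", "fruit_freq", "meat_freq", "soybean_freq", "fish_freq")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop_kdm("missing diet frequency fields: %s",
                             paste(miss, collapse = ", "))
  if (any(vapply(cohort[need], function(x) any(is.na(x)), logical(1)))) {
    stop_kdm("missing values in diet frequency fields")
  }
  score <- freq_lt_daily(cohort$veg_freq) +
    freq_lt_daily(cohort$fruit_freq) +
    (cohort$meat_freq == "daily" | freq_lt_weekly(cohort$meat_freq)) +
    (cohort$soybean_freq %in% c("never_rarely", "monthly", "1_3_per_week")) +
    freq_lt_weekly(cohort$fish_freq)
  as.integer(score)
}

#' Age- and sex-specific physical-activity medians
#'
#' Medians of total physical activity (MET-h/day) within the age bands
#' <50, 50-59, >=60 crossed with sex, computed on the analysis cohort.
#'
#' @param cohort analysis cohort with `ca`, `sex`, `total_activity`.
#' @return data.frame with `age_band`, `sex`, `median_activity`.
#' @export
activity_medians <- function(cohort) {
  band <- activity_age_band(cohort$ca)
  agg <- aggregate(cohort$total_activity,
                   by = list(age_band = band, sex = cohort$sex), FUN = median)
  names(agg)[3] <- "median_activity"
  agg
}

activity_age_band <- function(ca) {
  cut(ca, breaks = c(-Inf, 50, 60, Inf), right = FALSE,
      labels = c("<50", "50-59", ">=60"))
}

#' Risky lifestyle score (0-4) and risky-group flag
#'
#' One point each for: current smoking (quitting for illness counts as
#' current); daily alcohol of at least 30 g (men) / 15 g (women) or past
#' drinking; a risky dietary score of 4-5; and total physical activity
#' strictly below the age- and sex-specific median (ties are non-risky).
#' Subjects scoring 3 or 4 form the risky group.
#'
#' @param cohort analysis cohort.
#' @param medians activity medians as from [activity_medians()]; defaults to
#'   medians computed on `cohort` itself.
#' @return data.frame with `dietary_score`, `lifestyle_score`, `risky`.
#' @export
compute_lifestyle_score <- function(cohort, medians = activity_medians(cohort)) {
  parts <- lifestyle_components(cohort, medians)
  score <- as.integer(parts$current_smoker + parts$excessive_alcohol +
                        (parts$dietary_score >= 4) + parts$low_activity)
  data.frame(dietary_score = parts$dietary_score, lifestyle_score = score,
             risky = score >= 3)
}

lifestyle_components <- function(cohort, medians = activity_medians(cohort)) {
  smoke <- cohort$smoking_status == "current" |
    (cohort$smoking_status == "former" & cohort$quit_for_illness)
  alc_cut <- ifelse(cohort$sex == "male", 30, 15)
  alcohol <- cohort$alcohol_g >= alc_cut | cohort$past_drinker
  diet <- compute_dietary_score(cohort)
  band <- activity_age_band(cohort$ca)
  key <- paste(band, cohort$sex)
  med <- setNames(medians$median_activity,
                  paste(medians$age_band, medians$sex))
  m <- med[key]
  if (any(is.na(m))) stop_kdm("missing activity median for an age/sex band")
  low_activity <- cohort$total_activity < m
  data.frame(current_smoker = smoke, excessive_alcohol = alcohol,
             dietary_score = diet, low_activity = low_activity)
}

#' Append lifestyle analysis columns to a cohort
#'
#' Adds the derived lifestyle variables used as covariates and subgroup
#' stratifiers: `current_smoker` (quit-for-illness counts as current),
#' `excessive_alcohol` (>= 30 g/day men, >= 15 g/day women, or past
#' drinker), `dietary_score` (0-5), `low_activity` (strictly below the age-
#' and sex-specific median), `lifestyle_score` (0-4) and `risky` (score 3-4).
#'
#' @param cohort analysis cohort.
#' @param medians activity medians, defaulting to those of `cohort`.
#' @return the cohort with the six columns appended.
#' @export
add_lifestyle_columns <- function(cohort, medians = activity_medians(cohort)) {
  parts <- lifestyle_components(cohort, medians)
  score <- compute_lifestyle_score(cohort, medians)
  cohort$current_smoker <- parts$current_smoker
  cohort$excessive_alcohol <- parts$excessive_alcohol
  cohort$low_activity <- parts$low_activity
  cohort$dietary_score <- score$dietary_score
  cohort$lifestyle_score <- score$lifestyle_score
  cohort$risky <- score$risky
  cohort
}
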