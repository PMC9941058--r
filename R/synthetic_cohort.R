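#' Simulation configuration for a synthetic CVD-continuum cohort
#'
#' Bundles the parameters of the synthetic-cohort generator. Defaults encode
#' the study conditions the analysis assumes: four sampling groups (control,
#' MCE = major coronary event, IS = ischemic stroke, ICH_SAH = hemorrhagic
#' stroke) with the analysis-set sizes 4197/876/3837/3467, group-specific
#' mean latent age acceleration of -0.3/0.1/0.0/0.3 years with SD 1.4 years,
#' enrolment ages uniform on 30-79, ten study areas, all-cause mortality
#' rates of roughly 13.1/102.7/15.5/84.6 deaths per 1000 person-years across
#' the groups, a log-hazard slope of 0.182 per year of age acceleration
#' (hazard ratio 1.20), and administrative censoring at 13 years.
#'
#' @param n_per_group named counts per group.
#' @param group_aa_mean named mean latent age acceleration (years) per group.
#' @param aa_sd SD of latent age acceleration (years), > 0 unless exactly 0
#'   for degenerate noiseless checks.
#' @param age_range enrolment age range (years).
#' @param sex_fraction_female proportion female.
#' @param n_areas number of study areas.
#' @param marker_panel data.frame of marker generating models, see
#'   [default_marker_panel()].
#' @param log_hr_per_year_aa log-hazard slope per year of latent AA.
#' @param baseline_hazard named per-year baseline death rate per group.
#' @param hazard_family `"exponential"` (default) or `"gompertz"`.
#' @param gompertz_shape per-year log-hazard increase when
#'   `hazard_family = "gompertz"`.
#' @param admin_censor_years administrative censoring time (years).
#' @param covariate_effects named log-hazard effects for generated
#'   covariates; supported names: `current_smoker`, `male`.
#' @param seed integer RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(control = 4197L, MCE = 876L,
                                       IS = 3837L, ICH_SAH = 3467L),
                       group_aa_mean = c(control = -0.3, MCE = 0.1,
                                         IS = 0.0, ICH_SAH = 0.3),
                       aa_sd = 1.4,
                       age_range = c(30, 79),
                       sex_fraction_female = 0.502,
                       n_areas = 10L,
                       marker_panel = default_marker_panel(),
                       log_hr_per_year_aa = 0.182,
                       # target marginal rates 13.1/102.7/15.5/84.6 per
                       # 1000 py, deflated by the mean hazard multiplier
                       # (~1.33) of the default covariate and AA effects
                       baseline_hazard = c(control = 0.0131, MCE = 0.1027,
                                           IS = 0.0155, ICH_SAH = 0.0846) / 1.33,
                       hazard_family = c("exponential", "gompertz"),
                       gompertz_shape = 0.09,
                       admin_censor_years = 13,
                       covariate_effects = c(current_smoker = 0.4, male = 0.25),
                       seed = 1L) {
  hazard_family <- match.arg(hazard_family)
  groups <- names(n_per_group)
  if (is.null(groups) || !setequal(groups, names(group_aa_mean)) ||
      !setequal(groups, names(baseline_hazard))) {
    stop_kdm("n_per_group, group_aa_mean and baseline_hazard must share group names")
  }
  if (any(n_per_group < 0)) stop_kdm("group counts must be >= 0")
  if (aa_sd < 0) stop_kdm("aa_sd must be >= 0")
  if (age_range[1] >= age_range[2]) stop_kdm("age_range must be increasing")
  if (any(baseline_hazard <= 0)) stop_kdm("baseline hazards must be > 0")
  if (nrow(marker_panel) == 0) stop_kdm("marker panel must not be empty")
  structure(list(n_per_group = n_per_group, group_aa_mean = group_aa_mean,
                 aa_sd = aa_sd, age_range = age_range,
                 sex_fraction_female = sex_fraction_female,
                 n_areas = as.integer(n_areas), marker_panel = marker_panel,
                 log_hr_per_year_aa = log_hr_per_year_aa,
                 baseline_hazard = baseline_hazard,
                 hazard_family = hazard_family,
                 gompertz_shape = gompertz_shape,
                 admin_censor_years = admin_censor_years,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "sim_config")
}

diet_levels <- c("never_rarely", "monthly", "1_3_per_week", "4_6_per_week",
                 "daily")
education_levels <- c("primary_or_below", "middle_or_high", "college_plus")

# Draw one diet-frequency column so that P(risky criterion) = p_risky, with
# the risky mass split over the qualifying categories.
draw_freq <- function(n, p_risky, risky_levels) {
  safe_levels <- setdiff(diet_levels, risky_levels)
  lev <- character(n)
  risky <- runif(n) < p_risky
  lev[risky] <- sample(risky_levels, sum(risky), replace = TRUE)
  lev[!risky] <- sample(safe_levels, sum(!risky), replace = TRUE)
  factor(lev, levels = diet_levels)
}

#' Generate a synthetic cohort with latent-aging ground truth
#'
#' Draws, per subject: a group label, chronological age `ca`, a latent age
#' acceleration `Delta ~ Normal(group mean, aa_sd^2)` defining true
#' biological age `BA = ca + Delta`; marker values linear in `BA` on their
#' analysis scale with marker-specific noise (exponentiated for
#' log-transformed markers, quadratic in age for the non-monotone marker);
#' medication, fasting-glucose, lifestyle and sociodemographic covariates;
#' and a death/censoring time from a proportional-hazards model multiplicative
#' in `Delta`. Antihypertensive users have 15/10 mmHg subtracted from their
#' generated systolic/diastolic pressures (treatment lowers the measured
#' values; harmonization adds them back). Identical config and seed give
#' identical output.
#'
#' @param config a [sim_config()].
#' @return a list with `cohort` (one data.frame row per subject; raw marker
#'   scales, glucose as `rpg`/`fpg`) and `truth` (per-subject `true_aa`,
#'   `true_ba`, `hazard_multiplier`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    groups <- names(config$n_per_group)
    n <- sum(config$n_per_group)
    if (n == 0) stop_kdm("empty cohort requested")
    group <- factor(rep(groups, times = config$n_per_group), levels = groups)
    ca <- runif(n, config$age_range[1], config$age_range[2])
    delta <- rnorm(n, mean = config$group_aa_mean[as.character(group)],
                   sd = config$aa_sd)
    ba <- ca + delta
    sex <- factor(ifelse(runif(n) < config$sex_fraction_female,
                         "female", "male"), levels = c("female", "male"))
    area <- sample.int(config$n_areas, n, replace = TRUE)
    urban <- area <= max(1L, round(config$n_areas * 0.3))

    # group-specific antihypertensive prevalence (higher along the continuum)
    p_aht <- c(control = 0.105, MCE = 0.192, IS = 0.201, ICH_SAH = 0.225)
    p_aht <- p_aht[match(as.character(group), names(p_aht))]
    p_aht[is.na(p_aht)] <- 0.15
    antihypertensive <- runif(n) < p_aht

    panel <- config$marker_panel
    markers <- matrix(NA_real_, n, nrow(panel),
                      dimnames = list(NULL, panel$name))
    male <- sex == "male"
    for (j in seq_len(nrow(panel))) {
      sp <- panel[j, ]
      q <- sp$intercept_q + ifelse(male, sp$q_sex_diff / 2, -sp$q_sex_diff / 2)
      lin <- if (sp$monotone) q + sp$slope_k * ba else q + sp$slope_k * (ba - 55)^2
      val <- lin + rnorm(n, 0, sp$noise_sd_s)
      markers[, j] <- if (sp$log_transform) exp(val) else val
    }
    cohort <- data.frame(id = sprintf("S%06d", seq_len(n)), sex = sex,
                         ca = ca, area = area, urban = urban, group = group,
                         antihypertensive = antihypertensive,
                         stringsAsFactors = FALSE)
    # glucose is carried as random plasma glucose; a fasting retest exists for
    # most subjects whose random value falls in the retest window
    g <- which(colnames(markers) == "glucose")
    if (length(g)) {
      cohort$rpg <- markers[, g]
      sp <- panel[panel$name == "glucose", ]
      qg <- sp$intercept_q + ifelse(male, sp$q_sex_diff / 2, -sp$q_sex_diff / 2)
      retest <- cohort$rpg >= 7.8 & cohort$rpg <= 11.0 & runif(n) < 0.9
      fpg <- rep(NA_real_, n)
      fpg[retest] <- exp(qg[retest] + sp$slope_k * ba[retest] +
                           rnorm(sum(retest), 0, sp$noise_sd_s))
      cohort$fpg <- fpg
      markers <- markers[, -g, drop = FALSE]
    }
    cohort <- cbind(cohort, as.data.frame(markers))
    if (all(c("sbp", "dbp") %in% names(cohort))) {
      cohort$sbp[antihypertensive] <- cohort$sbp[antihypertensive] - 15
      cohort$dbp[antihypertensive] <- cohort$dbp[antihypertensive] - 10
    }

    cohort$fasting_hours <- pmax(0, rexp(n, 1 / 4.7))
    cohort$education <- factor(sample(education_levels, n, replace = TRUE,
                                      prob = c(0.617, 0.320, 0.063)),
                               levels = education_levels)
    p_smoke <- ifelse(male, 0.696, 0.040)
    status <- ifelse(runif(n) < p_smoke, "current",
                     ifelse(runif(n) < 0.10, "former", "never"))
    cohort$smoking_status <- factor(status,
                                    levels = c("never", "former", "current"))
    cohort$quit_for_illness <- cohort$smoking_status == "former" &
      runif(n) < 0.3
    heavy <- runif(n) < ifelse(male, 0.237, 0.018)
    cohort$alcohol_g <- ifelse(heavy,
                               ifelse(male, 30, 15) + rexp(n, 1 / 15),
                               runif(n, 0, ifelse(male, 29, 14)))
    cohort$past_drinker <- !heavy & runif(n) < 0.03
    cohort$veg_freq <- draw_freq(n, 0.071, diet_levels[diet_levels != "daily"])
    cohort$fruit_freq <- draw_freq(n, 0.871, diet_levels[diet_levels != "daily"])
    cohort$meat_freq <- draw_freq(n, 0.497, c("never_rarely", "monthly", "daily"))
    cohort$soybean_freq <- draw_freq(n, 0.908,
                                     c("never_rarely", "monthly", "1_3_per_week"))
    cohort$fish_freq <- draw_freq(n, 0.670, c("never_rarely", "monthly"))
    cohort$total_activity <- exp(rnorm(n, log(18.8) - 0.5 * 0.45^2, 0.45))

    lp <- config$log_hr_per_year_aa * delta
    ce <- config$covariate_effects
    if (!is.null(ce["current_smoker"]) && !is.na(ce["current_smoker"])) {
      lp <- lp + ce[["current_smoker"]] * (cohort$smoking_status == "current")
    }
    if (!is.null(ce["male"]) && !is.na(ce["male"])) {
      lp <- lp + ce[["male"]] * male
    }
    baseline <- list(family = config$hazard_family,
                     rate = unname(config$baseline_hazard[as.character(group)]),
                     shape = config$gompertz_shape)
    surv <- simulate_survival(lp, baseline, config$admin_censor_years,
                              seed = NULL)
    cohort$followup_years <- surv$time
    cohort$died <- surv$event
    cohort$exclusion_flag <- ""

    truth <- data.frame(id = cohort$id, true_aa = delta, true_ba = ba,
                        hazard_multiplier = exp(lp), stringsAsFactors = FALSE)
    list(cohort = cohort, truth = truth)
  })
}

#' Simulate censored survival times under a proportional-hazards model
#'
#' Subject `i` has hazard `h_i(t) = h0(t) * exp(lp_i)` with `h0` either a
#' constant exponential rate or a Gompertz hazard
#' `rate * exp(shape * t)`. Times are drawn by inversion and censored
#' administratively at `censor` years.
#'
#' @param linear_predictor per-subject log hazard multiplier.
#' @param baseline list with `family` ("exponential"/"gompertz"), `rate`
#'   (scalar or per-subject), and `shape` (Gompertz only); a bare number is
#'   taken as an exponential rate.
#' @param censor administrative censoring time in years.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return data.frame with `time` (years) and `event` (TRUE = death).
#' @export
simulate_survival <- function(linear_predictor, baseline, censor,
                              seed = NULL) {
  if (is.numeric(baseline)) baseline <- list(family = "exponential",
                                             rate = baseline)
  if (any(!is.finite(linear_predictor))) {
    stop_kdm("non-finite linear predictor")
  }
  if (any(baseline$rate <= 0)) stop_kdm("baseline rate must be > 0")
  with_seed(seed, {
    n <- length(linear_predictor)
    rate <- rep_len(baseline$rate, n) * exp(linear_predictor)
    u <- runif(n)
    t_death <- if (identical(baseline$family, "gompertz")) {
      g <- baseline$shape
      log1p(g * (-log(u)) / rate) / g
    } else {
      -log(u) / rate
    }
    event <- t_death <= censor
    data.frame(time = pmin(t_death, censor), event = event)
  })
}

#' Build a cohort fixture with prescribed exclusion-category counts
#'
#' Constructs a raw cohort of `initial_n` records and plants exactly the
#' requested number of records in each exclusion category, mutually
#' exclusively: `sample_quality` and `under_lod` as sample-level flags,
#' `missing_marker` as a missing marker value, and `outlier_4sd` as a marker
#' value far outside the distribution of the remaining records. Clean
#' records carry bounded marker noise so that none of them can fail the
#' 4-SD outlier screen by chance; the fixture is the arithmetic test bed for
#' the exclusion cascade.
#'
#' @param initial_n total records.
#' @param category_counts named counts among `sample_quality`, `under_lod`,
#'   `missing_marker`, `outlier_4sd` (missing names = 0).
#' @param seed RNG seed.
#' @return a raw cohort data.frame as from [generate_cohort()].
#' @export
generate_exclusion_fixture <- function(initial_n, category_counts = c(),
                                       seed = 1L) {
  cats <- c("sample_quality", "under_lod", "missing_marker", "outlier_4sd")
  bad <- setdiff(names(category_counts), cats)
  if (length(bad)) stop_kdm("unknown exclusion categories: %s",
                            paste(bad, collapse = ", "))
  counts <- setNames(rep(0L, length(cats)), cats)
  counts[names(category_counts)] <- as.integer(category_counts)
  if (sum(counts) > initial_n) stop_kdm("category counts exceed initial_n")

  panel <- default_marker_panel()
  n_groups <- c(control = initial_n %/% 2L,
                MCE = initial_n %/% 8L,
                IS = initial_n %/% 4L)
  n_groups <- c(n_groups,
                ICH_SAH = initial_n - sum(n_groups))
  cfg <- sim_config(n_per_group = n_groups,
                    group_aa_mean = c(control = -0.3, MCE = 0.1, IS = 0,
                                      ICH_SAH = 0.3),
                    marker_panel = panel, seed = seed)
  cohort <- generate_cohort(cfg)$cohort

  # Rebuild marker columns with bounded uniform noise and no latent spread:
  # the marginal of each clean marker is then a sum of bounded terms whose
  # extreme deviation stays well inside 4 SD, so only planted records can
  # fail the outlier screen and the category counts are exact.
  with_seed(seed + 1L, {
    n <- nrow(cohort)
    male <- cohort$sex == "male"
    for (j in seq_len(nrow(panel))) {
      sp <- panel[j, ]
      q <- sp$intercept_q + ifelse(male, sp$q_sex_diff / 2, -sp$q_sex_diff / 2)
      lin <- if (sp$monotone) q + sp$slope_k * cohort$ca else
        q + sp$slope_k * (cohort$ca - 55)^2
      u <- runif(n, -2.5 * sp$noise_sd_s, 2.5 * sp$noise_sd_s)
      col <- if (sp$name == "glucose") "rpg" else sp$name
      cohort[[col]] <- if (sp$log_transform) exp(lin + u) else lin + u
    }
    cohort$fpg <- NA_real_
    trt <- cohort$antihypertensive
    cohort$sbp[trt] <- cohort$sbp[trt] - 15
    cohort$dbp[trt] <- cohort$dbp[trt] - 10
  })

  idx <- seq_len(sum(counts))
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- idx[seq_len(k)]
    idx <<- idx[-seq_len(k)]
    out
  }
  cohort$exclusion_flag <- ""
  cohort$exclusion_flag[take(counts["sample_quality"])] <- "sample_quality"
  cohort$exclusion_flag[take(counts["under_lod"])] <- "under_lod"
  cohort$albumin[take(counts["missing_marker"])] <- NA_real_
  out_rows <- take(counts["outlier_4sd"])
  if (length(out_rows)) {
    clean <- setdiff(seq_len(initial_n), out_rows)
    cohort$creatinine[out_rows] <-
      mean(cohort$creatinine[clean]) + 1000 * sd(cohort$creatinine[clean])
  }
  cohort
}
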