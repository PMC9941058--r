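#' Pipeline configuration
#'
#' One object holding everything needed for an end-to-end, seeded run:
#' generator settings, preprocessing and construction options, association
#' and discrimination settings, and sensitivity toggles. A single master
#' seed is fanned out into stable per-stage child seeds so stages are
#' independently re-runnable.
#'
#' @param seed master seed.
#' @param sim a [sim_config()]; its own seed is overridden by the derived
#'   simulate-stage seed.
#' @param exclusion_counts planted exclusion-category counts for the raw
#'   cohort (`NULL` = generate without planted exclusions).
#' @param outlier_sd outlier cut for the exclusion cascade.
#' @param threshold marker screening threshold.
#' @param reps bootstrap replicates for discrimination CIs.
#' @param nri_threshold risk threshold of the NRI.
#' @param horizon prediction horizon, years.
#' @param sensitivity_control_derived run the control-derived construction.
#' @param sensitivity_no_antihypertensive rerun excluding antihypertensive
#'   users.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(),
                            exclusion_counts = NULL, outlier_sd = 4,
                            threshold = 0.10, reps = 200,
                            nri_threshold = 0.50, horizon = 10,
                            sensitivity_control_derived = TRUE,
                            sensitivity_no_antihypertensive = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> exclusion cascade -> harmonization and lifestyle scoring ->
#' sex-stratified biological-age construction -> age-acceleration mortality
#' association (overall, per group, subgroups, interactions) ->
#' discrimination analysis -> sensitivity analyses. Deterministic under a
#' fixed config and seed.
#'
#' @param config a [pipeline_config()]; alternatively pass a prebuilt raw
#'   cohort via `cohort`.
#' @param cohort optional raw cohort table overriding simulation.
#' @return a named list (report bundle) with all stage outputs and a
#'   manifest of seeds and settings.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  sim$seed <- derive_seed(config$seed, "simulate")
  if (is.null(cohort)) {
    gen <- if (!is.null(config$exclusion_counts)) {
      list(cohort = generate_exclusion_fixture(sum(sim$n_per_group),
                                               config$exclusion_counts,
                                               seed = sim$seed),
           truth = NULL)
    } else generate_cohort(sim)
    cohort <- gen$cohort
    truth <- gen$truth
  } else truth <- NULL

  excl <- apply_exclusions(cohort, outlier_k = config$outlier_sd)
  analysis <- harmonize_measurements(excl$cohort, panel = sim$marker_panel)
  analysis <- add_lifestyle_columns(analysis)

  fit <- fit_ba(analysis, panel = sim$marker_panel,
                threshold = config$threshold)
  analysis$ba <- fit$ba$ba
  analysis$aa <- fit$ba$aa
  analysis$aa_standardized <- fit$ba$aa_standardized

  spec_year <- cox_spec(exposure = "aa")
  spec_sd <- cox_spec(exposure = "aa_standardized")
  assoc <- list(
    overall = fit_stratified_cox(analysis, spec_year),
    overall_per_sd = fit_stratified_cox(analysis, spec_sd),
    by_group = subgroup_hr(analysis, spec_year, "group"),
    subgroups = lapply(c(age = "age60", sex = "sex", urban = "urban",
                         smoking = "current_smoker",
                         alcohol = "excessive_alcohol",
                         lifestyle = "risky"),
                       function(s) subgroup_hr(analysis, spec_year, s)),
    interactions = lapply(c(age = "age60", sex = "sex", urban = "urban",
                            smoking = "current_smoker",
                            alcohol = "excessive_alcohol",
                            lifestyle = "risky"),
                          function(s) interaction_test(analysis, spec_year, s)))
  assoc$ph_check <- ph_check(assoc$overall)

  events <- event_summary(analysis)
  ba_tab <- ba_summary_table(analysis)
  disc <- discrimination_table(analysis, reps = config$reps,
                               seed = derive_seed(config$seed, "bootstrap"),
                               threshold = config$nri_threshold,
                               horizon = config$horizon)

  sens <- list()
  if (config$sensitivity_control_derived) {
    ctrl <- analysis$group == "control"
    fit_ctrl <- fit_ba(analysis, panel = sim$marker_panel,
                       threshold = config$threshold,
                       aa_pool = ctrl, fit_pool = ctrl)
    sens_cohort <- analysis
    sens_cohort$aa <- fit_ctrl$ba$aa
    sens_cohort$aa_standardized <- fit_ctrl$ba$aa /
      sd(fit_ctrl$ba$aa)
    sens$control_derived <- list(
      fit = fit_ctrl,
      overall_per_sd = fit_stratified_cox(sens_cohort, spec_sd),
      by_group = subgroup_hr(sens_cohort, spec_sd, "group"))
  }
  if (config$sensitivity_no_antihypertensive) {
    sub <- analysis[!analysis$antihypertensive, , drop = FALSE]
    fit_sub <- fit_ba(sub, panel = sim$marker_panel,
                      threshold = config$threshold)
    sub$aa <- fit_sub$ba$aa
    sens$no_antihypertensive <- list(
      overall = fit_stratified_cox(sub, spec_year),
      by_group = subgroup_hr(sub, spec_year, "group"))
  }

  list(config = config, exclusion_log = excl$log, cohort = analysis,
       truth = truth, fit = fit, ba_table = ba_tab, events = events,
       association = assoc, discrimination = disc, sensitivity = sens,
       manifest = list(master_seed = config$seed,
                       stage_seeds = list(
                         simulate = derive_seed(config$seed, "simulate"),
                         bootstrap = derive_seed(config$seed, "bootstrap")),
                       n_input = attr(excl$log, "input"),
                       n_analysis = attr(excl$log, "output"),
                       package_version = as.character(
                         utils::packageVersion("kdmage"))))
}

#' Per-group summary of age and biological-age measurements
#'
#' Mean (SD) of chronological age, biological age and age acceleration, and
#' the fit diagnostics (Pearson r of BA with CA; RMSE of regressing CA on
#' BA), for all participants and per sampling group.
#'
#' @param cohort analysis cohort with `ca`, `ba`, `aa`, `group`.
#' @return data.frame, one row per population.
#' @export
ba_summary_table <- function(cohort) {
  one <- function(sub, label) {
    d <- ba_diagnostics(sub$ba, sub$ca)
    data.frame(population = label, n = nrow(sub),
               ca_mean = mean(sub$ca), ca_sd = sd(sub$ca),
               ba_mean = mean(sub$ba), ba_sd = sd(sub$ba),
               aa_mean = mean(sub$aa), aa_sd = sd(sub$aa),
               rmse = d$rmse, pearson_r = d$pearson_r)
  }
  groups <- levels(factor(cohort$group))
  do.call(rbind, c(list(one(cohort, "all")),
                   lapply(groups, function(g) {
                     one(cohort[cohort$group == g, , drop = FALSE], g)
                   })))
}

#' Write the report bundle as delimited text and JSON
#'
#' Human-readable tab-delimited tables (exclusion log, biological-age
#' summary, event summary, association tables, discrimination table) plus a
#' machine-readable JSON copy of all numeric results and the run manifest,
#' and the serialized per-sex construction.
#'
#' @param results a [run_pipeline()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  log <- results$exclusion_log
  log_out <- rbind(log, data.frame(stage = c("input", "analysis_set"),
                                   removed = c(attr(log, "input"),
                                               attr(log, "output"))))
  w(log_out, "exclusion_log.tsv")
  w(results$ba_table, "ba_summary.tsv")
  w(results$events, "event_summary.tsv")
  ov <- results$association$overall
  ov_sd <- results$association$overall_per_sd
  w(data.frame(model = c("per_year", "per_sd"),
               log_hr = c(ov$log_hr, ov_sd$log_hr),
               se = c(ov$se, ov_sd$se),
               hr = c(ov$hr, ov_sd$hr),
               ci_low = c(ov$ci95[1], ov_sd$ci95[1]),
               ci_high = c(ov$ci95[2], ov_sd$ci95[2]),
               n = c(ov$n, ov_sd$n), events = c(ov$events, ov_sd$events)),
    "association_overall.tsv")
  w(results$association$by_group, "association_groups.tsv")
  subg <- results$association$subgroups
  w(do.call(rbind, Map(function(tab, nm) cbind(factor = nm, tab),
                       subg, names(subg))), "association_subgroups.tsv")
  ints <- results$association$interactions
  w(data.frame(factor = names(ints),
               lrt_stat = vapply(ints, `[[`, 0, "lrt_stat"),
               df = vapply(ints, `[[`, 0, "df"),
               p_value = vapply(ints, `[[`, 0, "p_value")),
    "interactions.tsv")
  w(results$discrimination, "discrimination.tsv")
  if (!is.null(results$sensitivity$control_derived)) {
    w(results$sensitivity$control_derived$by_group,
      "sensitivity_control_derived_groups.tsv")
    write_kdm_fit(results$sensitivity$control_derived$fit,
                  file.path(dir, "kdm_fit_control_derived.json"))
  }
  if (!is.null(results$sensitivity$no_antihypertensive)) {
    w(results$sensitivity$no_antihypertensive$by_group,
      "sensitivity_no_antihypertensive_groups.tsv")
  }
  write_kdm_fit(results$fit, file.path(dir, "kdm_fit_primary.json"))
  machine <- list(
    manifest = results$manifest,
    exclusion_log = log_out,
    ba_table = results$ba_table,
    events = results$events,
    association_overall = list(log_hr = ov$log_hr, se = ov$se, hr = ov$hr,
                               ci95 = ov$ci95, n = ov$n, events = ov$events),
    association_groups = results$association$by_group,
    discrimination = results$discrimination)
  jsonlite::write_json(machine, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write / read a cohort as delimited text
#'
#' Tab-delimited, one header row, one row per participant. `read_cohort`
#' restores the factor and logical columns the generator emits.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  if ("sex" %in% names(cohort)) {
    cohort$sex <- factor(cohort$sex, levels = c("female", "male"))
  }
  if ("group" %in% names(cohort)) {
    cohort$group <- factor(cohort$group,
                           levels = intersect(c("control", "MCE", "IS",
                                                "ICH_SAH"),
                                              unique(cohort$group)))
  }
  if ("education" %in% names(cohort)) {
    cohort$education <- factor(cohort$education, levels = education_levels)
  }
  for (f in c("veg_freq", "fruit_freq", "meat_freq", "soybean_freq",
              "fish_freq")) {
    if (f %in% names(cohort)) cohort[[f]] <- factor(cohort[[f]],
                                                    levels = diet_levels)
  }
  if ("smoking_status" %in% names(cohort)) {
    cohort$smoking_status <- factor(cohort$smoking_status,
                                    levels = c("never", "former", "current"))
  }
  if ("exclusion_flag" %in% names(cohort)) {
    cohort$exclusion_flag[is.na(cohort$exclusion_flag)] <- ""
  }
  cohort
}
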