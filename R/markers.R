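#' Candidate marker panel for biological-age construction
#'
#' Returns the default panel of 25 candidate markers (8 physical, 17
#' biochemical) used by the synthetic-cohort generator and the
#' biological-age pipeline. The panel is a *synthetic stand-in*: marker names
#' are those of a routine clinical chemistry panel plus standard physical
#' measurements, but intercepts, age slopes and noise standard deviations are
#' invented. They are calibrated once so that a cohort generated with a
#' latent age-acceleration SD of 1.4 years reproduces the cohort-level
#' diagnostics expected of the method (biological age correlating ~0.99 with
#' chronological age, RMSE ~1.4 years, observed age-acceleration SD ~1.4
#' years). Individual marker-age correlations are therefore stronger than
#' those of typical single clinical markers.
#'
#' Each row describes a generating model on the marker's analysis scale
#' (natural-log scale when `log_transform` is `TRUE`):
#' `x = intercept_q + slope_k * BA + Normal(0, noise_sd_s)`, where `BA` is
#' the subject's latent biological age. For the one non-monotone marker
#' (`monotone = FALSE`, body weight) `slope_k` is instead the quadratic
#' coefficient of an inverted-U response centred at age 55, included so the
#' monotonicity screen has something to reject. `q_sex_diff` is the
#' male-minus-female intercept difference. Random plasma glucose is emitted
#' as the `rpg`/`fpg` pair rather than as a `glucose` column; measurement
#' harmonization resolves the pair into the `glucose` marker.
#'
#' @param informative_noise_scale multiplier applied to every marker's
#'   `noise_sd_s`; `0` gives exactly linear noiseless markers (used by
#'   identity checks), `1` the calibrated default.
#' @return a data.frame with one row per candidate marker and columns
#'   `name`, `klass`, `intercept_q`, `slope_k`, `noise_sd_s`,
#'   `log_transform`, `monotone`, `q_sex_diff`.
#' @export
default_marker_panel <- function(informative_noise_scale = 1) {
  p <- function(name, klass, q, k, s, lg, mono, sexd) {
    data.frame(name = name, klass = klass, intercept_q = q, slope_k = k,
               noise_sd_s = s, log_transform = lg, monotone = mono,
               q_sex_diff = sexd, stringsAsFactors = FALSE)
  }
  panel <- rbind(
    # physical, age-informative
    p("sbp",        "physical", 95.0,  0.55,  0.50, FALSE, TRUE,  2.0),
    p("dbp",        "physical", 60.0,  0.30,  0.30, FALSE, TRUE,  1.5),
    p("fev1",       "physical", 4.40, -0.032, 0.030, FALSE, TRUE,  0.80),
    p("waist",      "physical", 60.0,  0.35,  0.35, FALSE, TRUE,  4.0),
    p("heart_rate", "physical", 62.0,  0.18,  0.20, FALSE, TRUE, -1.0),
    # physical, weakly age-related (screened out at |r| <= 0.10)
    p("height",     "physical", 162.0, -0.010, 6.0, FALSE, TRUE, 11.0),
    p("hip",        "physical", 91.0,  0.010, 5.0, FALSE, TRUE,  0.0),
    # physical, non-monotone (inverted-U in age; slope_k = quadratic coef)
    p("weight",     "physical", 68.0, -0.012, 3.0, FALSE, FALSE, 6.0),
    # biochemical, age-informative (log scale)
    p("creatinine",    "biochemical", log(60),   0.0045, 0.0040, TRUE, TRUE, 0.18),
    p("cystatin_c",    "biochemical", log(0.75), 0.0060, 0.0050, TRUE, TRUE, 0.05),
    p("total_chol",    "biochemical", log(4.0),  0.0035, 0.0035, TRUE, TRUE, -0.02),
    p("ldl_c",         "biochemical", log(1.9),  0.0050, 0.0050, TRUE, TRUE, 0.00),
    p("triglycerides", "biochemical", log(1.0),  0.0060, 0.0070, TRUE, TRUE, 0.10),
    p("apob",          "biochemical", log(0.75), 0.0040, 0.0045, TRUE, TRUE, 0.02),
    p("glucose",       "biochemical", log(4.8),  0.0040, 0.0040, TRUE, TRUE, 0.00),
    p("crp",           "biochemical", log(0.80), 0.0120, 0.0120, TRUE, TRUE, -0.05),
    p("ggt",           "biochemical", log(20),   0.0080, 0.0090, TRUE, TRUE, 0.35),
    p("urea",          "biochemical", log(4.5),  0.0050, 0.0060, TRUE, TRUE, 0.05),
    p("uric_acid",     "biochemical", log(250),  0.0035, 0.0040, TRUE, TRUE, 0.15),
    # biochemical, weakly age-related
    p("albumin", "biochemical", 47.0, -0.012, 2.5, FALSE, TRUE, 0.5),
    p("alt",     "biochemical", log(22),  0.0010, 0.30, TRUE, TRUE, 0.25),
    p("ast",     "biochemical", log(24),  0.0008, 0.25, TRUE, TRUE, 0.10),
    p("hdl_c",   "biochemical", log(1.3), -0.0008, 0.15, TRUE, TRUE, -0.10),
    p("apoa1",   "biochemical", log(1.2), 0.0005, 0.12, TRUE, TRUE, -0.04),
    p("phosphate", "biochemical", log(1.15), 0.0006, 0.10, TRUE, TRUE, -0.03)
  )
  stopifnot(!anyDuplicated(panel$name), all(panel$noise_sd_s >= 0))
  panel$noise_sd_s <- panel$noise_sd_s * informative_noise_scale
  panel
}

# Approximate population |r(marker, CA)| implied by a MarkerSpec row under the
# default age distribution (uniform 30-79, aa_sd 1.4): used only to classify
# panel rows, not by the estimator.
marker_age_r <- function(panel, age_var = (79 - 30)^2 / 12, aa_var = 1.4^2) {
  sig <- abs(panel$slope_k) * sqrt(age_var + aa_var)
  ifelse(panel$monotone, sig / sqrt(sig^2 + panel$noise_sd_s^2), 0)
}

# Marker columns as stored in a raw cohort table: glucose lives in rpg/fpg.
raw_marker_columns <- function(panel) {
  ifelse(panel$name == "glucose", "rpg", panel$name)
}
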