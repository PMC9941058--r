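#' Screen candidate markers against chronological age
#'
#' A marker enters biological-age construction when the absolute Pearson
#' correlation with chronological age exceeds `threshold` and its relation
#' to age is monotone. Monotonicity is judged by a half-split slope test:
#' the cohort is split at the median age, a least-squares slope is fitted in
#' each half, and the marker is flagged non-monotone when the two slopes
#' differ in sign and each is significant at the two-sided 0.05 level.
#' Zero-variance markers are excluded with a warning rather than an error.
#'
#' @param cohort harmonized, per-sex cohort.
#' @param markers candidate marker column names.
#' @param threshold correlation threshold (default 0.10, absolute).
#' @return data.frame with `name`, `r`, `monotone`, `retained`.
#' @export
screen_markers <- function(cohort, markers, threshold = 0.10) {
  if (length(markers) < 2) stop_kdm("need at least two candidate markers")
  ca <- cohort$ca
  split_lo <- ca <= median(ca)
  res <- lapply(markers, function(m) {
    x <- cohort[[m]]
    if (sd(x) == 0) {
      warning(sprintf("marker %s has zero variance; excluded", m))
      return(data.frame(name = m, r = NA_real_, monotone = NA,
                        retained = FALSE))
    }
    r <- cor(x, ca)
    mono <- TRUE
    # suppressed: summary.lm warns about essentially perfect fits, which are
    # legitimate here (noiseless degenerate inputs)
    s1 <- suppressWarnings(summary(lm(x ~ ca, subset = split_lo)))$coefficients
    s2 <- suppressWarnings(summary(lm(x ~ ca, subset = !split_lo)))$coefficients
    if (nrow(s1) == 2 && nrow(s2) == 2) {
      b1 <- s1["ca", ]
      b2 <- s2["ca", ]
      if (sign(b1["Estimate"]) != sign(b2["Estimate"]) &&
          !is.na(b1["Pr(>|t|)"]) && !is.na(b2["Pr(>|t|)"]) &&
          b1["Pr(>|t|)"] < 0.05 && b2["Pr(>|t|)"] < 0.05) {
        mono <- FALSE
      }
    }
    data.frame(name = m, r = r, monotone = mono,
               retained = abs(r) > threshold && mono)
  })
  do.call(rbind, res)
}

#' Correlation-matrix principal components of retained markers
#'
#' Standardizes each retained marker to zero mean and unit SD, then
#' decomposes the correlation matrix. Components with eigenvalues that are
#' numerically zero relative to the largest (rank deficiency, e.g. exactly
#' collinear markers) are dropped.
#'
#' @param cohort harmonized, per-sex cohort.
#' @param markers retained marker names.
#' @return list with `center`, `scale`, `loadings` (markers x components,
#'   orthonormal), `eigenvalues` (non-increasing), `scores` (subjects x
#'   components).
#' @export
fit_pca <- function(cohort, markers) {
  X <- as.matrix(cohort[, markers, drop = FALSE])
  if (nrow(X) <= length(markers)) stop_kdm("need n > number of markers")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) stop_kdm("zero-variance marker reached PCA")
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  eg <- eigen(cor(X), symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-8
  loadings <- eg$vectors[, keep, drop = FALSE]
  rownames(loadings) <- markers
  list(center = ctr, scale = scl, loadings = loadings,
       eigenvalues = eg$values[keep], scores = Z %*% loadings)
}

#' Fit the Klemera-Doubal estimator on principal-component scores
#'
#' For each component `j`, ordinary least squares of the score on
#' chronological age yields an intercept `q_j`, slope `k_j`, residual SD
#' `s_j` and correlation `r_j`. The uncorrected biological-age estimate is
#' the inverse-variance-weighted combination
#' `BA_E = sum_j (x_j - q_j) k_j / s_j^2 / sum_j k_j^2 / s_j^2`.
#' The characteristic correlation is the root mean square of the `r_j`
#' (so that equal component correlations `r` give exactly `|r|`).
#'
#' The variance of true biological age around chronological age, `s_BA^2`,
#' is the observed variance of `BA_E - CA` minus the sampling variance of
#' the estimator itself. The default (`s_ba2_method = "direct"`) computes
#' that sampling variance exactly from the fitted component parameters,
#' `1 / sum_j k_j^2 / s_j^2`; this stays well defined when principal
#' components concentrate the age signal in a few components and leave the
#' rest nearly uncorrelated with age. The textbook approximation
#' `[(1 - r_char^2) / r_char^2] * (CA_max - CA_min)^2 / (12 m)` is
#' available as `s_ba2_method = "rchar"`; it assumes all `m` components are
#' comparably age-informative and degenerates after PCA. Either way
#' `s_BA^2` is floored at 0.01 yr^2 so the corrected estimator remains
#' defined when the correction overshoots (`s_ba2_floored` records this).
#' Residual SDs are floored at 1e-6 so exactly noiseless components remain
#' usable.
#'
#' When fitted on principal components of strongly age-correlated markers,
#' the residual of a component on chronological age conflates the latent
#' spread of biological age around chronological age with the component's
#' own measurement noise. `s_ba2` can therefore be supplied externally
#' (estimated at the marker level, where the independent noises of the m
#' markers identify it; see [estimate_s_ba2()]), and `deconflate = TRUE`
#' subtracts `k_j^2 * s_BA^2` from each squared residual SD so the
#' component weights reflect measurement noise only (bounded below at 5% of
#' the raw residual SD for numerical stability).
#'
#' @param scores subjects x components score matrix.
#' @param ca chronological ages (years).
#' @param ca_range optional (min, max) used in the `"rchar"` correction;
#'   defaults to the sample range.
#' @param s_ba2_method `"direct"` (default) or `"rchar"`, see Details.
#' @param s_ba2 optional externally estimated `s_BA^2` (years^2).
#' @param deconflate subtract `k_j^2 * s_BA^2` from component residual
#'   variances before weighting (requires `s_ba2`).
#' @return an object of class `kdm_model`.
#' @export
fit_kdm <- function(scores, ca, ca_range = range(ca),
                    s_ba2_method = c("direct", "rchar"), s_ba2 = NULL,
                    deconflate = FALSE) {
  s_ba2_method <- match.arg(s_ba2_method)
  scores <- as.matrix(scores)
  m <- ncol(scores)
  if (m < 1) stop_kdm("need at least one component")
  if (sd(ca) == 0) stop_kdm("chronological age is constant")
  pc <- t(vapply(seq_len(m), function(j) {
    fit <- lm(scores[, j] ~ ca)
    res <- fit$residuals
    c(q = unname(coef(fit)[1]), k = unname(coef(fit)[2]),
      s = max(sqrt(sum(res^2) / max(1, length(res) - 2)), 1e-6),
      r = cor(scores[, j], ca))
  }, numeric(4)))
  pc <- as.data.frame(pc)
  if (all(abs(pc$k) < 1e-12)) {
    stop_kdm("degenerate fit: all component slopes are zero")
  }
  r_char <- sqrt(mean(pc$r^2))
  if (deconflate) {
    if (is.null(s_ba2)) stop_kdm("deconflation requires an external s_ba2")
    pc$s <- sqrt(pmax(pc$s^2 - pc$k^2 * s_ba2, (0.05 * pc$s)^2))
  }
  ba_e <- kdm_ba_e(scores, pc)
  floored <- FALSE
  if (is.null(s_ba2)) {
    correction <- if (s_ba2_method == "direct") {
      1 / sum(pc$k^2 / pc$s^2)
    } else {
      ((1 - r_char^2) / r_char^2) * diff(ca_range)^2 / (12 * m)
    }
    s_ba2 <- var(ba_e - ca) - correction
    floored <- s_ba2 < 0.01
    s_ba2 <- max(s_ba2, 0.01)
  }
  structure(list(pc_params = pc, r_char = r_char,
                 s_ba2 = s_ba2, s_ba2_floored = floored,
                 ca_range = ca_range, m = m),
            class = "kdm_model")
}

#' Marker-level estimate of the variance of biological age around age
#'
#' Fits each retained marker on chronological age and combines them with
#' the uncorrected Klemera-Doubal weights into a marker-level biological-age
#' estimate `BA_E`. The observed `Var(BA_E - CA)` is the latent variance of
#' true biological age around chronological age (`s_BA^2`) plus the
#' estimator's own sampling noise; but each marker's residual variance on
#' age is itself `noise_j^2 + k_j^2 * s_BA^2`, because the residual absorbs
#' the latent spread. The two are separated self-consistently: with
#' weights `w_j = k_j / s_j^2` fixed, the noise variance of `BA_E` given a
#' latent variance `v` is
#' `N(v) = sum w_j^2 (s_j^2 - k_j^2 v) / (sum w_j k_j)^2`,
#' and `s_BA^2` solves the fixed point `v = Var(BA_E - CA) - N(v)`, found
#' by root bracketing on `[0, Var(BA_E - CA)]`. This stays exact under the
#' linear-marker model for arbitrarily heterogeneous panels (weak markers
#' get small weights and correspondingly small influence), unlike
#' characteristic-correlation approximations that assume comparably
#' informative markers. The result is floored at 0.01 yr^2; the
#' root-mean-square marker-age correlation is reported as a diagnostic.
#'
#' @param cohort harmonized per-sex cohort.
#' @param markers retained marker names.
#' @param ca_range (min, max) age range, reported for audit.
#' @return list with `s_ba2`, `r_char`, `marker_params`, `floored`.
#' @export
estimate_s_ba2 <- function(cohort, markers, ca_range = range(cohort$ca)) {
  ca <- cohort$ca
  mm <- t(vapply(markers, function(nm) {
    fit <- lm(cohort[[nm]] ~ ca)
    res <- fit$residuals
    c(q = unname(coef(fit)[1]), k = unname(coef(fit)[2]),
      s = max(sqrt(sum(res^2) / max(1, length(res) - 2)), 1e-6),
      r = cor(cohort[[nm]], ca))
  }, numeric(4)))
  mm <- as.data.frame(mm)
  mm$name <- markers
  r_char <- sqrt(mean(mm$r^2))
  ba_e <- kdm_ba_e(as.matrix(cohort[, markers, drop = FALSE]), mm)
  D <- var(ba_e - ca)
  w <- mm$k / mm$s^2
  denom <- sum(w * mm$k)^2
  noise_var <- function(v) sum(w^2 * pmax(mm$s^2 - mm$k^2 * v, 0)) / denom
  h <- function(v) v - D + noise_var(v)
  s_ba2 <- if (D <= 0 || h(0) >= 0) {
    0                                  # no detectable latent spread
  } else {
    stats::uniroot(h, c(0, D), tol = 1e-10)$root
  }
  list(s_ba2 = max(s_ba2, 0.01), r_char = r_char, marker_params = mm,
       floored = s_ba2 < 0.01, ca_range = ca_range)
}

# Uncorrected estimator: weighted average of per-component age estimates.
kdm_ba_e <- function(scores, pc) {
  w <- pc$k / pc$s^2
  denom <- sum(pc$k^2 / pc$s^2)
  as.vector(sweep(scores, 2, pc$q) %*% w) / denom
}

#' Corrected Klemera-Doubal biological age
#'
#' Evaluates the corrected estimator, which treats chronological age as one
#' more composite marker weighted by `1 / s_BA^2`:
#' `BA_EC = [sum_j (x_j - q_j) k_j / s_j^2 + CA / s_BA^2] /
#' [sum_j k_j^2 / s_j^2 + 1 / s_BA^2]`.
#' As `s_BA^2` grows the estimate tends to the uncorrected `BA_E`; as it
#' shrinks the estimate tends to chronological age.
#'
#' @param model a fitted [fit_kdm()] model.
#' @param scores score matrix with columns matching the model components.
#' @param ca chronological ages.
#' @return numeric vector of biological ages (years).
#' @export
estimate_ba <- function(model, scores, ca) {
  scores <- as.matrix(scores)
  if (ncol(scores) != model$m) {
    stop_kdm("score columns (%d) do not match model components (%d)",
             ncol(scores), model$m)
  }
  pc <- model$pc_params
  num <- as.vector(sweep(scores, 2, pc$q) %*% (pc$k / pc$s^2)) +
    ca / model$s_ba2
  den <- sum(pc$k^2 / pc$s^2) + 1 / model$s_ba2
  num / den
}

#' Age acceleration as the residual of biological age on chronological age
#'
#' Fits ordinary least squares of biological age on chronological age within
#' a fitting pool (by default all subjects) and returns, for every subject,
#' the deviation from the fitted line. Standardized age acceleration divides
#' by the residual SD within the pool.
#'
#' @param ba biological ages.
#' @param ca chronological ages.
#' @param fit_pool logical mask of subjects defining the regression pool.
#' @return list with `aa`, `aa_standardized`, `intercept`, `slope`, `sd_aa`.
#' @export
compute_aa <- function(ba, ca, fit_pool = rep(TRUE, length(ba))) {
  if (sum(fit_pool) < 3) stop_kdm("need at least 3 subjects in the fit pool")
  if (sd(ca[fit_pool]) == 0) stop_kdm("chronological age constant in pool")
  fit <- lm(ba ~ ca, subset = fit_pool)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  aa <- ba - (a + b * ca)
  sd_aa <- sd(aa[fit_pool])
  list(aa = aa, aa_standardized = aa / sd_aa, intercept = a, slope = b,
       sd_aa = sd_aa)
}

#' Fit diagnostics of biological age against chronological age
#'
#' @param ba biological ages.
#' @param ca chronological ages.
#' @return list with `pearson_r` (correlation of BA with CA) and `rmse`
#'   (root-mean-square residual of regressing CA on BA, years).
#' @export
ba_diagnostics <- function(ba, ca) {
  if (length(ba) < 3) stop_kdm("need at least 3 subjects")
  if (sd(ba) == 0 || sd(ca) == 0) stop_kdm("constant input vector")
  fit <- lm(ca ~ ba)
  list(pearson_r = cor(ba, ca), rmse = sqrt(mean(fit$residuals^2)))
}

#' Sex-stratified biological-age construction
#'
#' Runs, separately within each sex: marker screening, correlation-matrix
#' principal components, and the Klemera-Doubal fit; evaluates the corrected
#' biological age for every subject; then derives age acceleration from a
#' single regression of biological age on chronological age within
#' `aa_pool` (all subjects for the primary analysis, the control group for
#' the control-derived sensitivity analysis).
#'
#' @param cohort harmonized analysis cohort.
#' @param panel marker panel (defines candidate marker names).
#' @param threshold screening correlation threshold.
#' @param aa_pool logical mask for the age-acceleration regression pool.
#' @param fit_pool logical mask of subjects used to *fit* the per-sex models
#'   (screening, PCA, KDM); defaults to all. Subjects outside the pool are
#'   projected through the fitted models.
#' @return an object of class `kdm_fit`: per-sex models (screening report,
#'   standardization, loadings, component parameters), a per-subject result
#'   table `ba` (`id`, `sex`, `ca`, `ba`, `aa`, `aa_standardized`), and the
#'   age-acceleration regression.
#' @export
fit_ba <- function(cohort, panel = default_marker_panel(), threshold = 0.10,
                   aa_pool = rep(TRUE, nrow(cohort)),
                   fit_pool = rep(TRUE, nrow(cohort))) {
  if (!isTRUE(attr(cohort, "harmonized"))) {
    stop_kdm("cohort must be harmonized first (harmonize_measurements)")
  }
  candidates <- panel$name
  ba <- rep(NA_real_, nrow(cohort))
  models <- list()
  for (sx in levels(factor(cohort$sex))) {
    in_sex <- cohort$sex == sx
    fit_rows <- in_sex & fit_pool
    sub <- cohort[fit_rows, , drop = FALSE]
    screening <- screen_markers(sub, candidates, threshold)
    retained <- screening$name[screening$retained]
    if (length(retained) < 1) stop_kdm("no markers retained for sex %s", sx)
    pca <- fit_pca(sub, retained)
    sb <- estimate_s_ba2(sub, retained)
    model <- fit_kdm(pca$scores, sub$ca, s_ba2 = sb$s_ba2,
                     deconflate = TRUE)
    models[[sx]] <- list(sex = sx, screening = screening,
                         markers = retained, center = pca$center,
                         scale = pca$scale, loadings = pca$loadings,
                         eigenvalues = pca$eigenvalues, model = model,
                         marker_stage = sb)
    ba[in_sex] <- project_ba_sex(models[[sx]],
                                 cohort[in_sex, , drop = FALSE])
  }
  aa <- compute_aa(ba, cohort$ca, fit_pool = aa_pool)
  structure(list(models = models,
                 aa_fit = aa[c("intercept", "slope", "sd_aa")],
                 aa_pool = aa_pool,
                 ba = data.frame(id = cohort$id, sex = cohort$sex,
                                 ca = cohort$ca, ba = ba, aa = aa$aa,
                                 aa_standardized = aa$aa_standardized,
                                 stringsAsFactors = FALSE)),
            class = "kdm_fit")
}

# Project one sex's cohort rows through that sex's fitted construction.
project_ba_sex <- function(sex_model, cohort) {
  miss <- setdiff(sex_model$markers, names(cohort))
  if (length(miss)) stop_kdm("missing marker columns: %s",
                             paste(miss, collapse = ", "))
  X <- as.matrix(cohort[, sex_model$markers, drop = FALSE])
  Z <- sweep(sweep(X, 2, sex_model$center), 2, sex_model$scale, "/")
  estimate_ba(sex_model$model, Z %*% sex_model$loadings, cohort$ca)
}

#' Project a fitted construction onto another cohort
#'
#' Standardizes the new cohort's markers with the fitting cohort's means and
#' SDs, maps them through the fitted loadings, evaluates the corrected
#' biological age with the fitted component parameters, and derives age
#' acceleration from the *fitting* cohort's biological-age-on-age
#' regression. Used by the control-derived sensitivity analysis, where
#' screening, components and weights come from controls only. Standardized
#' age acceleration divides by the SD of the projected cohort's age
#' acceleration, so it has unit SD within that cohort.
#'
#' @param fit a [fit_ba()] object (fitted e.g. on controls).
#' @param cohort harmonized cohort to project (must contain every marker the
#'   fit uses).
#' @return data.frame `id`, `sex`, `ca`, `ba`, `aa`, `aa_standardized`.
#' @export
project_control_model <- function(fit, cohort) {
  stopifnot(inherits(fit, "kdm_fit"))
  ba <- rep(NA_real_, nrow(cohort))
  for (sx in names(fit$models)) {
    in_sex <- cohort$sex == sx
    if (!any(in_sex)) next
    ba[in_sex] <- project_ba_sex(fit$models[[sx]],
                                 cohort[in_sex, , drop = FALSE])
  }
  if (any(is.na(ba))) stop_kdm("cohort contains a sex absent from the fit")
  aa <- ba - (fit$aa_fit$intercept + fit$aa_fit$slope * cohort$ca)
  data.frame(id = cohort$id, sex = cohort$sex, ca = cohort$ca, ba = ba,
             aa = aa, aa_standardized = aa / sd(aa),
             stringsAsFactors = FALSE)
}

#' Serialize a fitted construction to structured text (JSON)
#'
#' Writes every parameter needed to audit or re-apply the construction:
#' screening report, per-marker standardization, loadings, component
#' regression parameters, characteristic correlation, `s_BA^2`, and the
#' age-acceleration regression.
#'
#' @param fit a `kdm_fit` object.
#' @param path output file.
#' @export
write_kdm_fit <- function(fit, path) {
  ser <- list(aa_fit = fit$aa_fit,
              models = lapply(fit$models, function(m) {
                list(sex = m$sex, screening = m$screening,
                     markers = m$markers, center = as.list(m$center),
                     scale = as.list(m$scale),
                     loadings = unclass(m$loadings),
                     eigenvalues = m$eigenvalues,
                     pc_params = m$model$pc_params,
                     r_char = m$model$r_char, s_ba2 = m$model$s_ba2,
                     ca_range = m$model$ca_range, m = m$model$m)
              }))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
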