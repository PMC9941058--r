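test_that("marker screening applies the correlation threshold and monotonicity", {
  set.seed(101)
  n <- 4000
  ca <- runif(n, 30, 79)
  cohort <- data.frame(
    sex = factor(rep("female", n), levels = c("female", "male")), ca = ca,
    lin = 0.5 * ca + rnorm(n, 0, 1),          # strongly age-linear
    weak = 0.004 * ca + rnorm(n, 0, 2),       # population r ~ 0.03
    ushape = (ca - 55)^2 / 20 + rnorm(n, 0, 1),
    exact = 2 * ca)
  scr <- screen_markers(cohort, c("lin", "weak", "ushape", "exact"))
  expect_true(scr$retained[scr$name == "lin"])
  expect_true(scr$retained[scr$name == "exact"])
  expect_false(scr$retained[scr$name == "weak"])
  expect_false(scr$retained[scr$name == "ushape"])
  expect_false(scr$monotone[scr$name == "ushape"])

  # half-split slope oracle agrees on the U-shaped marker
  lo <- ca <= median(ca)
  s1 <- coef(lm(cohort$ushape ~ ca, subset = lo))[2]
  s2 <- coef(lm(cohort$ushape ~ ca, subset = !lo))[2]
  expect_true(sign(s1) != sign(s2))

  cohort$flat <- 1
  expect_warning(scr2 <- screen_markers(cohort, c("lin", "flat")),
                 "zero variance")
  expect_false(scr2$retained[scr2$name == "flat"])
})

test_that("correlation-matrix PCA has closed-form eigenvalues and reconstructs", {
  set.seed(7)
  n <- 5000
  a <- rnorm(n); b <- rnorm(n)
  cohort <- data.frame(x1 = a, x2 = b)
  p <- fit_pca(cohort, c("x1", "x2"))
  expect_equal(p$eigenvalues, c(1, 1), tolerance = 0.1)

  # correlation 0.6 gives eigenvalues 1.6 and 0.4
  z <- 0.6 * a + sqrt(1 - 0.36) * rnorm(n)
  cohort2 <- data.frame(x1 = a, x2 = z)
  p2 <- fit_pca(cohort2, c("x1", "x2"))
  r <- cor(a, z)
  expect_equal(p2$eigenvalues, c(1 + r, 1 - r), tolerance = 1e-10)

  # 5-marker reconstruction: L diag(ev) L^T equals the correlation matrix
  X <- matrix(rnorm(600 * 5), 600, 5) %*% matrix(runif(25, -1, 1), 5, 5)
  cohort5 <- as.data.frame(X)
  p5 <- fit_pca(cohort5, names(cohort5))
  rebuilt <- p5$loadings %*% diag(p5$eigenvalues) %*% t(p5$loadings)
  expect_equal(unname(rebuilt), unname(cor(X)), tolerance = 1e-10)
  expect_equal(unname(t(p5$loadings) %*% p5$loadings), diag(5),
               tolerance = 1e-10)
  # scores are the standardized markers rotated by the loadings
  Z <- scale(X)
  expect_equal(unname(p5$scores), unname(Z %*% p5$loadings),
               tolerance = 1e-10)
})

test_that("Klemera-Doubal component fit recovers generating parameters", {
  # single noiseless component
  ca <- seq(40, 70, length.out = 100)
  s1 <- fit_kdm(cbind(3 + 0.5 * ca), ca)
  expect_equal(s1$pc_params$q, 3, tolerance = 1e-8)
  expect_equal(s1$pc_params$k, 0.5, tolerance = 1e-10)

  # equal component correlations force r_char = |r|
  set.seed(12)
  n <- 20000
  ca2 <- runif(n, 30, 79)
  sd_n <- sqrt(var(ca2) * (1 - 0.64) / 0.64)  # population r = 0.8 per comp
  sc <- cbind(ca2 + rnorm(n, 0, sd_n), -ca2 + rnorm(n, 0, sd_n))
  m2 <- fit_kdm(sc, ca2)
  expect_equal(abs(m2$pc_params$r), c(0.8, 0.8), tolerance = 0.02)
  expect_equal(m2$r_char, sqrt(mean(m2$pc_params$r^2)), tolerance = 1e-12)

  # three components with known (q, k, s): parameter recovery within 3 SE
  # and row-by-row agreement with an independently coded estimator
  set.seed(13)
  n3 <- 500
  ca3 <- runif(n3, 30, 79)
  q <- c(1, -2, 10); k <- c(0.8, -0.3, 0.1); s <- c(2, 1.5, 0.9)
  sc3 <- sapply(1:3, function(j) q[j] + k[j] * ca3 + rnorm(n3, 0, s[j]))
  m3 <- fit_kdm(sc3, ca3)
  se_k <- s / (sd(ca3) * sqrt(n3))
  expect_true(all(abs(m3$pc_params$k - k) < 3 * se_k))
  se_q <- s * sqrt(1 / n3 + mean(ca3)^2 / (var(ca3) * n3))
  expect_true(all(abs(m3$pc_params$q - q) < 3 * se_q))
  ba_e <- kdmage:::kdm_ba_e(sc3, m3$pc_params)
  oracle <- apply(sc3, 1, brute_force_ba_e, q = m3$pc_params$q,
                  k = m3$pc_params$k, s = m3$pc_params$s)
  expect_equal(ba_e, oracle, tolerance = 1e-10)

  expect_error(fit_kdm(cbind(rnorm(50)), runif(50, 30, 79) * 0 + 50),
               "constant")
})

test_that("corrected estimator matches hand evaluation and its limits", {
  model <- structure(list(pc_params = data.frame(q = c(0, 10), k = c(1, 0.5),
                                                 s = c(1, 2), r = c(0.9, 0.8)),
                          r_char = 0.85, s_ba2 = 100, ca_range = c(30, 79),
                          m = 2), class = "kdm_model")
  x <- matrix(c(52, 36), 1, 2)
  expect_equal(estimate_ba(model, x, 50), 55.75 / 1.0725, tolerance = 1e-10)

  # s_BA^2 -> infinity: tends to the uncorrected estimate
  model_inf <- model; model_inf$s_ba2 <- 1e12
  ba_e <- kdmage:::kdm_ba_e(x, model$pc_params)
  expect_equal(estimate_ba(model_inf, x, 50), ba_e, tolerance = 1e-6)

  # s_BA^2 -> 0: tends to chronological age
  model_zero <- model; model_zero$s_ba2 <- 1e-9
  expect_equal(estimate_ba(model_zero, x, 50), 50, tolerance = 1e-6)

  # rescaling a component (q, k, s rescaled accordingly) leaves BA unchanged
  c_scale <- 3.7
  model_resc <- model
  model_resc$pc_params[1, c("q", "k", "s")] <-
    model$pc_params[1, c("q", "k", "s")] * c_scale
  x_resc <- x; x_resc[1] <- x[1] * c_scale
  expect_equal(estimate_ba(model_resc, x_resc, 50),
               estimate_ba(model, x, 50), tolerance = 1e-10)

  expect_error(estimate_ba(model, matrix(1, 1, 3), 50), "components")
})

test_that("age acceleration satisfies the least-squares residual identities", {
  set.seed(19)
  n <- 800
  ca <- runif(n, 30, 79)
  ba <- 2 + 1.01 * ca + rnorm(n, 0, 1.4)
  res <- compute_aa(ba, ca)
  expect_lt(abs(mean(res$aa)), 1e-10)
  expect_lt(abs(cor(res$aa, ca)), 1e-10)
  expect_equal(sd(res$aa_standardized), 1, tolerance = 1e-12)

  # against the normal-equation oracle
  o <- ols_oracle(ba, ca)
  expect_equal(res$aa, ba - o["intercept"] - o["slope"] * ca,
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_equal(compute_aa(ca, ca)$aa, rep(0, n), tolerance = 1e-12)
  expect_error(compute_aa(ba, rep(50, n)), "constant")
})

test_that("fit diagnostics reduce to closed forms and reject degenerate input", {
  ca <- seq(30, 79, length.out = 200)
  d <- ba_diagnostics(ca, ca)
  expect_equal(d$pearson_r, 1)
  expect_equal(d$rmse, 0, tolerance = 1e-12)

  set.seed(23)
  n <- 10000
  ca2 <- runif(n, 30, 79)
  ba2 <- ca2 + rnorm(n, 0, 1.4)
  d2 <- ba_diagnostics(ba2, ca2)
  fit <- lm(ca2 ~ ba2)
  expect_equal(d2$rmse, sqrt(mean(fit$residuals^2)), tolerance = 1e-12)
  expect_equal(d2$pearson_r, cor(ba2, ca2), tolerance = 1e-12)

  expect_error(ba_diagnostics(rep(50, 10), runif(10, 30, 79)), "constant")
})

test_that("noiseless markers give biological age equal to chronological age", {
  panel <- default_marker_panel(informative_noise_scale = 0)
  cfg <- sim_config(n_per_group = c(control = 700, MCE = 240, IS = 330,
                                    ICH_SAH = 330),
                    group_aa_mean = c(control = 0, MCE = 0, IS = 0,
                                      ICH_SAH = 0),
                    aa_sd = 1e-15, marker_panel = panel, seed = 29)
  g <- generate_cohort(cfg)
  h <- harmonize_measurements(g$cohort, panel = panel)
  fit <- fit_ba(h, panel = panel)
  expect_lt(max(abs(fit$ba$ba - h$ca)), 1e-8)
})

test_that("marker column order does not affect biological age", {
  sc <- small_cohort(seed = 31, n_scale = 0.05)
  fit1 <- fit_ba(sc$cohort)
  panel_rev <- default_marker_panel()[rev(seq_len(25)), ]
  fit2 <- fit_ba(sc$cohort, panel = panel_rev)
  expect_equal(fit1$ba$ba, fit2$ba$ba, tolerance = 1e-9)
})

test_that("estimated age acceleration tracks the latent truth, more so with less noise", {
  cors <- sapply(c(2, 1, 0.25), function(scl) {
    # scale only the age-informative markers so the screened set is stable
    # across noise levels and the property isolates the noise level itself
    panel <- default_marker_panel()
    inf <- panel$monotone & kdmage:::marker_age_r(panel) > 0.10
    panel$noise_sd_s[inf] <- panel$noise_sd_s[inf] * scl
    cfg <- sim_config(n_per_group = c(control = 500, MCE = 160, IS = 220,
                                      ICH_SAH = 220),
                      marker_panel = panel, seed = 37)
    g <- generate_cohort(cfg)
    h <- harmonize_measurements(g$cohort, panel = panel)
    fit <- fit_ba(h, panel = panel)
    tr <- g$truth[match(h$id, g$truth$id), ]
    cor(fit$ba$aa, tr$true_aa)
  })
  expect_true(all(cors > 0))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.97)
})

test_that("per-sex fits are independent of the other sex's data", {
  sc <- small_cohort(seed = 41, n_scale = 0.06)
  h <- sc$cohort
  fit_all <- fit_ba(h)
  for (sx in c("female", "male")) {
    sub <- h[h$sex == sx, , drop = FALSE]
    scr <- screen_markers(sub, default_marker_panel()$name)
    pca <- fit_pca(sub, scr$name[scr$retained])
    sb <- estimate_s_ba2(sub, scr$name[scr$retained])
    mod <- fit_kdm(pca$scores, sub$ca, s_ba2 = sb$s_ba2, deconflate = TRUE)
    ba_sex <- estimate_ba(mod, pca$scores, sub$ca)
    expect_equal(fit_all$ba$ba[h$sex == sx], ba_sex, tolerance = 1e-9)
  }
})

test_that("control-fitted construction projects exactly onto itself and recovers case shifts", {
  cfg_ctrl <- sim_config(n_per_group = c(control = 2500, MCE = 2, IS = 2,
                                         ICH_SAH = 2),
                         group_aa_mean = c(control = 0, MCE = 0, IS = 0,
                                           ICH_SAH = 0), seed = 43)
  ctrl <- generate_cohort(cfg_ctrl)
  h_ctrl <- add_lifestyle_columns(harmonize_measurements(ctrl$cohort))
  h_ctrl <- h_ctrl[h_ctrl$group == "control", , drop = FALSE]
  fit_ctrl <- fit_ba(h_ctrl)

  proj_self <- project_control_model(fit_ctrl, h_ctrl)
  expect_equal(proj_self$ba, fit_ctrl$ba$ba, tolerance = 1e-10)
  expect_equal(proj_self$aa, fit_ctrl$ba$aa, tolerance = 1e-10)
  expect_equal(sd(proj_self$aa_standardized), 1, tolerance = 1e-10)

  cfg_case <- sim_config(n_per_group = c(control = 2, MCE = 2, IS = 2,
                                         ICH_SAH = 2000),
                         group_aa_mean = c(control = 0, MCE = 0, IS = 0,
                                           ICH_SAH = 0.3), seed = 44)
  case <- generate_cohort(cfg_case)
  h_case <- add_lifestyle_columns(harmonize_measurements(case$cohort))
  h_case <- h_case[h_case$group == "ICH_SAH", , drop = FALSE]
  proj <- project_control_model(fit_ctrl, h_case)
  expect_lt(abs(mean(proj$aa) - 0.3), 3 * sd(proj$aa) / sqrt(nrow(h_case)))
})
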