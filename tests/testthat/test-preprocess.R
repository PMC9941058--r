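test_that("exclusion cascade removes categories in order and conserves counts", {
  fx <- generate_exclusion_fixture(1000, c(sample_quality = 50, under_lod = 30,
                                           missing_marker = 10,
                                           outlier_4sd = 20), seed = 4)
  res <- apply_exclusions(fx)
  expect_equal(res$log$removed, c(50, 30, 10, 20))
  expect_equal(attr(res$log, "input"), 1000)
  expect_equal(attr(res$log, "output"), 890)
  expect_equal(nrow(res$cohort), 890)
  expect_equal(attr(res$log, "input"),
               attr(res$log, "output") + sum(res$log$removed))
})

test_that("constant markers skip the outlier screen with a warning record", {
  n <- 30
  cohort <- data.frame(id = as.character(1:n), exclusion_flag = "",
                       x = rep(5, n))
  res <- apply_exclusions(cohort, marker_cols = "x")
  expect_equal(sum(res$log$removed), 0)
  expect_match(attr(res$log, "warnings"), "constant")
})

test_that("outlier rule is strict: exactly 4 SD is retained", {
  # construct a value sitting exactly at mean + 4 * SD of the full pool
  set.seed(8)
  base <- scale(rnorm(120))[, 1]     # mean 0, sd 1 exactly
  n <- length(base) + 2
  t_exact <- sqrt(16 * sum(base^2) / (n - 1 - 32)) * (1 - 1e-9)
  x <- c(base, t_exact, -t_exact)
  z <- abs(x - mean(x)) / sd(x)
  expect_equal(max(z), 4, tolerance = 1e-6)
  cohort <- data.frame(id = as.character(seq_len(n)), exclusion_flag = "",
                       x = x)
  res <- apply_exclusions(cohort, marker_cols = "x")
  expect_equal(sum(res$log$removed), 0)

  # push the extreme pair outward until it is strictly outside 4 SD
  x2 <- c(base, 1.1 * t_exact, -1.1 * t_exact)
  z2 <- abs(x2 - mean(x2)) / sd(x2)
  expect_gt(max(z2), 4)
  cohort2 <- data.frame(id = as.character(seq_len(n)), exclusion_flag = "",
                        x = x2)
  res2 <- apply_exclusions(cohort2, marker_cols = "x")
  # brute-force rule application is the oracle
  expect_equal(res2$log$removed[4], sum(z2 > 4))
})

test_that("harmonization applies medication, glucose and log rules once", {
  cohort <- data.frame(id = c("a", "b", "c"),
                       antihypertensive = c(TRUE, FALSE, FALSE),
                       sbp = c(140, 120, 118), dbp = c(80, 70, 72),
                       rpg = c(5.0, 8.2, 6.0), fpg = c(NA, 6.1, NA),
                       albumin = c(45, 46, 47),
                       creatinine = c(60, 70, 80))
  h <- harmonize_measurements(cohort)
  expect_equal(h$sbp, c(155, 120, 118))
  expect_equal(h$dbp, c(90, 70, 72))
  expect_equal(h$glucose, log(c(5.0, 6.1, 6.0)))
  expect_equal(h$albumin, c(45, 46, 47))        # albumin never logged
  expect_equal(h$creatinine, log(c(60, 70, 80)))
  expect_error(harmonize_measurements(h), "twice")

  bad <- cohort
  bad$creatinine[1] <- -1
  expect_error(harmonize_measurements(bad), "non-positive")
})

test_that("dietary score counts the five risky habits", {
  make <- function(veg, fruit, meat, soy, fish) {
    data.frame(veg_freq = factor(veg, levels = kdmage:::diet_levels),
               fruit_freq = factor(fruit, levels = kdmage:::diet_levels),
               meat_freq = factor(meat, levels = kdmage:::diet_levels),
               soybean_freq = factor(soy, levels = kdmage:::diet_levels),
               fish_freq = factor(fish, levels = kdmage:::diet_levels))
  }
  # all five risky
  expect_equal(compute_dietary_score(
    make("monthly", "monthly", "daily", "1_3_per_week", "monthly")), 5L)
  # none risky
  expect_equal(compute_dietary_score(
    make("daily", "daily", "4_6_per_week", "4_6_per_week", "1_3_per_week")), 0L)
  # four risky: fruit monthly, red meat daily, soybean 1-3/wk, fish < weekly
  expect_equal(compute_dietary_score(
    make("daily", "monthly", "daily", "1_3_per_week", "monthly")), 4L)
  expect_error(compute_dietary_score(make("daily", "daily", "daily",
                                          "daily", "daily")[, -1]),
               "missing")
})

test_that("lifestyle score assembles the four risk factors and flags 3-4", {
  base <- data.frame(sex = factor(c("male", "male"),
                                  levels = c("female", "male")),
                     ca = c(45, 45),
                     smoking_status = factor(c("current", "never"),
                                             levels = c("never", "former",
                                                        "current")),
                     quit_for_illness = c(FALSE, FALSE),
                     alcohol_g = c(40, 0), past_drinker = c(FALSE, FALSE),
                     veg_freq = factor(c("monthly", "daily"),
                                       levels = kdmage:::diet_levels),
                     fruit_freq = factor(c("monthly", "daily"),
                                         levels = kdmage:::diet_levels),
                     meat_freq = factor(c("daily", "4_6_per_week"),
                                        levels = kdmage:::diet_levels),
                     soybean_freq = factor(c("monthly", "daily"),
                                           levels = kdmage:::diet_levels),
                     fish_freq = factor(c("monthly", "daily"),
                                        levels = kdmage:::diet_levels),
                     total_activity = c(10, 30))
  med <- data.frame(age_band = factor("<50", levels = c("<50", "50-59",
                                                        ">=60")),
                    sex = factor("male", levels = c("female", "male")),
                    median_activity = 20)
  sc <- compute_lifestyle_score(base, med)
  expect_equal(sc$lifestyle_score, c(4L, 0L))
  expect_equal(sc$risky, c(TRUE, FALSE))

  # quitting for illness counts as current smoking; score 3 is risky
  base$smoking_status <- factor(c("former", "never"),
                                levels = c("never", "former", "current"))
  base$quit_for_illness <- c(TRUE, FALSE)
  base$alcohol_g <- c(10, 0)
  sc2 <- compute_lifestyle_score(base, med)
  expect_equal(sc2$lifestyle_score[1], 3L)
  expect_true(sc2$risky[1])
})

test_that("scores stay within bounds on generated cohorts", {
  sc <- small_cohort(seed = 17, n_scale = 0.05)
  s <- compute_lifestyle_score(sc$cohort)
  expect_true(all(s$dietary_score >= 0 & s$dietary_score <= 5))
  expect_true(all(s$lifestyle_score >= 0 & s$lifestyle_score <= 4))
  expect_equal(s$risky, s$lifestyle_score >= 3)
})

test_that("activity ties go to the non-risky side", {
  cohort <- data.frame(sex = factor(rep("male", 3),
                                    levels = c("female", "male")),
                       ca = c(45, 45, 45),
                       total_activity = c(10, 20, 30))
  med <- data.frame(age_band = factor("<50", levels = c("<50", "50-59",
                                                        ">=60")),
                    sex = factor("male", levels = c("female", "male")),
                    median_activity = 20)
  comp <- kdmage:::lifestyle_components(
    cbind(cohort,
          smoking_status = factor("never", levels = c("never", "former",
                                                      "current")),
          quit_for_illness = FALSE, alcohol_g = 0, past_drinker = FALSE,
          veg_freq = factor("daily", levels = kdmage:::diet_levels),
          fruit_freq = factor("daily", levels = kdmage:::diet_levels),
          meat_freq = factor("4_6_per_week", levels = kdmage:::diet_levels),
          soybean_freq = factor("daily", levels = kdmage:::diet_levels),
          fish_freq = factor("daily", levels = kdmage:::diet_levels)),
    med)
  expect_equal(comp$low_activity, c(TRUE, FALSE, FALSE))
})
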