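# Independent oracles used across the suite. Each reimplements a quantity
# from first principles (enumeration, closed form, normal equations) without
# touching the package's own code paths.

# O(n^2) pairwise Harrell concordance: subject i dying at t_i forms a usable
# pair with every j still at risk at t_i; ties in risk score count one half.
brute_force_c <- function(time, event, risk) {
  n <- length(time)
  conc <- ties <- usable <- 0
  for (i in seq_len(n)) {
    if (!event[i]) next
    for (j in seq_len(n)) {
      if (j == i) next
      at_risk <- time[j] > time[i] || (time[j] == time[i] && !event[j])
      if (!at_risk) next
      usable <- usable + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) ties <- ties + 1
    }
  }
  (conc + ties / 2) / usable
}

# Closed-form uncorrected Klemera-Doubal estimate, written independently of
# the package's matrix formulation.
brute_force_ba_e <- function(x_row, q, k, s) {
  sum((x_row - q) * k / s^2) / sum(k^2 / s^2)
}

# Grid-search maximizer of the Cox partial likelihood (no ties).
grid_search_cox <- function(time, event, x, grid = seq(-5, 5, by = 1e-4)) {
  logpl <- vapply(grid, function(b) {
    ll <- 0
    for (i in which(event)) {
      at_risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[at_risk])))
    }
    ll
  }, numeric(1))
  grid[which.max(logpl)]
}

# Two-parameter least squares via the normal equations.
ols_oracle <- function(y, x) {
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  c(intercept = a, slope = b)
}

# Small analysis-ready synthetic cohort used by several tests.
small_cohort <- function(seed = 11, n_scale = 0.08) {
  cfg <- sim_config(n_per_group = round(c(control = 4197, MCE = 876,
                                          IS = 3837, ICH_SAH = 3467) * n_scale),
                    seed = seed)
  gen <- generate_cohort(cfg)
  h <- harmonize_measurements(gen$cohort)
  h <- add_lifestyle_columns(h)
  truth <- gen$truth[match(h$id, gen$truth$id), ]
  list(cohort = h, truth = truth, config = cfg)
}
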