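.fit_setup <- function(n_doses = 1) {
  rig <- rig_config()
  tp <- target_pk(10.7, ke = 0.230, tau = 12, mode = "iv", t_infusion = 0.5,
                  n_doses = n_doses)
  list(rig = rig, sch = infusion_schedule(design_iv(tp, rig),
                                          n_doses = n_doses))
}

test_that("synthetic observations: zero noise, determinism, truncation count", {
  s <- .fit_setup()
  times <- c(0.25, 0.5, 1, 2, 4, 8, 12)
  clean <- generate_synthetic_observations(s$rig, s$sch, times,
                                           prop_sd = 0, add_sd = 0, seed = 1)
  sim <- simulate_rig(s$rig, s$sch, times)
  sim <- sim[sim$compartment %in% c("central", "ECS"), ]
  expect_equal(clean$conc_mg_L, sim$conc_mg_L)
  a <- generate_synthetic_observations(s$rig, s$sch, times, seed = 99)
  b <- generate_synthetic_observations(s$rig, s$sch, times, seed = 99)
  expect_identical(a, b)
  expect_error(generate_synthetic_observations(s$rig, s$sch, times), "seed")
  # large additive noise on tiny concentrations must truncate and say so
  noisy <- generate_synthetic_observations(s$rig, s$sch, times,
                                           prop_sd = 0, add_sd = 50, seed = 3)
  expect_gt(attr(noisy, "n_truncated"), 0)
  expect_true(all(noisy$conc_mg_L >= 0))
})

test_that("proportional error produces the nominal coefficient of variation", {
  s <- .fit_setup()
  obs <- generate_synthetic_observations(s$rig, s$sch, c(1, 4),
                                         prop_sd = 0.1, add_sd = 0,
                                         n_replicates = 400, seed = 11)
  for (cmp in c("central", "ECS")) {
    x <- obs$conc_mg_L[obs$compartment == cmp & obs$time_h == 4]
    cv <- sd(x) / mean(x)
    expect_lt(abs(cv - 0.10), 0.02)
  }
})

test_that("noise-free data returns the generating diffusion rate", {
  s <- .fit_setup()
  times <- c(0.1, 0.2, 0.3, 0.5, 0.75, 1, 2, 4, 8, 12)
  obs <- generate_synthetic_observations(s$rig, s$sch, times,
                                         q_diffusion = 0.387,
                                         prop_sd = 0, add_sd = 0, seed = 5)
  fit <- fit_qdiffusion(obs, s$rig, s$sch, q_starts = c(0.05, 1))
  expect_true(fit$converged)
  expect_equal(fit$q_diffusion, 0.387, tolerance = 1e-3)
})

test_that("multi-start finds a distant optimum", {
  s <- .fit_setup()
  times <- c(0.1, 0.2, 0.3, 0.5, 0.75, 1, 2, 4, 8, 12)
  obs <- generate_synthetic_observations(s$rig, s$sch, times,
                                         q_diffusion = 1.0,
                                         prop_sd = 0.02, add_sd = 0,
                                         n_replicates = 2, seed = 17)
  fit <- fit_qdiffusion(obs, s$rig, s$sch, q_starts = 0.01)
  expect_equal(fit$q_diffusion, 1.0, tolerance = 0.1)
})

test_that("prediction band behaves at the edges and monotonically in sd", {
  s <- .fit_setup()
  times <- seq(0.25, 12, by = 0.25)
  obs0 <- generate_synthetic_observations(s$rig, s$sch, times,
                                          prop_sd = 0, add_sd = 0, seed = 2)
  fit0 <- list(q_diffusion = 0.387, prop_sd = 1e-12, add_sd = 1e-12)
  pic <- prediction_interval_check(fit0, obs0, s$rig, s$sch, n_sims = 200,
                                   seed = 4)
  expect_equal(pic$coverage, 1.0)
  # grossly shifted observations fall outside the band
  shifted <- obs0
  shifted$conc_mg_L <- shifted$conc_mg_L * 1.5
  fit1 <- list(q_diffusion = 0.387, prop_sd = 0.1, add_sd = 0.01)
  pic_bad <- prediction_interval_check(fit1, shifted, s$rig, s$sch,
                                       n_sims = 200, seed = 4)
  expect_lt(pic_bad$coverage, 0.5)
  expect_false(pic_bad$pass)
  # a larger residual sd never shrinks coverage on fixed observations
  obs <- generate_synthetic_observations(s$rig, s$sch, times,
                                         prop_sd = 0.1, add_sd = 0, seed = 6)
  cov_small <- prediction_interval_check(
    list(q_diffusion = 0.387, prop_sd = 0.05, add_sd = 0.01),
    obs, s$rig, s$sch, n_sims = 300, seed = 8)$coverage
  cov_large <- prediction_interval_check(
    list(q_diffusion = 0.387, prop_sd = 0.2, add_sd = 0.01),
    obs, s$rig, s$sch, n_sims = 300, seed = 8)$coverage
  expect_gte(cov_large, cov_small)
})

test_that("target-vs-observed comparison implements the 20% rule", {
  r <- compare_to_target(c(cmax_1 = 4.25), c(cmax_1 = 4.25))
  expect_equal(r$bias, 0)
  expect_true(r$pass)
  r2 <- compare_to_target(c(auc_tau_ss = 66.9), c(auc_tau_ss = 67.1))
  expect_equal(r2$bias, 100 * (67.1 - 66.9) / 66.9)
  expect_true(r2$pass)
  r3 <- compare_to_target(c(cmax_ss = 10), c(cmax_ss = 12.5))
  expect_false(r3$pass)
  # boundary: exactly 20% passes
  expect_true(compare_to_target(c(x = 10), c(x = 12))$pass)
  # Tmax is compared absolutely in hours and flagged, not pass/failed
  r4 <- compare_to_target(c(tmax_1 = 0.5), c(tmax_1 = 0.75))
  expect_equal(r4$bias, 0.25)
  expect_identical(r4$bias_type, "absolute_h")
  expect_true(is.na(r4$pass))
  r5 <- compare_to_target(c(cmin_ss = 0), c(cmin_ss = 0.3))
  expect_true(is.na(r5$bias))
  expect_identical(r5$bias_type, "undefined_target_zero")
})

test_that("swapping target and observed flips the bias up to the denominator", {
  fwd <- compare_to_target(c(x = 10), c(x = 12))$bias
  rev <- compare_to_target(c(x = 12), c(x = 10))$bias
  # -20% vs +16.7%: antisymmetric after rescaling by the denominators
  expect_equal(rev, -fwd * 10 / 12)
})

test_that("profile bias metrics: closed-form cases and zero handling", {
  g <- seq(0.5, 12, by = 0.5)
  tgt <- concentration_series(g, 5 * exp(-0.2 * g))
  same <- profile_bias_metrics(tgt, tgt)
  expect_equal(same$mpe, 0)
  expect_equal(same$rmse, 0)
  lower <- concentration_series(g, 0.9 * tgt$conc_mg_L)
  m <- profile_bias_metrics(lower, tgt)
  expect_equal(m$mpe, -10)
  expect_equal(m$rmse, 0.1 * sqrt(mean(tgt$conc_mg_L^2)))
  tgt0 <- concentration_series(g, c(0, tgt$conc_mg_L[-1]))
  m0 <- profile_bias_metrics(lower, tgt0)
  expect_identical(m0$n_excluded, 1L)
})

test_that("the 12-sub-interval program tracks the CSF target within 10% bias", {
  rig <- rig_config()
  dose <- compute_dose(4.25, 0.300, 0.230, v_total(rig))
  s <- build_schedule(dose, 0.300, 12L, 12)
  g <- seq(0.1, 12, by = 0.1)
  lp <- expected_lumped_profile(
    data.frame(t_start = s$t_start, t_end = s$t_end, rate_mg_h = s$rate_mg_h),
    ke = 0.230, v_total = v_total(rig), grid = g)
  tgt <- simulate_mono_profile(
    target_pk(4.25, ke = 0.230, tau = 12, ka = 0.300, n_doses = 1), g)
  m <- profile_bias_metrics(lp, tgt)
  expect_lt(abs(m$mpe), 10)
})
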