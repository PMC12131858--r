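test_that("dose inversion reproduces the requested peak", {
  # oracle: evaluate the textbook absorption curve for a trial dose on a
  # fine grid and scale linearly to the target peak
  cmax1 <- 4.25; ka <- 0.300; ke <- 0.230; v <- 0.360
  tt <- seq(0.0005, 24, by = 0.0005)
  unit_peak <- max(1 * ka / (v * (ka - ke)) * (exp(-ke * tt) - exp(-ka * tt)))
  expect_equal(compute_dose(cmax1, ka, ke, v), cmax1 / unit_peak,
               tolerance = 1e-6)
  expect_equal(compute_dose(0, ka, ke, v), 0)
  expect_equal(compute_dose(cmax1, ka, ke, v, F = 0.5),
               2 * compute_dose(cmax1, ka, ke, v))
  # equal-rate limit: peak of ka*t*exp(-ka t)/v is exp(-1)/v
  expect_equal(compute_dose(1, 0.3, 0.3, v), v * exp(1), tolerance = 1e-9)
  expect_error(compute_dose(1, 0.3, 0.23, v, F = 0))
})

test_that("delivered-dose fraction behaves like 1 - exp(-ka t_n)", {
  expect_identical(floor(100 * compute_fdose(0.300, 12)), 97)
  expect_identical(floor(100 * compute_fdose(0.300, 8)), 90)
  expect_equal(compute_fdose(0.3, 1e4), 1.0)
  expect_true(compute_fdose(0.3, 8) < compute_fdose(0.3, 12))
  expect_true(compute_fdose(0.2, 12) < compute_fdose(0.3, 12))
  expect_error(compute_fdose(0, 12))
})

test_that("sub-interval schedule delivers equal amounts on the exact clock", {
  dose <- 3.663; ka <- 0.300; n <- 12L; t_n <- 12
  s <- build_schedule(dose, ka, n, t_n)
  expect_identical(nrow(s), 12L)
  # equal amounts to machine precision
  expect_lt(max(s$amount_mg) - min(s$amount_mg), 1e-12 * dose)
  expect_equal(sum(s$amount_mg), dose * attr(s, "f_dose"), tolerance = 1e-12)
  # cumulative delivery at each end time equals the absorption curve
  expect_equal(cumsum(s$amount_mg), dose * (1 - exp(-ka * s$t_end)),
               tolerance = 1e-12)
  expect_equal(s$t_end[n], t_n)
  # durations grow strictly with the index (convexity of the end times)
  expect_true(all(diff(s$duration_h) > 0))
  expect_error(build_schedule(dose, ka, 1L, t_n), "n must be")
})

test_that("two sub-intervals at small ka split the dose in near-equal halves", {
  s <- build_schedule(10, 0.001, 2L, 12)
  expect_equal(s$amount_mg, rep(10 * attr(s, "f_dose") / 2, 2))
  expect_equal(s$duration_h[1L], s$duration_h[2L], tolerance = 0.01)
})

test_that("infusion concentration targets the per-sub-interval volume", {
  s <- build_schedule(3.663036, 0.300, 12L, 12)
  c_inf <- select_infusion_concentration(s, 2)
  expect_equal(c_inf, s$amount_mg[1L] / 2)
  expect_equal(select_infusion_concentration(s, 4), c_inf / 2)
  s0 <- s; s0$amount_mg <- 0
  expect_error(select_infusion_concentration(s0), "amounts")
})

test_that("quantization is idempotent on already-programmable schedules", {
  s <- build_schedule(3.663036, 0.300, 12L, 12)
  c_inf <- select_infusion_concentration(s, 2)
  p1 <- quantize_program(s, c_inf)
  # feed the quantized values back through as a schedule on the grid
  s2 <- s
  s2$duration_h <- p1$duration_min / 60
  s2$t_end <- cumsum(s2$duration_h)
  s2$t_start <- c(0, utils::head(s2$t_end, -1))
  s2$rate_mg_h <- p1$flow_mL_h * c_inf
  p2 <- quantize_program(s2, c_inf)
  expect_equal(p2$duration_min, p1$duration_min)
  expect_equal(p2$flow_mL_h, p1$flow_mL_h)
})

test_that("quantization conserves the delivered dose within 3%", {
  s <- build_schedule(compute_dose(4.25, 0.3, 0.23, 0.36), 0.300, 12L, 12)
  c_inf <- select_infusion_concentration(s, 2)
  p <- quantize_program(s, c_inf)
  target <- attr(s, "dose") * attr(s, "f_dose")
  expect_lt(abs(sum(p$amount_delivered_mg) - target) / target, 0.03)
})

test_that("a positive rate quantized to zero flow is flagged with a warning", {
  s <- build_schedule(0.01, 0.300, 4L, 12)  # tiny dose -> tiny flows
  c_inf <- 1  # mg/mL, makes flows ~1e-3 mL/h
  expect_warning(p <- quantize_program(s, c_inf), "zero flow")
  expect_true(any(p$zero_flow_flag))
})

test_that("dilution-pump sizing follows CL = ke * V and V_dil = CL * T", {
  e <- elimination_setup(0.230, 0.360, 96)
  expect_equal(e$cl_elim, 0.0828)
  expect_equal(e$v_diluent, 7.9488)
  expect_equal(elimination_setup(0, 0.360, 96), list(cl_elim = 0, v_diluent = 0))
  e2 <- elimination_setup(0.230, 0.360, 192)
  expect_equal(e2$cl_elim, e$cl_elim)
  expect_equal(e2$v_diluent, 2 * e$v_diluent)
})

test_that("iv design reaches the target peak at end of infusion", {
  rig <- rig_config()
  tp <- target_pk(10.7, ke = 0.230, tau = 12, mode = "iv", t_infusion = 0.5,
                  n_doses = 1)
  d <- design_iv(tp, rig)
  sch <- infusion_schedule(d, n_doses = 1)
  grid <- seq(0.005, 12, by = 0.005)  # grid hits t = 0.5 exactly
  prof <- expected_lumped_profile(sch, ke = 0.230, v_total = v_total(rig),
                                  grid = grid)
  expect_equal(max(prof$conc_mg_L), 10.7, tolerance = 1e-6)
  # no-elimination limit: dose -> cmax1 * v_total
  tp0 <- target_pk(10.7, ke = 1e-9, tau = 12, mode = "iv", t_infusion = 0.5)
  expect_equal(design_iv(tp0, rig)$dose, 10.7 * v_total(rig), tolerance = 1e-6)
  # linearity in the target peak
  tp2 <- target_pk(21.4, ke = 0.230, tau = 12, mode = "iv", t_infusion = 0.5)
  expect_equal(design_iv(tp2, rig)$c_infusion, 2 * d$c_infusion)
  expect_error(design_iv(tp, rig, infusion_volume = 0))
})

test_that("finer sub-division tracks the absorption curve ever closer", {
  rig <- rig_config()
  tgt <- target_pk(4.25, ke = 0.230, tau = 12, ka = 0.300, n_doses = 1)
  grid <- seq(0.01, 12, by = 0.01)
  ref <- simulate_mono_profile(tgt, grid)$conc_mg_L
  dose <- compute_dose(4.25, 0.300, 0.230, v_total(rig))
  sup <- vapply(c(4L, 8L, 16L, 32L), function(n) {
    s <- build_schedule(dose, 0.300, n, 12)
    lp <- expected_lumped_profile(
      data.frame(t_start = s$t_start, t_end = s$t_end, rate_mg_h = s$rate_mg_h),
      ke = 0.230, v_total = v_total(rig), grid = grid)
    max(abs(lp$conc_mg_L - ref))
  }, numeric(1))
  expect_true(all(diff(sup) < 0))
})
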