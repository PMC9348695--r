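test_that("a lesion-free start stays at the trivial equilibrium", {
  p <- athero_params(R0 = 1, init_MONO = 0, init_IM = 0, init_L = 0,
                     init_F = 0)
  tr <- simulate_model(p, t_end_weeks = 52, output_weeks = c(0, 10, 52))
  for (col in c("MONO", "IM", "L", "F")) expect_equal(tr[[col]], rep(0, 3))
  expect_equal(tr$R, rep(1, 3))
  expect_equal(tr$MONO_B, rep(1, 3), tolerance = 1e-9)
  expect_equal(tr$L_B, rep(1, 3), tolerance = 1e-9)
  expect_equal(tr$lesion_area_pct, rep(0, 3))
})

test_that("a small initial lesion grows away from the trivial equilibrium", {
  p <- athero_params(R0 = 1 - 1e-4)
  tr <- simulate_model(p, t_end_weeks = 52,
                       output_weeks = seq(0, 52, by = 4))
  les <- tr$lesion_area_pct
  expect_true(all(diff(les) > 0))
  expect_gt(les[length(les)], 10 * les[1])
})

test_that("lesion fraction obeys the exact foam-cell exponential relation", {
  # dR/dt = xi/2 (R - 1/R) dF/dt integrates to
  # 1 - R(t)^2 = (1 - R0^2) exp(xi (F(t) - F(0))): an analytic invariant
  # of the equations that the numerical trajectory must respect.
  p <- athero_params()
  fc <- athero_factors()
  for (id in c(1, 4, 8)) {
    tr <- simulate_model(p, scenario_ = builtin_scenario(id), factors = fc,
                         t_end_weeks = 80, output_weeks = seq(0, 80, by = 2))
    u <- 1 - tr$R^2
    u_pred <- (1 - p$R0^2) * exp(p$xi * (tr$F - p$init_F))
    expect_equal(u, u_pred, tolerance = 1e-7)
  }
})

test_that("adaptive and fixed-step (0.05 d) solutions agree to 1e-6", {
  p <- athero_params()
  fc <- athero_factors()
  wk <- seq(0, 30, by = 2)
  ad <- simulate_model(p, scenario_ = builtin_scenario(4), factors = fc,
                       t_end_weeks = 30, output_weeks = wk)
  fx <- simulate_model(p, scenario_ = builtin_scenario(4), factors = fc,
                       t_end_weeks = 30, output_weeks = wk,
                       method = "fixed", step = 0.05)
  for (col in c("LDL_blood", "MONO_blood", "lesion_area_pct")) {
    expect_equal(ad[[col]], fx[[col]], tolerance = 1e-6)
    expect_lt(max(abs(ad[[col]] - fx[[col]])), 1e-6 * max(1, max(ad[[col]])))
  }
})

test_that("refining the output grid does not change reported values", {
  p <- athero_params()
  coarse <- simulate_model(p, t_end_weeks = 40,
                           output_weeks = seq(0, 40, by = 2))
  fine <- simulate_model(p, t_end_weeks = 40,
                         output_weeks = seq(0, 40, by = 1))
  common <- fine[fine$time_weeks %in% coarse$time_weeks, ]
  for (col in c("LDL_blood", "MONO_blood", "lesion_area_pct")) {
    expect_equal(coarse[[col]], common[[col]], tolerance = 1e-8)
  }
})

test_that("terminal lesion burden responds monotonically to uptake factors", {
  p <- athero_params()
  terminal <- vapply(c(0.8, 1, 1.3, 1.8, 2.4), function(fhfd) {
    sc <- scenario(data.frame(kind = "HFD", start_week = 16, end_week = Inf))
    fc <- athero_factors(d_HFD = fhfd)
    tr <- simulate_model(p, scenario_ = sc, factors = fc, t_end_weeks = 104,
                         output_weeks = c(0, 104))
    tr$lesion_area_pct[2]
  }, numeric(1))
  expect_true(all(diff(terminal) >= 0))
})

test_that("steady-state detection converges from the standard start", {
  p <- athero_params()
  ss <- steady_state(p, din_value = 1, horizon_days = 2 * 730, tol = 1e-6)
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-6)
  expect_gt(ss$observables$lesion_area_pct, 0)

  # exact equilibrium start: residual is zero to solver accuracy
  p0 <- athero_params(R0 = 1, init_MONO = 0, init_IM = 0, init_L = 0,
                      init_F = 0)
  ss0 <- steady_state(p0, din_value = 1, horizon_days = 30)
  expect_true(ss0$converged)
  expect_lt(ss0$residual, 1e-9)
  expect_equal(ss0$observables$lesion_area_pct, 0)

  g <- glance(ss)
  expect_s3_class(g, "tbl_df")
  expect_named(g, c("din_value", "horizon_days", "converged", "residual",
                    "lesion_area_pct", "LDL_blood", "MONO_blood"))
})

test_that("an all-neutral schedule reproduces the control simulation exactly", {
  p <- athero_params()
  unit <- athero_factors(d_HFD = 1, d_ABIO = 1, d_Immod = 1, d_PA = 1)
  wk <- c(20, 40, 60)
  via_schedule <- predict_experiment(p, builtin_scenario(8), wk,
                                     factors = unit)
  control <- predict_experiment(p, builtin_scenario(1), wk,
                                factors = athero_factors())
  expect_equal(via_schedule, control)
})

test_that("interventions are reversible: trajectories return to control", {
  # treat during weeks 16-56, then wash out for two years; by the end of
  # the horizon every observable is back on the control trajectory
  p <- athero_params()
  fc <- athero_factors()
  ctrl <- predict_experiment(p, builtin_scenario(1), 160, factors = fc)
  for (kind in c("HFD", "PA")) {
    sc <- scenario(data.frame(kind = kind, start_week = 16, end_week = 56))
    trt <- predict_experiment(p, sc, 160, factors = fc)
    for (col in c("LDL_blood", "MONO_blood", "lesion_area_pct")) {
      expect_lt(abs(trt[[col]] - ctrl[[col]]) / ctrl[[col]], 0.01)
    }
  }
})

test_that("parameters driving full occlusion raise an error", {
  p <- athero_params(xi = 40)   # radius collapse under high uptake
  expect_error(
    simulate_model(p, din = athero_factors()$d_ABIO, t_end_weeks = 104),
    "occlusion"
  )
})

test_that("simulation inputs are validated", {
  p <- athero_params()
  expect_error(simulate_model(p, t_end_weeks = -1), "positive")
  expect_error(simulate_model(p, t_end_weeks = 10, output_weeks = c(5, 20)),
               "within")
  expect_error(simulate_model(p, scenario_ = builtin_scenario(4)),
               "factors")
})
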