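test_that("built-in scenarios carry the study's event patterns", {
  expect_equal(nrow(builtin_scenario(1)$events), 0)
  expect_equal(nrow(builtin_scenario(2)$events), 0)

  ev8 <- builtin_scenario(8)$events
  expect_setequal(ev8$kind, c("ABIO", "HFD", "PA"))
  expect_equal(ev8$start_week[ev8$kind == "ABIO"], 12)
  expect_equal(ev8$start_week[ev8$kind == "HFD"], 16)
  expect_equal(ev8$start_week[ev8$kind == "PA"], 18)
  expect_true(all(is.infinite(ev8$end_week)))

  ev11 <- builtin_scenario(11)$events
  expect_equal(ev11$kind, "ABIO")
  expect_equal(ev11$start_week, 12)

  # the literature high-fat groups start the diet at week 8
  expect_equal(builtin_scenario(3)$events$start_week, 8)
  expect_equal(builtin_scenario(5)$events$start_week, 8)
  expect_equal(builtin_scenario(4)$events$start_week, 16)

  expect_error(builtin_scenario(14), "between 1 and 13")
  expect_error(builtin_scenario(0), "between 1 and 13")
})

test_that("d_in is constant 1 when all factors are 1 (intervention-free limit)", {
  unit <- athero_factors(d_HFD = 1, d_ABIO = 1, d_Immod = 1, d_PA = 1)
  grid <- seq(0, 400, by = 1)
  for (id in 1:13) {
    din <- build_din(builtin_scenario(id), unit)
    expect_true(all(din_value(din, grid) == 1), label = paste("scenario", id))
  }
})

test_that("d_in multiplies the factors of concurrently active interventions", {
  fc <- athero_factors(d_HFD = 2.5, d_ABIO = 3, d_Immod = 2, d_PA = 0.5)

  din3 <- build_din(builtin_scenario(3), fc)
  expect_equal(din_value(din3, 6 * 7), 1)
  expect_equal(din_value(din3, 10 * 7), 2.5)

  din8 <- build_din(builtin_scenario(8), fc)
  expect_equal(din_value(din8, 20 * 7), 2.5 * 3 * 0.5)
  expect_equal(din_value(din8, 13 * 7), 3)          # only antibiotics yet
  expect_equal(din_value(din8, 17 * 7), 3 * 2.5)    # + diet

  # scenario 1 is the normal-diet reference: d_in = 1 throughout
  expect_equal(din_value(build_din(builtin_scenario(1), fc), c(0, 100, 700)),
               rep(1, 3))
})

test_that("d_in has no spurious breakpoints", {
  fc <- athero_factors(d_HFD = 2.5, d_ABIO = 3, d_Immod = 2, d_PA = 0.5)
  din8 <- build_din(builtin_scenario(8), fc)
  # three distinct onsets -> four distinct active-event subsets over time
  expect_equal(length(din8$breaks), 3)
  expect_equal(length(unique(din8$values)), 4)
  din1 <- build_din(builtin_scenario(1), fc)
  expect_equal(length(din1$breaks), 0)
})

test_that("scenario 9 equals scenario 10 times the propionate step", {
  fc <- athero_factors(d_HFD = 2.2, d_ABIO = 3, d_Immod = 1.8, d_PA = 0.6)
  din9 <- build_din(builtin_scenario(9), fc)
  din10 <- build_din(builtin_scenario(10), fc)
  pa_step <- step_function(18 * 7, c(1, fc$d_PA))
  grid <- seq(0, 300, by = 0.5)
  expect_equal(din_value(din9, grid),
               din_value(din10, grid) * din_value(pa_step, grid))
})

test_that("step functions are right-continuous at breakpoints", {
  fn <- step_function(112, c(1, 2.5))
  expect_equal(din_value(fn, 111.9), 1)
  expect_equal(din_value(fn, 112), 2.5)   # post-change value at the break
  expect_equal(din_value(fn, 112.1), 2.5)
  expect_equal(din_value(step_function(numeric(), 1), c(0, 5, 1e4)),
               rep(1, 3))
  expect_error(step_function(c(5, 3), c(1, 2, 3)), "increasing")
  expect_error(step_function(5, c(1, -2)), "positive")
  expect_error(step_function(5, 1), "one more value")
})

test_that("finite treatment windows and the six-week antibiotics reading work", {
  fc <- athero_factors(d_HFD = 2, d_ABIO = 3, d_Immod = 2, d_PA = 0.5)
  sc <- scenario(data.frame(kind = "HFD", start_week = 16, end_week = 56))
  din <- build_din(sc, fc)
  expect_equal(din_value(din, c(15, 20, 55.9, 56, 60) * 7),
               c(1, 2, 2, 1, 1))

  din11 <- build_din(builtin_scenario(11, abio_weeks = 6), fc)
  expect_equal(din_value(din11, c(11, 13, 18, 19) * 7), c(1, 3, 1, 1))
})

test_that("invalid scenarios are rejected", {
  expect_error(scenario(data.frame(kind = "XYZ", start_week = 1,
                                   end_week = 2)), "unknown intervention")
  expect_error(scenario(data.frame(kind = "HFD", start_week = 5,
                                   end_week = 5)), "exceed")
  ov <- data.frame(kind = c("HFD", "HFD"), start_week = c(10, 12),
                   end_week = c(14, Inf))
  expect_error(build_din(scenario(ov), athero_factors()), "overlapping")
})
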