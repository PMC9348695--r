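# a zero-generation "fit" pinned at given parameters: the cheapest way to
# obtain a completed athero_fit at a known optimum
fit_at <- function(data, free = c("b", "k_LDL"), gens = 0, seed = 1,
                   params = ref_params, factors = ref_factors) {
  cfg <- fit_config(free = free, max_generations = gens, stagnation = gens + 1,
                    fit_rtol = 1e-6, fit_atol = 1e-8,
                    final_rtol = 1e-8, final_atol = 1e-10)
  fit_evolutionary(data, init_params = params, init_factors = factors,
                   config = cfg, seed = seed)
}

test_that("zero-spread data give degenerate bootstrap intervals", {
  dat <- toy_data(cv = 0)   # all sd = 0, model passes through every mean
  fit <- fit_at(dat)
  boot <- bootstrap_ci(fit, dat, n_reps = 6, seed = 3,
                       refit_config = fit$config)
  expect_equal(boot$intervals$lower, boot$intervals$estimate,
               tolerance = 1e-12)
  expect_equal(boot$intervals$upper, boot$intervals$estimate,
               tolerance = 1e-12)
  expect_equal(boot$n_failed, 0L)
})

test_that("bootstrap replicates are reproducible given the master seed", {
  dat <- toy_data(cv = 0.1, seed = 21)
  fit <- fit_at(dat)
  cfg <- fit_config(free = c("b", "k_LDL"), max_generations = 5,
                    stagnation = 10, fit_rtol = 1e-6, fit_atol = 1e-8)
  b1 <- bootstrap_ci(fit, dat, n_reps = 4, seed = 7, refit_config = cfg)
  b2 <- bootstrap_ci(fit, dat, n_reps = 4, seed = 7, refit_config = cfg)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(tidy(b1), tidy(b2))
})

test_that("doubling the data spread widens bootstrap intervals", {
  dat <- toy_data(cv = 0.05, seed = 31)
  wide <- dat; wide$sd <- 2 * dat$sd
  fit_n <- fit_at(dat)
  fit_w <- fit_at(wide)
  cfg <- fit_config(free = c("b", "k_LDL"), max_generations = 25,
                    stagnation = 30, sigma0 = 0.05,
                    fit_rtol = 1e-6, fit_atol = 1e-8)
  bn <- bootstrap_ci(fit_n, dat, n_reps = 20, seed = 5, refit_config = cfg)
  bw <- bootstrap_ci(fit_w, wide, n_reps = 20, seed = 5, refit_config = cfg)
  width <- function(b) mean(b$intervals$upper - b$intervals$lower)
  expect_gt(width(bw), width(bn))
})

test_that("a factor absent from all fitted scenarios has zero sensitivity", {
  dat <- toy_data(cv = 0.1, seed = 41)   # scenarios 1 and 4: no antibiotics
  fit <- fit_at(dat, free = c("b", "d_ABIO"))
  sens <- sensitivity(fit, dat, delta = 0.01, rtol = 1e-8, atol = 1e-10)
  ab <- sens[sens$parameter == "d_ABIO", ]
  expect_equal(ab$deterioration_plus, 0, tolerance = 1e-8)
  expect_equal(ab$deterioration_minus, 0, tolerance = 1e-8)
  expect_false(any(is.na(sens$fitness_plus)))
})

test_that("at an exact optimum every 1% perturbation deteriorates the fit", {
  dat <- toy_data(cv = 0)   # the generating truth has fitness 0
  fit <- fit_at(dat, free = c("b", "k_LDL", "d_HFD"))
  sens <- sensitivity(fit, dat, delta = 0.01, rtol = 1e-8, atol = 1e-10)
  expect_true(all(sens$deterioration_plus >= -1e-8))
  expect_true(all(sens$deterioration_minus >= -1e-8))
  expect_true(any(sens$deterioration_plus > 0))
  expect_equal(attr(sens, "fitness_optimum"), 0, tolerance = 1e-8)
})

test_that("sensitivity vanishes continuously as delta shrinks", {
  dat <- toy_data(cv = 0)
  fit <- fit_at(dat, free = "b")
  det <- vapply(c(1e-2, 1e-3, 1e-4), function(d) {
    s <- sensitivity(fit, dat, delta = d, rtol = 1e-8, atol = 1e-10)
    max(abs(c(s$deterioration_plus, s$deterioration_minus)))
  }, numeric(1))
  expect_true(all(diff(det) < 0))
  expect_lt(det[3], 1e-3 * det[1])
})

test_that("1% deteriorations match a quadratic finite-difference estimate", {
  dat <- toy_data(cv = 0)
  fit <- fit_at(dat, free = "b")
  delta <- 0.01
  s <- sensitivity(fit, dat, delta = delta, rtol = 1e-8, atol = 1e-10)
  # near a zero-residual optimum: det(+) + det(-) = delta^2 p^2 f''(p)
  second_diff <- s$deterioration_plus + s$deterioration_minus
  # independent three-point stencil at half the step predicts 1/4 the size
  s2 <- sensitivity(fit, dat, delta = delta / 2, rtol = 1e-8, atol = 1e-10)
  ratio <- (s2$deterioration_plus + s2$deterioration_minus) / second_diff
  expect_equal(ratio, 0.25, tolerance = 0.1)
})

test_that("bootstrap input contracts are enforced", {
  dat <- toy_data(cv = 0.1)
  fit <- fit_at(dat)
  expect_error(bootstrap_ci(fit, dat, n_reps = 0), "n_reps")
  expect_error(bootstrap_ci(fit, dat, n_reps = 5, level = 1.2), "level")
  expect_error(sensitivity(fit, dat, delta = 0), "positive")
})
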