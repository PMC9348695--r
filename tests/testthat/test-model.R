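test_that("the lesion-free state is an exact equilibrium of the rates", {
  p <- athero_params()
  s <- c(MONO_B = 1, MONO = 0, IM = 0, L = 0, F = 0, L_B = 1, R = 1)
  expect_equal(unname(athero_derivatives(s, p, din = 1)), rep(0, 7))

  # with a different uptake the blood-LDL baseline shifts to din / d_L_B
  s2 <- s; s2[["L_B"]] <- 2.5
  expect_equal(unname(athero_derivatives(s2, p, din = 2.5)), rep(0, 7))
})

test_that("dR vanishes identically at R = 1", {
  p <- athero_params()
  set.seed(42)
  for (i in 1:10) {
    s <- c(MONO_B = runif(1, 0, 2), MONO = runif(1, 0, 2),
           IM = runif(1, 0, 2), L = runif(1, 0, 2), F = runif(1, 0, 2),
           L_B = runif(1, 0, 2), R = 1)
    expect_equal(athero_derivatives(s, p, 1)[["R"]], 0)
  }
})

test_that("macrophage balance follows differentiation minus foam conversion", {
  # c * MONO - b * IM * L with c = 0.5, b = 0.1, MONO = 2, IM = 3, L = 4
  p <- athero_params(c = 0.5, b = 0.1)
  s <- c(MONO_B = 1, MONO = 2, IM = 3, L = 4, F = 0, L_B = 1, R = 0.95)
  expect_equal(athero_derivatives(s, p, 1)[["IM"]], 0.5 * 2 - 0.1 * 3 * 4)
})

test_that("radius reduction opposes foam-cell growth below R = 1", {
  p <- athero_params()
  set.seed(7)
  for (i in 1:20) {
    s <- c(MONO_B = 1, MONO = runif(1, 0, 2), IM = runif(1, 0, 2),
           L = runif(1, 0, 2), F = runif(1, 0, 2), L_B = 1,
           R = runif(1, 0.3, 0.999))
    r <- athero_derivatives(s, p, 1)
    if (r[["F"]] >= 0) expect_lte(r[["R"]], 0)
  }
})

test_that("derivative evaluation rejects invalid states and inputs", {
  p <- athero_params()
  s <- c(MONO_B = 1, MONO = 0, IM = 0, L = 0, F = 0, L_B = 1, R = 1)
  bad <- s; bad[["MONO"]] <- -0.1
  expect_error(athero_derivatives(bad, p, 1), "non-negative")
  bad <- s; bad[["R"]] <- 0
  expect_error(athero_derivatives(bad, p, 1), "occlusion|positive")
  expect_error(athero_derivatives(s, p, din = 0), "positive")
  expect_error(athero_derivatives(s[-1], p, 1), "components")
})

test_that("lesion area fraction is 1 - R^2 with its domain checks", {
  expect_equal(lesion_area_fraction(1), 0)
  expect_equal(lesion_area_fraction(0.9996), 1 - 0.9996^2)
  expect_equal(lesion_area_fraction(0.9996), 7.998e-4, tolerance = 1e-4)
  # the inverse: 49% lesion corresponds to R = sqrt(0.51)
  expect_equal(lesion_area_fraction(sqrt(0.51)), 0.49)
  # monotone decreasing in R
  r <- seq(0.2, 1, by = 0.05)
  expect_true(all(diff(lesion_area_fraction(r)) < 0))
  expect_error(lesion_area_fraction(1.01), "R must")
  expect_error(lesion_area_fraction(0), "R must")
})

test_that("observables are denormalized states and a lesion percentage", {
  p <- athero_params(L_B_nor = 120, MONO_B_nor = 77)
  s <- c(MONO_B = 1, MONO = 0, IM = 0, L = 0, F = 0, L_B = 1, R = 0.9996)
  obs <- to_observables(s, p)
  expect_equal(obs$LDL_blood, 120)
  expect_equal(obs$MONO_blood, 77)
  expect_equal(obs$lesion_area_pct, 100 * (1 - 0.9996^2))
  expect_equal(obs$lesion_area_pct, 0.080, tolerance = 1e-3)
})

test_that("parameter validation enforces signs and ranges", {
  expect_error(athero_params(b = -1), "non-negative")
  expect_error(athero_params(R0 = 0), "R0")
  expect_error(athero_params(R0 = 1.2), "R0")
  expect_error(athero_params(L_B_nor = -5), "positive")
  expect_silent(athero_params(R0 = 1))
  expect_error(athero_factors(d_PA = 0), "positive")
})

test_that("parameter files round-trip and reject unknown keys", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  p <- athero_params(a = 1.23456789, R0 = 0.9987)
  fc <- athero_factors(d_HFD = 3.21)
  write_params(p, tmp, factors = fc)
  back <- read_params(tmp)
  expect_equal(unclass(back$params), unclass(p))
  expect_equal(unclass(back$factors), unclass(fc))

  writeLines("a: 1\nnot_a_parameter: 2", tmp)
  expect_error(read_params(tmp), "unknown parameter keys")

  # missing normalization-fixed rates fall back to 1, missing kinetics fail
  writeLines(c("a: 1", "alpha: 1", "epsilon: 1", "c: 1", "b: 1",
               "k_LDL: 1", "f: 1", "e: 1", "d_LDL: 1", "d_F: 1", "xi: 1",
               "R0: 0.99", "MONO_B_nor: 10", "L_B_nor: 10"), tmp)
  got <- read_params(tmp)
  expect_equal(got$params$k_MONO, 1)
  expect_equal(got$params$d_L_B, 1)
  expect_equal(got$params$init_F, 0)
  expect_null(got$factors)

  writeLines("a: 1", tmp)
  expect_error(read_params(tmp), "missing required keys")

  # a partial factor set is ambiguous
  writeLines(c("d_HFD: 2"), tmp)
  expect_error(read_params(tmp), "all four or none")
})

test_that("the bundled reference parameter file matches the defaults", {
  ref <- reference_params()
  expect_equal(unclass(ref$params), unclass(athero_params()))
  expect_equal(unclass(ref$factors), unclass(athero_factors()))
})
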