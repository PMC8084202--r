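test_that("timescale and branching parameter convert exactly", {
  expect_equal(tau_from_m(0.98, 1), -1 / log(0.98))
  expect_equal(round(tau_from_m(0.98, 1), 1), 49.5)
  expect_equal(tau_from_m(exp(-1), 1), 1)
  expect_equal(tau_from_m(0.5, 2), 2 / log(2))
  expect_equal(m_from_tau(tau_from_m(0.98, 1), 1), 0.98)
  expect_equal(m_from_tau(49.5, 1), 0.98, tolerance = 1e-4)
  # monotone approach of the critical point
  expect_true(all(diff(m_from_tau(c(10, 100, 1e4, 1e8), 1)) > 0))
  expect_true(all(m_from_tau(c(10, 1e8), 1) < 1))
  expect_error(tau_from_m(1, 1), "0, 1")
  expect_error(tau_from_m(-0.1, 1))
  expect_error(m_from_tau(0, 1), "> 0")
})

test_that("fit functions evaluate to their closed forms", {
  expect_equal(evaluate_fitfunc("exp", 49.5, c(tau = 49.5, A = 1)), exp(-1))
  expect_equal(evaluate_fitfunc("eo", c(0, 10, 1e6),
                                c(tau = 5, A = 0, O = 0.3)),
               rep(0.3, 3))
  p <- c(tau = 50, D = 0.4, O = 0.05, tau_osc = 100, E = 0.2, gamma = 1.5,
         nu = 0.07, tau_gauss = 8, F = 0.1)
  expect_equal(evaluate_fitfunc("complex", 0, p),
               sum(p[c("D", "E", "F", "O")]))
  expect_error(evaluate_fitfunc("exp", 1, c(tau = 5)), "missing parameter")
  expect_error(fitfunc_spec("gaussian"), "unknown fit function")
  # abbreviation map
  for (lab in c("e", "exp", "exponential")) {
    expect_identical(fitfunc_spec(lab)$name, "exponential")
  }
  for (lab in c("eo", "exp_offset", "exp_off", "exponential_offset")) {
    expect_identical(fitfunc_spec(lab)$name, "exponential_offset")
  }
  for (lab in c("c", "cplx", "complex")) {
    expect_identical(fitfunc_spec(lab)$name, "complex")
  }
})

test_that("noiseless model data is recovered to optimizer precision", {
  k <- 1:500
  co <- make_coeffs(k, 0.5 * exp(-k / 100))
  ft <- fit(co, fitfunc = "exponential")
  expect_lt(rel_err(ft$tau, 100), 1e-6)
  expect_lt(rel_err(ft$params[["A"]], 0.5), 1e-6)

  co2 <- make_coeffs(k, 0.3 * exp(-k / 50) + 0.01)
  ft2 <- fit(co2, fitfunc = "exponential_offset")
  expect_lt(rel_err(ft2$tau, 50), 1e-6)
  expect_lt(rel_err(ft2$params[["A"]], 0.3), 1e-6)
  expect_lt(rel_err(ft2$params[["O"]], 0.01), 1e-6)

  truth <- c(tau = 60, D = 0.4, O = 0.02, tau_osc = 150, E = 0.25, gamma = 1,
             nu = 0.05, tau_gauss = 10, F = 0.1)
  co3 <- make_coeffs(k, evaluate_fitfunc("complex", k, truth))
  ft3 <- fit(co3, fitfunc = "complex")
  expect_lt(rel_err(ft3$tau, truth[["tau"]]), 1e-6)
  for (nm in names(truth)) {
    expect_lt(rel_err(ft3$params[[nm]], truth[[nm]]), 1e-6)
  }
})

test_that("derived quantities and nesting behave as the models demand", {
  bp <- simulate_branching(m = 0.95, a = 300, length = 4000, numtrials = 6,
                           seed = 21)
  rk <- coefficients(bp, steps = c(1, 100), method = "sm", numboot = 0)
  fe <- fit(rk, "exponential")
  feo <- fit(rk, "exponential_offset")
  expect_equal(fe$mre, m_from_tau(fe$tau, 1))
  expect_gt(fe$tau, 0)
  expect_true(fe$mre > 0 && fe$mre < 1)
  # the offset model nests the plain exponential
  expect_lte(feo$ssres, fe$ssres + 1e-12)
})

test_that("an oscillatory component breaks the plain exponential but not the complex fit", {
  k <- 1:400
  r <- 0.5 * exp(-k / 50) + 0.25 * exp(-k / 200) * cos(2 * pi * 0.05 * k)
  co <- make_coeffs(k, r)
  plain <- fit(co, "exponential_offset")
  cplx <- fit(co, "complex")
  expect_lt(rel_err(cplx$tau, 50), 0.05)
  expect_lt(rel_err(cplx$params[["nu"]], 0.05), 0.05)
  expect_gt(rel_err(plain$tau, 50), rel_err(cplx$tau, 50))
  expect_lt(cplx$ssres, plain$ssres)
})

test_that("growing coefficients trigger the supercritical diagnostic", {
  k <- 1:60
  co <- make_coeffs(k, 1.02^k)
  expect_warning(ft <- fit(co, "exponential"), "supercritical")
  expect_true(is.na(ft$tau))
  expect_gt(ft$mre, 1)
  expect_lt(rel_err(ft$mre, 1.02), 1e-3)
  expect_identical(ft$flags, "supercritical")
})

test_that("fitrange subsets the coefficients before fitting", {
  k <- 1:200
  co <- make_coeffs(k, 0.4 * exp(-k / 30) + 0.005)
  full <- fit(co, "eo")
  sub <- fit(co, "eo", fitrange = c(1, 100))
  expect_identical(range(sub$fitrange), c(1L, 100L))
  expect_lt(rel_err(sub$tau, 30), 1e-6)
  expect_lt(rel_err(full$tau, 30), 1e-6)
  expect_error(fit(co, "eo", fitrange = c(500, 600)), "no steps")
  expect_error(fit(co, "eo", fitrange = c(3, 7, 300)), "subset")
})

test_that("bootstrap CIs cover the point estimate and respect the level", {
  bp <- simulate_branching(m = 0.9, a = 200, length = 2000, numtrials = 10,
                           seed = 71)
  rk <- coefficients(bp, steps = c(1, 40), method = "ts", numboot = 60,
                     seed = 72)
  ft <- fit(rk, "exponential_offset")
  expect_false(is.null(ft$tau_ci))
  expect_lte(ft$tau_ci[["lower"]], ft$tau_ci[["upper"]])
  expect_true(ft$tau >= ft$tau_ci[["lower"]] - 1 &&
                ft$tau <= ft$tau_ci[["upper"]] + 1)
  # m CI maps monotonically from the tau CI (up to quantile interpolation)
  expect_equal(unname(ft$mre_ci),
               unname(m_from_tau(ft$tau_ci, rk$dt)), tolerance = 1e-3)
  td <- tidy(ft)
  expect_true(all(c("ci_lower", "ci_upper") %in% names(td)))
  expect_identical(td$term[1], "tau")
})
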