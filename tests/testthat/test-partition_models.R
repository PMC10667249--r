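test_that("rectangular hyperbola evaluates exactly and saturates at GPmax", {
  expect_equal(predict_gep(0, -0.02, -15), 0)
  expect_equal(predict_gep(500, -0.02, -15), -6)   # 150 / -25
  expect_equal(predict_gep(1e6, -0.02, -15), -15, tolerance = 1e-3)
  expect_error(predict_gep(500, 0.03, -15), "pole")
  expect_error(predict_gep(-1, -0.02, -15), "non-negative")
})

test_that("light response is monotone non-increasing and bounded by GPmax", {
  par <- seq(0, 3000, by = 10)
  g <- predict_gep(par, -0.03, -20)
  expect_true(all(diff(g) <= 0))
  expect_true(all(abs(g) < 20))
})

test_that("light-response fitting recovers noise-free truth to 1e-6", {
  obs <- gep_truth_obs(c(0, 200, 600, 1200, 1800), Q = -0.03, GPmax = -20)
  f <- fit_light_response(obs$par_umol_m2_s, obs$gep)
  expect_true(f$ok)
  expect_equal(f$Q, -0.03, tolerance = 1e-6)
  expect_equal(f$GPmax, -20, tolerance = 1e-6)
})

test_that("degenerate light-response data yields a fit-failure signal", {
  obs <- gep_truth_obs(rep(500, 6), Q = -0.03, GPmax = -20)
  expect_false(fit_light_response(obs$par_umol_m2_s, obs$gep)$ok)
  expect_false(fit_light_response(c(100, 600), c(-2, -8))$ok)   # too few points
})

test_that("period partition selection prefers the simplest adequate model", {
  set.seed(11)
  times <- season_times(c("06-01", "06-12", "06-25", "07-05", "07-15", "07-28",
                          "08-08", "08-20", "09-01"))
  par_levels <- c(300, 800, 1500)
  tt <- rep(times, each = 3)
  pp <- rep(par_levels, times = length(times))

  # identical parameters all season -> whole-season partition wins
  obs <- gep_truth_obs(pp, Q = -0.03, GPmax = -20, times = tt)
  obs$gep <- obs$gep + rnorm(nrow(obs), 0, 0.3)
  sel <- choose_period_partition(obs)
  expect_equal(sel$partition, "whole")
  expect_length(sel$fits, 1)

  # GPmax doubled in July, low noise -> the partition isolating July wins
  gp <- ifelse(format(tt, "%m") == "07", -40, -20)
  obs2 <- data.frame(time = tt, par_umol_m2_s = pp,
                     gep = pp * -0.03 * gp / (pp * -0.03 + gp) +
                       rnorm(length(pp), 0, 0.1))
  sel2 <- choose_period_partition(obs2)
  expect_equal(sel2$partition, "three")
  expect_equal(sel2$fits$mid$GPmax, -40, tolerance = 0.1)
})

test_that("sparse seasons force the whole-season partition", {
  # one campaign per period: no per-period part can meet the 4-point minimum
  times <- season_times(c("06-05", "07-10", "08-20"))
  tt <- rep(times, each = 2)
  pp <- c(300, 1500, 800, 400, 1500, 900)
  obs <- gep_truth_obs(pp, Q = -0.03, GPmax = -20, times = tt)
  sel <- choose_period_partition(obs)
  expect_equal(sel$partition, "whole")
  expect_named(sel$scores, "whole")   # the only feasible candidate
})

test_that("respiration prediction matches hand evaluation of both forms", {
  expfit <- list(form = "exponential", coeffs = c(ERref = 5, E0 = 300),
                 t_ref_C = 10.35, t0_C = -35.67)
  # at the reference temperature the bracket vanishes
  expect_equal(predict_er(expfit, 10.35), 5, tolerance = 1e-12)
  # Kelvin evaluation: 5 * exp(300 * (1/46.02 - 1/55.67))
  expect_equal(predict_er(expfit, 20), 5 * exp(300 * (1 / 46.02 - 1 / 55.67)),
               tolerance = 1e-12)
  expect_equal(predict_er(expfit, 20), 15.478, tolerance = 1e-3)
  expect_error(predict_er(expfit, -40), "biological")

  linfit <- list(form = "linear", temp_source = "Tair", uses_wtl = TRUE,
                 coeffs = c(a = 0.5, b = -0.1, c = 1))
  expect_equal(predict_er(linfit, 10, wtl_cm = -20), 8)
  # with the WTL term unused, b is ignored
  linfit$uses_wtl <- FALSE
  expect_equal(predict_er(linfit, 10, wtl_cm = -20), 6)
})

test_that("exponential respiration increases with air temperature", {
  fit <- list(form = "exponential", coeffs = c(ERref = 4, E0 = 250),
              t_ref_C = 10.35, t0_C = -35.67)
  t <- seq(-30, 35, by = 1)
  expect_true(all(diff(predict_er(fit, t)) > 0))
})

test_that("respiration model selection recovers noise-free generating forms", {
  tair <- c(6, 9, 12, 15, 18, 21, 24, 14, 17, 11)
  t5 <- tair - 2
  wtl <- c(-20, -15, -5, 0, 5, 10, -10, 3, -2, 8)

  # exponential truth -> exponential selected, parameters recovered
  er1 <- data.frame(er = er_exp_truth(tair, 6, 250), air_temp_C = tair,
                    soil_temp5_C = t5, wtl_cm = wtl)
  f1 <- fit_er(er1)
  expect_equal(f1$form, "exponential")
  expect_equal(unname(f1$coeffs[["ERref"]]), 6, tolerance = 1e-6)
  expect_equal(unname(f1$coeffs[["E0"]]), 250, tolerance = 1e-6)

  # linear truth with a WTL effect -> linear + WTL selected, coefficients exact
  er2 <- data.frame(er = 0.4 * tair - 0.2 * wtl + 1.5, air_temp_C = tair,
                    soil_temp5_C = t5, wtl_cm = wtl)
  f2 <- fit_er(er2)
  expect_equal(f2$form, "linear")
  expect_true(f2$uses_wtl)
  expect_equal(unname(f2$coeffs[c("a", "b", "c")]), c(0.4, -0.2, 1.5),
               tolerance = 1e-8)

  # too few observations -> unfittable
  expect_null(fit_er(er1[1:4, ]))
})

test_that("model fitting is deterministic for identical inputs", {
  set.seed(3)
  par <- rep(c(100, 400, 900, 1600), 3)
  gep <- predict_gep(par, -0.04, -25) + rnorm(length(par), 0, 0.5)
  f1 <- fit_light_response(par, gep)
  f2 <- fit_light_response(par, gep)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$GPmax, f2$GPmax)
})
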