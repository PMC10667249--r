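test_that("OLS slope and r2 match the closed-form least-squares formulas", {
  # exact line
  f <- fit_slope(c(0, 60, 120), c(400, 406, 412))
  expect_equal(f$slope_ppm_per_s, 0.1)
  expect_equal(f$r2, 1)

  # constant series: slope 0 and r2 defined as 0
  f0 <- fit_slope(c(0, 60, 120), c(400, 400, 400))
  expect_equal(f0$slope_ppm_per_s, 0)
  expect_equal(f0$r2, 0)

  # two readings: r2 reported as 1 by construction
  expect_equal(fit_slope(c(0, 60), c(400, 401))$r2, 1)

  # 5-point methane series against the closed-form OLS oracle
  x <- c(0, 420, 900, 1500, 2100)
  y <- c(2.0, 2.4, 2.9, 3.5, 4.2)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  f5 <- fit_slope(x, y)
  expect_equal(f5$slope_ppm_per_s, sxy / sxx, tolerance = 1e-12)
  expect_equal(f5$r2, sxy^2 / (sxx * syy), tolerance = 1e-12)
})

test_that("malformed chamber runs are rejected with errors", {
  expect_error(fit_slope(0, 400), "at least 2")
  expect_error(fit_slope(c(0, 60, 60), c(1, 2, 3)), "strictly increasing")
  expect_error(fit_slope(c(0, 60), c(400, -1)), "positive")
  expect_error(slope_to_flux(0.1, 20, 0, "CO2"), "positive")
  expect_error(slope_to_flux(0.1, -300, 0.3, "CO2"), "absolute zero")
})

test_that("slope-to-flux follows the ideal-gas conversion and is linear", {
  # oracle: molar density times height times molar mass times seconds per day
  expect_equal(slope_to_flux(0.1, 20, 0.30, "CO2"),
               0.1e-6 * 101325 / (8.314462618 * 293.15) * 0.30 * 44 * 86400,
               tolerance = 1e-12)
  expect_equal(slope_to_flux(0.1, 20, 0.30, "CO2"), 4.74, tolerance = 2e-3)
  expect_equal(slope_to_flux(0, 20, 0.30, "CO2"), 0)
  # linear in slope and in height; sign preserved
  expect_equal(slope_to_flux(0.2, 20, 0.30, "CO2"),
               2 * slope_to_flux(0.1, 20, 0.30, "CO2"))
  expect_equal(slope_to_flux(0.1, 20, 0.60, "CO2"),
               2 * slope_to_flux(0.1, 20, 0.30, "CO2"))
  expect_lt(slope_to_flux(-0.1, 20, 0.30, "CH4"), 0)
  # molar mass ratio CH4 : CO2 = 16 : 44
  expect_equal(slope_to_flux(0.1, 20, 0.30, "CH4") /
                 slope_to_flux(0.1, 20, 0.30, "CO2"), 16 / 44)
})

test_that("QC rules classify boundary cases exactly as the protocol states", {
  # CO2: zero rule takes precedence over the linearity rule
  expect_equal(qc_co2(1.5, 0.30), "zero")
  expect_equal(qc_co2(25, 0.70), "rejected_nonlinear")
  expect_equal(qc_co2(25, 0.90), "accepted")
  expect_equal(qc_co2(2.0, 0.90), "accepted")     # exactly 2 ppm is NOT zero
  expect_equal(qc_co2(25, 0.75), "rejected_nonlinear")  # exactly 0.75 rejected
  expect_equal(qc_co2(25, 0.7500001), "accepted")

  # CH4
  expect_equal(qc_ch4(0.4, 0.99), "zero")
  expect_equal(qc_ch4(0.5, 0.10), "zero")         # exactly 0.5 ppm IS zero
  expect_equal(qc_ch4(3, 0.55), "rejected_ebullition")
  expect_equal(qc_ch4(3, 0.60), "accepted")       # exactly 0.60 accepted
  expect_equal(qc_ch4(3, 0.95), "accepted")
})

test_that("zero-classified runs yield flux exactly 0 through compute_fluxes", {
  mk_run <- function(id, gas, conc) data.frame(
    collar_id = id, gas = gas, start_time = "2016-06-10 12:00:00",
    elapsed_s = seq_along(conc) * 15, conc_ppm = conc, air_temp_C = 15,
    par_umol_m2_s = 0, chamber_height_m = 0.3, collar_area_m2 = 0.36,
    headspace_adjust_m = 0.05)
  runs <- rbind(mk_run("A", "CO2", 400 + c(0, 0.4, 0.9, 1.3, 0.2, 0.7)),
                mk_run("B", "CH4", 2 + c(0, 0.1, 0.35, 0.2)))
  fx <- compute_fluxes(runs)
  expect_equal(fx$qc, c("zero", "zero"))
  expect_equal(fx$flux_g_m2_d, c(0, 0))
})

test_that("NEE/ER partitioning subtracts the dark flux per campaign", {
  camp <- rbind(flux_row(flux = 4, par = 0),
                flux_row(flux = -2, par = 250),
                flux_row(flux = -6, par = 700),
                flux_row(flux = -9, par = 1400))
  p <- partition_nee_er(camp)
  expect_equal(attr(p, "er"), 4)
  expect_false(attr(p, "flagged"))
  expect_equal(p$gep, c(-6, -10, -13))
  # GEP at PAR = 0 would be 0 by definition: NEE(-5) - ER(8) = -13 check
  p2 <- partition_nee_er(rbind(flux_row(flux = 8, par = 0),
                               flux_row(flux = -5, par = 1000)))
  expect_equal(p2$gep, -13)
})

test_that("a campaign without a usable dark run is flagged: NEE only, no GEP", {
  camp <- rbind(flux_row(flux = 4, par = 0, qc = "rejected_nonlinear"),
                flux_row(flux = -5, par = 1000))
  p <- partition_nee_er(camp)
  expect_true(attr(p, "flagged"))
  expect_equal(p$nee, -5)
  expect_true(is.na(p$gep))
})

test_that("mean recovered flux over repeated noisy runs is unbiased", {
  set.seed(7)
  cfg <- sim_config(ebullition_prob = 0)
  truths <- default_collar_truths(cfg)
  collar <- truths[truths$cover_type == "herbaceous", ][1, ]
  truth <- collar$truth[[1]]
  drow <- data.frame(par_umol_m2_s = 1200, air_temp_C = 18,
                     soil_temp5_C = 14, wtl_cm = 0)
  fluxes <- replicate(200, {
    r <- gen_chamber_run(truth, collar, as.POSIXct("2016-07-01 12:00:00", tz = "UTC"),
                         drow, "CO2", 1, cfg)
    sl <- fit_slope(r$elapsed_s, r$conc_ppm)
    slope_to_flux(sl$slope_ppm_per_s, 18, 0.35, "CO2")
  })
  true_flux <- gep_truth_flux(truth, 1200) +
    er_truth_flux(truth, 18, 14, truth$wtl_offset_cm)
  se <- sd(fluxes) / sqrt(length(fluxes))
  expect_lt(abs(mean(fluxes) - true_flux), 2 * se)
})
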