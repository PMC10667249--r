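# Shared fixtures built in code.

# One fabricated QC-labelled flux row, as produced by compute_fluxes().
flux_row <- function(collar_id = "C1", gas = "CO2", time = "2016-06-10 12:00:00",
                     flux = 1, qc = "accepted", par = 0, tair = 15,
                     t5 = 12, wtl = 0, r2 = 0.95) {
  data.frame(collar_id = collar_id, gas = gas,
             time = as.POSIXct(time, tz = "UTC"),
             slope_ppm_per_s = NA_real_, r2 = r2, conc_range_ppm = NA_real_,
             n_readings = 13L, flux_g_m2_d = flux, qc = qc,
             par_umol_m2_s = par, air_temp_C = tair,
             date = as.Date(substr(time, 1, 10)),
             soil_temp5_C = t5, wtl_cm = wtl, stringsAsFactors = FALSE)
}

# Noise-free GEP observations from rectangular-hyperbola truth.
gep_truth_obs <- function(par, Q, GPmax, times = NULL) {
  data.frame(time = if (is.null(times))
    rep(as.POSIXct("2016-06-15 12:00:00", tz = "UTC"), length(par)) else times,
    par_umol_m2_s = par,
    gep = par * Q * GPmax / (par * Q + GPmax))
}

# Lloyd-Taylor-type truth evaluated in Kelvin with the package constants.
er_exp_truth <- function(tair_C, ERref, E0, t_ref_C = 10.35, t0_C = -35.67) {
  ERref * exp(E0 * (1 / (t_ref_C - t0_C) - 1 / (tair_C + 273.15 - (t0_C + 273.15))))
}

# Campaign times spread over the default season, one per listed month-day.
season_times <- function(days) {
  as.POSIXct(paste0("2016-", days, " 12:00:00"), tz = "UTC")
}
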