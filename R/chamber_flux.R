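#' Ordinary least-squares slope of a chamber concentration series
#'
#' The static-chamber flux is derived from the linear change in headspace
#' concentration over the deployment. This fits concentration (ppm) against
#' elapsed time (s) by OLS and reports the slope and the coefficient of
#' determination of that line.
#'
#' @param elapsed_s numeric vector of elapsed seconds, strictly increasing.
#' @param conc_ppm numeric vector of concentrations (ppm), all positive.
#' @return list with `slope_ppm_per_s`, `r2`, `conc_range_ppm` (max - min) and
#'   `n`. With exactly two readings `r2` is 1 by construction; for a constant
#'   series (zero variance in concentration) `r2` is defined as 0 — such runs
#'   are classified as zero flux by the range rule anyway.
#' @examples
#' fit_slope(c(0, 60, 120), c(400, 406, 412))  # slope 0.1 ppm/s, r2 = 1
#' @export
fit_slope <- function(elapsed_s, conc_ppm) {
  if (length(elapsed_s) != length(conc_ppm))
    stop("elapsed_s and conc_ppm must have the same length")
  if (length(elapsed_s) < 2)
    stop("a chamber run needs at least 2 readings")
  if (anyNA(elapsed_s) || anyNA(conc_ppm))
    stop("chamber readings must not contain NA")
  if (any(diff(elapsed_s) <= 0))
    stop("elapsed times must be strictly increasing")
  if (any(conc_ppm <= 0))
    stop("concentrations must be positive")

  fit <- stats::lm(conc_ppm ~ elapsed_s)
  slope <- unname(stats::coef(fit)[2])
  syy <- sum((conc_ppm - mean(conc_ppm))^2)
  r2 <- if (length(conc_ppm) == 2) 1
        else if (syy == 0) 0
        else 1 - sum(stats::resid(fit)^2) / syy
  list(slope_ppm_per_s = slope,
       r2 = min(max(r2, 0), 1),
       conc_range_ppm = max(conc_ppm) - min(conc_ppm),
       n = length(conc_ppm))
}

#' Convert a concentration slope to a mass flux
#'
#' Applies the ideal-gas conversion used for closed chambers:
#' flux = slope x 1e-6 x P/(R T) x h x M x 86400, with P the chamber pressure
#' (Pa), T the air temperature (K), h the effective chamber height (m) —
#' chamber height plus collar rim headspace minus water depth inside the
#' collar — and M the molar mass of the gas. The sign of the slope is
#' preserved: positive = emission, negative = uptake.
#'
#' @param slope_ppm_per_s OLS slope, ppm per second.
#' @param air_temp_C air temperature during the run, degrees Celsius.
#' @param effective_height_m effective headspace height, metres; must be > 0.
#' @param gas `"CO2"` or `"CH4"`.
#' @param config pipeline configuration (pressure, molar masses, gas constant).
#' @return flux in g gas per square metre per day.
#' @examples
#' slope_to_flux(0.1, 20, 0.30, "CO2")  # about 4.74 g CO2 m^-2 d^-1
#' @export
slope_to_flux <- function(slope_ppm_per_s, air_temp_C, effective_height_m,
                          gas = c("CO2", "CH4"), config = default_config()) {
  gas <- match.arg(gas)
  if (any(effective_height_m <= 0))
    stop("effective chamber height must be positive")
  if (any(air_temp_C <= -273.15))
    stop("air temperature below absolute zero")
  molar_density <- (config$pressure_kPa * 1000) /
    (config$gas_constant * (air_temp_C + 273.15))   # mol m^-3
  slope_ppm_per_s * 1e-6 * molar_density * effective_height_m *
    config$molar_mass_g[[gas]] * 86400
}

#' Quality-control label for a CO2 chamber run
#'
#' A run whose concentration range stays below 2 ppm is taken as zero flux
#' (stable headspace); this rule takes precedence over the linearity rule.
#' Otherwise a run whose linear fit has r-squared at or below 0.75 is rejected
#' as non-linear; the remainder are accepted. Boundaries follow the protocol
#' exactly: a range of exactly 2 ppm is not zero, an r-squared of exactly
#' 0.75 is rejected.
#'
#' @param conc_range_ppm max minus min concentration over the run, ppm.
#' @param r2 coefficient of determination of the linear fit.
#' @param config pipeline configuration (thresholds).
#' @return one of `"zero"`, `"rejected_nonlinear"`, `"accepted"`.
#' @export
qc_co2 <- function(conc_range_ppm, r2, config = default_config()) {
  ifelse(conc_range_ppm < config$co2_zero_range_ppm, "zero",
         ifelse(r2 <= config$co2_r2_min, "rejected_nonlinear", "accepted"))
}

#' Quality-control label for a CH4 chamber run
#'
#' A run whose concentration change is within the 0.5 ppm precision of the
#' sampling and analysis method is taken as zero flux (a range of exactly
#' 0.5 ppm is still "within the precision", hence zero). Otherwise a run with
#' slope r-squared below 0.60 is rejected as inconsistent, suggesting
#' ebullition (exactly 0.60 is accepted); the remainder are accepted.
#'
#' @inheritParams qc_co2
#' @return one of `"zero"`, `"rejected_ebullition"`, `"accepted"`.
#' @export
qc_ch4 <- function(conc_range_ppm, r2, config = default_config()) {
  ifelse(conc_range_ppm <= config$ch4_zero_range_ppm, "zero",
         ifelse(r2 < config$ch4_r2_min, "rejected_ebullition", "accepted"))
}

#' Compute QC-labelled fluxes from a long table of chamber readings
#'
#' Groups readings into runs (one run = one `collar_id` x `gas` x
#' `start_time`), fits the OLS slope per run, converts it to a mass flux using
#' the effective chamber height (chamber height + `headspace_adjust_m`), and
#' attaches the quality-control label. Zero-classified runs get flux exactly 0.
#' Rejected runs keep their computed flux for inspection but must be excluded
#' from all downstream fitting and budgeting via the `qc` column.
#'
#' @param runs data.frame in long format with columns `collar_id`, `gas`
#'   ("CO2"/"CH4"), `start_time` (POSIXct or ISO 8601 string), `elapsed_s`,
#'   `conc_ppm`, `air_temp_C`, `par_umol_m2_s`, `chamber_height_m`,
#'   `collar_area_m2`, `headspace_adjust_m`; one row per reading.
#' @param wells optional data.frame with `collar_id`, `date`, `soil_temp5_C`,
#'   `wtl_cm` (water table level, cm, positive above the peat surface),
#'   joined by collar and calendar date of the run.
#' @param config pipeline configuration.
#' @return data.frame with one row per run: identifiers, drivers,
#'   `slope_ppm_per_s`, `r2`, `conc_range_ppm`, `flux_g_m2_d`, `qc`.
#' @export
compute_fluxes <- function(runs, wells = NULL, config = default_config()) {
  need <- c("collar_id", "gas", "start_time", "elapsed_s", "conc_ppm",
            "air_temp_C", "par_umol_m2_s", "chamber_height_m",
            "collar_area_m2", "headspace_adjust_m")
  miss <- setdiff(need, names(runs))
  if (length(miss)) stop("runs is missing columns: ", paste(miss, collapse = ", "))
  runs$start_time <- as_utc(runs$start_time)

  key <- interaction(runs$collar_id, runs$gas, format(runs$start_time, "%Y-%m-%d %H:%M:%S"),
                     drop = TRUE)
  pieces <- split(runs, key)
  out <- lapply(pieces, function(d) {
    d <- d[order(d$elapsed_s), ]
    sl <- fit_slope(d$elapsed_s, d$conc_ppm)
    gas <- as.character(d$gas[1])
    h_eff <- d$chamber_height_m[1] + d$headspace_adjust_m[1]
    flux <- slope_to_flux(sl$slope_ppm_per_s, d$air_temp_C[1], h_eff, gas, config)
    qc <- if (gas == "CO2") qc_co2(sl$conc_range_ppm, sl$r2, config)
          else qc_ch4(sl$conc_range_ppm, sl$r2, config)
    if (qc == "zero") flux <- 0
    data.frame(collar_id = d$collar_id[1], gas = gas, time = d$start_time[1],
               slope_ppm_per_s = sl$slope_ppm_per_s, r2 = sl$r2,
               conc_range_ppm = sl$conc_range_ppm, n_readings = sl$n,
               flux_g_m2_d = flux, qc = qc,
               par_umol_m2_s = d$par_umol_m2_s[1], air_temp_C = d$air_temp_C[1],
               stringsAsFactors = FALSE)
  })
  fluxes <- do.call(rbind, out)
  rownames(fluxes) <- NULL
  fluxes <- fluxes[order(fluxes$collar_id, fluxes$gas, fluxes$time), ]

  fluxes$date <- as.Date(fluxes$time, tz = "UTC")
  if (!is.null(wells)) {
    wneed <- c("collar_id", "date", "soil_temp5_C", "wtl_cm")
    wmiss <- setdiff(wneed, names(wells))
    if (length(wmiss)) stop("wells is missing columns: ", paste(wmiss, collapse = ", "))
    wells$date <- as.Date(wells$date)
    fluxes <- merge(fluxes, wells[, wneed], by = c("collar_id", "date"),
                    all.x = TRUE, sort = FALSE)
  } else {
    fluxes$soil_temp5_C <- NA_real_
    fluxes$wtl_cm <- NA_real_
  }
  fluxes[order(fluxes$collar_id, fluxes$gas, fluxes$time), ]
}

#' Partition one campaign's CO2 fluxes into NEE, ER and GEP
#'
#' Within a campaign (one visit to one collar), the fully darkened run
#' (PAR = 0) measures ecosystem respiration; every lit run measures net
#' ecosystem exchange at its light level, and gross ecosystem productivity is
#' GEP = NEE - ER. Only accepted or zero-classified runs are used. If the
#' campaign has no usable dark run it is flagged: the lit runs still yield
#' NEE, but GEP is NA.
#'
#' @param campaign data.frame of CO2 flux rows (as from [compute_fluxes()])
#'   for one collar and one campaign.
#' @return data.frame with one row per lit run (`par_umol_m2_s`, `nee`,
#'   `gep`, `time`, drivers) and attributes `er` (dark flux, NA if flagged)
#'   and `flagged`.
#' @export
partition_nee_er <- function(campaign) {
  ok <- campaign$qc %in% c("accepted", "zero")
  dark <- campaign[ok & campaign$par_umol_m2_s == 0, ]
  lit  <- campaign[ok & campaign$par_umol_m2_s > 0, ]
  flagged <- nrow(dark) == 0
  er <- if (flagged) NA_real_ else mean(dark$flux_g_m2_d)
  res <- data.frame(collar_id = lit$collar_id, time = lit$time,
                    par_umol_m2_s = lit$par_umol_m2_s,
                    nee = lit$flux_g_m2_d,
                    gep = if (flagged) rep(NA_real_, nrow(lit))
                          else lit$flux_g_m2_d - er,
                    air_temp_C = lit$air_temp_C,
                    stringsAsFactors = FALSE)
  attr(res, "er") <- er
  attr(res, "flagged") <- flagged
  res
}

# Parse character/POSIXct timestamps to POSIXct UTC.
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (anyNA(out)) stop("unparseable timestamps: ", paste(utils::head(x[is.na(out)], 3), collapse = ", "))
  out
}
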