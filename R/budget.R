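#' Integrate an hourly flux series over the season
#'
#' Each hourly value is a daily-rate sample (g m^-2 d^-1) covering 1/24 of a
#' day, so the seasonal total is the sum divided by 24. The series must cover
#' the full hourly grid of the season window; gaps are an error naming the
#' missing timestamps.
#'
#' @param timestamps POSIXct vector of the series.
#' @param flux_g_m2_d hourly flux values, g m^-2 d^-1.
#' @param config pipeline configuration (season window).
#' @return seasonal total, g m^-2.
#' @export
integrate_hourly <- function(timestamps, flux_g_m2_d, config = default_config()) {
  grid <- season_grid(config)
  timestamps <- as_utc(timestamps)
  idx <- match(as.numeric(grid), as.numeric(timestamps))
  if (anyNA(idx)) {
    missing <- grid[is.na(idx)]
    stop("hourly grid has gaps; first missing timestamps: ",
         paste(format(utils::head(missing, 3), "%Y-%m-%d %H:%M"), collapse = ", "))
  }
  vals <- flux_g_m2_d[idx]
  if (anyNA(vals)) stop("hourly flux series contains NA inside the season window")
  sum(vals) / 24
}

#' Seasonal methane total by trapezoidal interpolation
#'
#' Integrates sparse instantaneous CH4 fluxes over the season window with the
#' trapezoid rule between consecutive measurements,
#' F(1-2) = 1/2 (f1 + f2)(t2 - t1), summed over pairs. The window edges are
#' filled by constant extension of the first and last measurement so the
#' total spans exactly the configured season. Zero-classified fluxes
#' participate as true zeros; rejected fluxes must not be passed in (the
#' trapezoid bridges their gap between neighbours).
#'
#' @param times POSIXct (or parseable) measurement times.
#' @param flux_g_m2_d instantaneous fluxes, g CH4 m^-2 d^-1.
#' @param config pipeline configuration (season window).
#' @return seasonal total, g CH4 m^-2.
#' @examples
#' cfg <- default_config(season_start = "2016-06-01", season_end = "2016-06-08")
#' interpolate_ch4(c("2016-06-01", "2016-06-08"), c(10, 20), cfg) / 1  # 105
#' @export
interpolate_ch4 <- function(times, flux_g_m2_d, config = default_config()) {
  if (length(times) == 0) stop("no methane measurements to interpolate")
  w <- season_window(config)
  t_day <- as.numeric(difftime(as_utc(times), w[["start"]], units = "days"))
  o <- order(t_day)
  t_day <- t_day[o]; f <- flux_g_m2_d[o]
  span <- as.numeric(difftime(w[["end"]], w[["start"]], units = "days"))
  keep <- t_day >= 0 & t_day <= span
  t_day <- t_day[keep]; f <- f[keep]
  if (length(t_day) == 0) stop("no methane measurements inside the season window")
  # constant extension to the window edges
  t_day <- c(0, t_day, span)
  f <- c(f[1], f, f[length(f)])
  sum(0.5 * (f[-1] + f[-length(f)]) * diff(t_day))
}

#' Convert a methane total to its CO2 equivalent
#'
#' Multiplies by the 100-year global warming potential of non-fossil methane
#' (default 27 g CO2-e per g CH4).
#'
#' @param ch4_total_g_m2 seasonal methane total, g CH4 m^-2.
#' @param config pipeline configuration (`gwp_factor`).
#' @return g CO2-e m^-2.
#' @export
ch4_co2_equivalent <- function(ch4_total_g_m2, config = default_config()) {
  config$gwp_factor * ch4_total_g_m2
}

#' Total carbon balance from CO2 and CH4 totals
#'
#' Converts mass totals of each gas to carbon using the molar ratios 12/44
#' (CO2) and 12/16 (CH4) and sums them.
#'
#' @param nee_total_g_m2 seasonal NEE, g CO2 m^-2.
#' @param ch4_total_g_m2 seasonal methane total, g CH4 m^-2.
#' @return g C m^-2.
#' @export
total_carbon <- function(nee_total_g_m2, ch4_total_g_m2) {
  nee_total_g_m2 * 12 / 44 + ch4_total_g_m2 * 12 / 16
}

#' Global warming potential of a collar's season
#'
#' The methane CO2 equivalent added to the modelled NEE (GEP minus ER under
#' the uptake-negative convention, i.e. GEP + ER with ER positive).
#'
#' @inheritParams total_carbon
#' @param config pipeline configuration (`gwp_factor`).
#' @return g CO2-e m^-2.
#' @export
gwp <- function(nee_total_g_m2, ch4_total_g_m2, config = default_config()) {
  nee_total_g_m2 + ch4_co2_equivalent(ch4_total_g_m2, config)
}

#' Assemble a collar's seasonal budget
#'
#' Bundles the seasonal totals and derived quantities, enforcing the defining
#' identities NEE = GEP + ER, C = NEE x 12/44 + CH4 x 12/16 and
#' GWP = NEE + gwp_factor x CH4.
#'
#' @param collar_id collar identifier.
#' @param gep_total,er_total seasonal GEP (<= 0) and ER (>= 0), g CO2 m^-2.
#' @param ch4_total seasonal methane, g CH4 m^-2.
#' @param config pipeline configuration.
#' @return one-row data.frame with `gep_total`, `er_total`, `nee_total`,
#'   `ch4_total`, `c_total`, `gwp`, `season_days`.
#' @export
collar_budget <- function(collar_id, gep_total, er_total, ch4_total,
                          config = default_config()) {
  nee <- gep_total + er_total
  w <- season_window(config)
  data.frame(collar_id = collar_id,
             gep_total = gep_total, er_total = er_total, nee_total = nee,
             ch4_total = ch4_total,
             c_total = total_carbon(nee, ch4_total),
             gwp = gwp(nee, ch4_total, config),
             season_days = as.numeric(difftime(w[["end"]], w[["start"]], units = "days")),
             stringsAsFactors = FALSE)
}
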