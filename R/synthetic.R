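#' Simulation configuration for the synthetic-data generator
#'
#' Defaults emulate the field protocol the pipeline targets: campaigns every
#' 10 days (one-to-two-weekly visits) at midday over the 113-day season, CO2
#' light-response runs under shade fractions 1, 0.5, 0.25 and 0 (the dark run)
#' with readings every 15 s for 3 minutes, 4-point CH4 headspace series
#' sampled at 7, 15, 25 and 35 minutes, reading noise of 1 ppm (infrared gas
#' analyser) and 0.05 ppm (vials; well below the 0.5 ppm zero-classification
#' precision), and occasional ebullition events injected as a concentration
#' spike at the mid-series CH4 sample with a 7% probability per run.
#'
#' @param ... named overrides for any default entry.
#' @return named list of generator settings.
#' @export
sim_config <- function(...) {
  cfg <- list(
    season_start          = "2016-05-24",
    season_end            = "2016-09-14",
    campaign_interval_days = 10,
    campaign_jitter_days  = 1,
    campaign_hour         = 12,
    shade_fractions       = c(1, 0.5, 0.25, 0),
    ch4_sample_min        = c(7, 15, 25, 35),
    co2_cadence_s         = 15,
    co2_duration_s        = 180,
    co2_noise_sd_ppm      = 1,
    ch4_noise_sd_ppm      = 0.05,
    ebullition_prob       = 0.07,
    ebullition_spike_ppm  = 40,
    co2_ambient_ppm       = 410,
    ch4_ambient_ppm       = 1.9,
    chamber_height_m      = 0.30,
    collar_area_m2        = 0.36,
    par_peak_umol         = 1500,
    pressure_kPa          = 101.325
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim config entries: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(any(cfg$shade_fractions == 0))  # a dark run is required
  cfg
}

#' Generate an hourly driver series for the season
#'
#' PAR is a clear-sky half-sinusoid between sunrise and sunset (day length
#' varying with day of year) scaled by a daily cloudiness factor, and exactly
#' zero at night. Air temperature is a seasonal arc plus a diurnal sinusoid
#' peaking mid-afternoon plus AR(1) noise; soil temperature at 5 cm is a
#' strongly damped, lagged filter of air temperature; water table level is a
#' slow mean-reverting walk around zero (collar-specific offsets are added by
#' the collar truths). Deterministic given the seed.
#'
#' @param config simulation configuration.
#' @param seed integer RNG seed.
#' @return data.frame `timestamp`, `par_umol_m2_s`, `air_temp_C`,
#'   `soil_temp5_C`, `wtl_cm` on the hourly season grid.
#' @export
gen_drivers <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  grid <- season_grid(default_config(season_start = config$season_start,
                                     season_end = config$season_end))
  n <- length(grid)
  doy <- as.integer(format(grid, "%j"))
  hour <- as.integer(format(grid, "%H"))
  day_idx <- as.integer(as.Date(grid, tz = "UTC") - as.Date(config$season_start)) + 1
  n_days <- max(day_idx)

  daylen <- 12 + 4 * sin(2 * pi * (doy - 80) / 365)
  sunrise <- 12 - daylen / 2
  cloud <- stats::runif(n_days, 0.35, 1)
  up <- hour > sunrise & hour < sunrise + daylen
  par <- ifelse(up,
                config$par_peak_umol * cloud[day_idx] *
                  sin(pi * (hour - sunrise) / daylen), 0)

  frac <- (day_idx - 1) / (n_days - 1)
  trend <- 10 + 8 * sin(pi * frac)
  diurnal <- 5 * cos(2 * pi * (hour - 15) / 24)
  ar <- stats::filter(stats::rnorm(n, 0, 0.5), 0.95, method = "recursive")
  tair <- trend + diurnal + as.numeric(ar)

  t5 <- numeric(n)
  t5[1] <- trend[1]
  for (i in 2:n) t5[i] <- t5[i - 1] + 0.02 * (tair[i] - t5[i - 1])

  wtl <- numeric(n)
  eps <- stats::rnorm(n, 0, 0.15)
  wtl[1] <- 0
  for (i in 2:n) wtl[i] <- wtl[i - 1] + 0.02 * (0 - wtl[i - 1]) + eps[i]

  data.frame(timestamp = grid, par_umol_m2_s = par, air_temp_C = tair,
             soil_temp5_C = t5, wtl_cm = wtl)
}

#' Generate the campaign visit schedule
#'
#' Visits at the configured interval from mid-interval after the season start,
#' jittered by +/- `campaign_jitter_days` (uniform), clipped inside the
#' window, at the configured hour of day.
#'
#' @param config simulation configuration.
#' @param seed integer RNG seed.
#' @return POSIXct vector of campaign times.
#' @export
gen_campaign_schedule <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  span <- as.numeric(as.Date(config$season_end) - as.Date(config$season_start))
  days <- seq(config$campaign_interval_days / 2, span - 0.5,
              by = config$campaign_interval_days)
  if (config$campaign_jitter_days > 0)
    days <- days + stats::runif(length(days), -config$campaign_jitter_days,
                                config$campaign_jitter_days)
  days <- pmin(pmax(days, 0), span - 0.5)
  as.POSIXct(config$season_start, tz = "UTC") +
    floor(days) * 86400 + config$campaign_hour * 3600
}

# Piecewise water-table response of the methane truth model: emissions rise
# log-linearly with WTL up to +30 cm of standing water, then decline (water
# column oxidation).
ch4_wtl_factor <- function(wtl_cm) {
  exp(0.02 * pmin(wtl_cm, 30) - 0.04 * pmax(wtl_cm - 30, 0))
}

# True instantaneous CH4 flux (g CH4 m^-2 d^-1) for a collar truth at given
# 5 cm soil temperature and water table level.
ch4_truth_flux <- function(truth, soil_temp5_C, wtl_cm) {
  truth$ch4_base * exp(truth$ch4_kT * (soil_temp5_C - 10)) * ch4_wtl_factor(wtl_cm)
}

# True instantaneous ER (g CO2 m^-2 d^-1) for a collar truth.
er_truth_flux <- function(truth, air_temp_C, soil_temp5_C = NULL, wtl_cm = NULL) {
  predict_er(truth$er_fit, air_temp_C, soil_temp5_C, wtl_cm)
}

# True instantaneous GEP for a collar truth (0 for unvegetated collars).
gep_truth_flux <- function(truth, par_umol) {
  if (!truth$vegetated) return(rep(0, length(par_umol)))
  predict_gep(par_umol, truth$Q_true, truth$GPmax_true)
}

#' Default collar truths for the synthetic site
#'
#' Four sectors of six collars emulating a rewetting chronosequence: an
#' unrestored sector (bare-dominated, deep water table), a freshly rewetted
#' and profiled sector (submerged, open water, no vegetation — only dark CO2
#' and CH4 runs are generated there), a rewetted sector (mixed bare /
#' herbaceous / shrub cover near the surface) and a reference fen (herbaceous
#' and shrub cover, shallow standing water). Light-response, respiration and
#' methane truth parameters are set per cover type at magnitudes typical of
#' growing-season fen chamber work.
#'
#' @param config simulation configuration.
#' @return data.frame of collar metadata with a `truth` list-column.
#' @export
default_collar_truths <- function(config = sim_config()) {
  type_pars <- list(
    bare       = list(Q = -0.008, GPmax = -4,  ERref = 5.0, E0 = 180,
                      ch4_base = 0.02, ch4_kT = 0.06),
    herbaceous = list(Q = -0.050, GPmax = -40, ERref = 4.0, E0 = 200,
                      ch4_base = 0.10, ch4_kT = 0.06),
    shrubs     = list(Q = -0.050, GPmax = -45, ERref = 4.5, E0 = 200,
                      ch4_base = 0.08, ch4_kT = 0.06),
    open_water = list(Q = 0, GPmax = 0, ERref = 2.0, E0 = 120,
                      ch4_base = 0.06, ch4_kT = 0.06)
  )
  sectors <- list(
    UNR = list(wtl = -15, types = c("bare", "bare", "bare",
                                    "herbaceous", "herbaceous", "herbaceous")),
    RP1 = list(wtl = 40, types = rep("open_water", 6)),
    R1  = list(wtl = 0,  types = c("bare", "bare", "herbaceous", "herbaceous",
                                   "shrubs", "shrubs")),
    REF = list(wtl = 8,  types = c("herbaceous", "herbaceous", "herbaceous",
                                   "shrubs", "shrubs", "shrubs"))
  )
  rows <- list()
  cfg0 <- default_config()
  for (sec in names(sectors)) {
    s <- sectors[[sec]]
    for (i in seq_along(s$types)) {
      ct <- s$types[i]
      p <- type_pars[[ct]]
      veget <- ct != "open_water"
      truth <- list(
        vegetated = veget,
        Q_true = p$Q, GPmax_true = p$GPmax,
        er_fit = er_fit_record("exponential", "Tair", FALSE,
                               c(ERref = p$ERref, E0 = p$E0),
                               n = NA_integer_, rss = 0, cfg0),
        ch4_base = p$ch4_base, ch4_kT = p$ch4_kT,
        wtl_offset_cm = s$wtl,
        ebullition_prob = config$ebullition_prob
      )
      rows[[length(rows) + 1]] <- data.frame(
        collar_id = sprintf("%s-C%d", sec, i), sector_id = sec,
        cover_type = ct, vegetated = veget, wtl_offset_cm = s$wtl,
        headspace_adjust_m = 0.05 - pmin(pmax(s$wtl, 0), 20) / 100,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$truth <- list(truth)
    }
  }
  do.call(rbind, rows)
}

#' Generate one chamber run from a collar truth
#'
#' The true instantaneous flux (NEE at the shaded PAR level for CO2, or the
#' methane truth model for CH4) is converted to a true ppm slope by inverting
#' the ideal-gas slope-to-flux relation at the run's temperature and effective
#' height, and readings are the ambient concentration plus that slope plus
#' Gaussian reading noise. With probability `ebullition_prob` a CH4 run gets
#' an ebullition spike added to its mid-series sample, which degrades the
#' linear r-squared. Uses the current RNG stream.
#'
#' @param truth a collar truth (one element of the `truth` column of
#'   [default_collar_truths()]).
#' @param collar one row of the collar metadata.
#' @param time POSIXct run start.
#' @param driver_row drivers at the run hour (`par_umol_m2_s`, `air_temp_C`,
#'   `soil_temp5_C`, `wtl_cm` site anomaly).
#' @param gas `"CO2"` or `"CH4"`.
#' @param shade shade fraction for CO2 runs (1 = clear, 0 = darkened).
#' @param config simulation configuration.
#' @return long-format data.frame of readings (chamber_runs schema) with
#'   attribute `true_flux`.
#' @export
gen_chamber_run <- function(truth, collar, time, driver_row, gas, shade = 1,
                            config = sim_config()) {
  wtl <- driver_row$wtl_cm + truth$wtl_offset_cm
  if (gas == "CO2") {
    par_chamber <- shade * driver_row$par_umol_m2_s
    true_flux <- gep_truth_flux(truth, par_chamber) +
      er_truth_flux(truth, driver_row$air_temp_C, driver_row$soil_temp5_C, wtl)
    t_s <- seq(0, config$co2_duration_s, by = config$co2_cadence_s)
    sd <- config$co2_noise_sd_ppm
    ambient <- config$co2_ambient_ppm
  } else {
    par_chamber <- 0
    true_flux <- ch4_truth_flux(truth, driver_row$soil_temp5_C, wtl)
    t_s <- config$ch4_sample_min * 60
    sd <- config$ch4_noise_sd_ppm
    ambient <- config$ch4_ambient_ppm
  }
  h_eff <- config$chamber_height_m + collar$headspace_adjust_m
  pcfg <- default_config(pressure_kPa = config$pressure_kPa)
  per_slope <- slope_to_flux(1, driver_row$air_temp_C, h_eff, gas, pcfg)
  slope <- true_flux / per_slope
  conc <- ambient + slope * t_s + stats::rnorm(length(t_s), 0, sd)
  if (gas == "CH4" && stats::runif(1) < truth$ebullition_prob) {
    mid <- ceiling(length(t_s) / 2)
    conc[mid] <- conc[mid] + config$ebullition_spike_ppm
  }
  conc <- pmax(conc, 0.01)
  out <- data.frame(
    collar_id = collar$collar_id, gas = gas,
    start_time = format(time, "%Y-%m-%d %H:%M:%S"),
    elapsed_s = t_s, conc_ppm = conc,
    air_temp_C = driver_row$air_temp_C, par_umol_m2_s = par_chamber,
    chamber_height_m = config$chamber_height_m,
    collar_area_m2 = config$collar_area_m2,
    headspace_adjust_m = collar$headspace_adjust_m,
    stringsAsFactors = FALSE)
  attr(out, "true_flux") <- true_flux
  out
}

#' Generate survey plots for a sector specification
#'
#' Plot cover percentages are drawn from uniform ranges chosen so the
#' classification rule reproduces the intended cover type with certainty, and
#' species covers are drawn from the default species pool matching each
#' type's community. Uses the current RNG stream.
#'
#' @param sector_id sector identifier.
#' @param counts named integer vector of plots per intended cover type
#'   (names among bare / herbaceous / shrubs / open_water).
#' @return list with `plots` (one row per plot: covers + open-water flag) and
#'   `species_cover` (long species-by-plot percent cover).
#' @export
gen_survey <- function(sector_id, counts) {
  pool <- default_species_pool()
  plots <- list(); species <- list()
  plot_no <- 0
  for (ct in names(counts)) {
    for (i in seq_len(counts[[ct]])) {
      plot_no <- plot_no + 1
      pid <- sprintf("%s-P%02d", sector_id, plot_no)
      ow <- ct == "open_water"
      vasc <- switch(ct, bare = stats::runif(1, 2, 18),
                     herbaceous = stats::runif(1, 25, 70),
                     shrubs = stats::runif(1, 35, 80), open_water = 0)
      shrub <- switch(ct, bare = stats::runif(1, 0, 5),
                      herbaceous = stats::runif(1, 0, 15),
                      shrubs = stats::runif(1, 22, 45), open_water = 0)
      bryo <- switch(ct, bare = stats::runif(1, 0, 3),
                     herbaceous = stats::runif(1, 0, 20),
                     shrubs = stats::runif(1, 5, 40), open_water = 0)
      plots[[plot_no]] <- data.frame(
        sector_id = sector_id, plot_id = pid, vascular_pct = vasc,
        shrub_pct = shrub, graminoid_pct = max(vasc - shrub, 0),
        bryophyte_pct = bryo, open_water = ow, stringsAsFactors = FALSE)
      if (!ow) {
        sp <- pool[pool$community %in% c(ct, "any"), ]
        n_sp <- min(nrow(sp), sample(2:4, 1))
        pick <- sp[sample(nrow(sp), n_sp), ]
        species[[length(species) + 1]] <- data.frame(
          sector_id = sector_id, plot_id = pid, species = pick$species,
          cover_pct = round(stats::runif(n_sp, 1, max(vasc, 5)), 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(plots = do.call(rbind, plots),
       species_cover = if (length(species)) do.call(rbind, species) else
         data.frame(sector_id = character(), plot_id = character(),
                    species = character(), cover_pct = numeric()))
}

#' Species pool with preferential habitat labels
#'
#' A small pool of fen species typical of the communities the generator
#' emulates, with preferential habitat category and growth form.
#'
#' @return data.frame `species`, `habitat`, `growth_form`, `community`.
#' @export
default_species_pool <- function() {
  data.frame(
    species = c("Carex lasiocarpa", "Campylium stellatum", "Scorpidium cossonii",
                "Betula pumila", "Larix laricina", "Typha latifolia",
                "Salix candida", "Calamagrostis canadensis",
                "Hordeum jubatum", "Agrostis scabra"),
    habitat = c("peatland", "peatland", "peatland", "peatland", "peatland",
                "wetland", "wetland", "facultative", "other", "other"),
    growth_form = c("vascular", "bryophyte", "bryophyte", "vascular", "vascular",
                    "vascular", "vascular", "vascular", "vascular", "vascular"),
    community = c("herbaceous", "shrubs", "shrubs", "shrubs", "shrubs",
                  "herbaceous", "shrubs", "any", "bare", "bare"),
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic site with truth bookkeeping
#'
#' Builds the hourly drivers, campaign schedule, collar truths, chamber runs
#' (per campaign: one CO2 run per shade fraction for vegetated collars, the
#' dark run only for open-water collars, and one CH4 run), well records (soil
#' temperature and water table at each visit), sector survey plots, and the
#' truth ledger: per collar, the generative parameters and the seasonal truth
#' integrals of NEE (= GEP + ER truth models on the hourly drivers) and CH4
#' (continuous truth model on the hourly grid). All randomness flows from the
#' single seed.
#'
#' @param config simulation configuration.
#' @param seed integer RNG seed.
#' @return list with `runs`, `wells`, `drivers`, `collars`, `plots`,
#'   `species_cover`, `schedule`, `truth`.
#' @export
gen_site <- function(config = sim_config(), seed = 1) {
  drivers <- gen_drivers(config, seed)
  schedule <- gen_campaign_schedule(config, seed + 1)
  set.seed(seed + 2)
  collars <- default_collar_truths(config)

  hour_key <- as.numeric(drivers$timestamp)
  runs <- list(); wells <- list(); true_pts <- list()
  for (ci in seq_len(nrow(collars))) {
    collar <- collars[ci, ]
    truth <- collar$truth[[1]]
    for (tm in as.list(schedule)) {
      drow <- drivers[match(round(as.numeric(tm) / 3600) * 3600, hour_key), ]
      shades <- if (truth$vegetated) config$shade_fractions else 0
      for (si in seq_along(shades)) {   # shade runs are sequential in the field
        r <- gen_chamber_run(truth, collar, tm + (si - 1) * 300, drow, "CO2",
                             shades[si], config)
        runs[[length(runs) + 1]] <- r
      }
      r4 <- gen_chamber_run(truth, collar, tm + length(shades) * 300, drow,
                            "CH4", 0, config)
      runs[[length(runs) + 1]] <- r4
      true_pts[[length(true_pts) + 1]] <- data.frame(
        collar_id = collar$collar_id, time = tm,
        ch4_true = attr(r4, "true_flux"), stringsAsFactors = FALSE)
      wells[[length(wells) + 1]] <- data.frame(
        collar_id = collar$collar_id, date = as.Date(tm, tz = "UTC"),
        soil_temp5_C = drow$soil_temp5_C,
        wtl_cm = drow$wtl_cm + truth$wtl_offset_cm, stringsAsFactors = FALSE)
    }
  }

  survey_counts <- list(UNR = c(bare = 25, herbaceous = 5),
                        RP1 = c(open_water = 30),
                        R1  = c(bare = 5, herbaceous = 20, shrubs = 5),
                        REF = c(herbaceous = 16, shrubs = 14))
  plots <- list(); spc <- list()
  for (sec in names(survey_counts)) {
    sv <- gen_survey(sec, survey_counts[[sec]])
    plots[[sec]] <- sv$plots
    spc[[sec]] <- sv$species_cover
  }

  # Seasonal truth integrals on the hourly grid.
  truth_totals <- lapply(seq_len(nrow(collars)), function(ci) {
    collar <- collars[ci, ]
    tr <- collar$truth[[1]]
    wtl <- drivers$wtl_cm + tr$wtl_offset_cm
    gep <- gep_truth_flux(tr, drivers$par_umol_m2_s)
    er <- er_truth_flux(tr, drivers$air_temp_C, drivers$soil_temp5_C, wtl)
    ch4 <- ch4_truth_flux(tr, drivers$soil_temp5_C, wtl)
    data.frame(collar_id = collar$collar_id,
               gep_true = sum(gep) / 24, er_true = sum(er) / 24,
               nee_true = sum(gep + er) / 24, ch4_true = sum(ch4) / 24,
               stringsAsFactors = FALSE)
  })

  list(runs = do.call(rbind, runs),
       wells = do.call(rbind, wells),
       drivers = drivers,
       collars = collars,
       plots = do.call(rbind, plots),
       species_cover = do.call(rbind, spc),
       schedule = schedule,
       truth = list(collars = collars,
                    totals = do.call(rbind, truth_totals),
                    instantaneous_ch4 = do.call(rbind, true_pts),
                    seed = seed))
}
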