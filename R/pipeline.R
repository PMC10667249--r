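#' Fit light-response and respiration models for every collar
#'
#' For each collar, dark-run (PAR = 0) CO2 fluxes give the ecosystem
#' respiration observations and each campaign's lit runs give NEE, hence
#' GEP = NEE - ER observations. The respiration candidate set is fitted and
#' selected per collar, and the seasonal light-response partition is chosen
#' for vegetated collars; unvegetated collars (open water / bare with no
#' vascular cover) get GEP identically zero, so NEE = ER for them. Collars
#' whose data do not meet the minimum requirements are reported as unfittable
#' with a warning — no silent imputation.
#'
#' @param fluxes QC-labelled flux table from [compute_fluxes()].
#' @param collars collar metadata: `collar_id`, `sector_id`, `cover_type`,
#'   `vegetated` (logical).
#' @param config pipeline configuration.
#' @return named list per collar: `light` (partition fit or NULL), `er`
#'   (respiration fit or NULL), `gep_obs`, `er_obs`, `vegetated`, `ok`.
#' @export
fit_collar_models <- function(fluxes, collars, config = default_config()) {
  out <- list()
  for (ci in seq_len(nrow(collars))) {
    cid <- collars$collar_id[ci]
    veg <- isTRUE(collars$vegetated[ci])
    co2 <- fluxes[fluxes$collar_id == cid & fluxes$gas == "CO2", ]
    gep_obs <- list(); er_obs <- list()
    for (camp in split(co2, as.character(co2$date))) {
      part <- partition_nee_er(camp)
      dark <- camp[camp$qc %in% c("accepted", "zero") & camp$par_umol_m2_s == 0, ]
      if (nrow(dark) > 0) {
        er_obs[[length(er_obs) + 1]] <- data.frame(
          time = dark$time[1], er = mean(dark$flux_g_m2_d),
          air_temp_C = dark$air_temp_C[1], soil_temp5_C = dark$soil_temp5_C[1],
          wtl_cm = dark$wtl_cm[1], stringsAsFactors = FALSE)
      }
      if (nrow(part) > 0 && !attr(part, "flagged"))
        gep_obs[[length(gep_obs) + 1]] <- part
    }
    gep_obs <- if (length(gep_obs)) do.call(rbind, gep_obs) else NULL
    er_obs <- if (length(er_obs)) do.call(rbind, er_obs) else NULL

    er_fit <- if (!is.null(er_obs)) fit_er(er_obs, config) else NULL
    light <- if (veg && !is.null(gep_obs))
      choose_period_partition(gep_obs, config) else NULL
    ok <- !is.null(er_fit) && (!veg || !is.null(light))
    if (!ok) warning("collar ", cid, " is unfittable and will be excluded")
    out[[cid]] <- list(collar_id = cid, vegetated = veg, light = light,
                       er = er_fit, gep_obs = gep_obs, er_obs = er_obs, ok = ok)
  }
  out
}

# Hourly GEP prediction from a chosen period partition (0 for NULL = unvegetated).
predict_gep_hourly <- function(light, timestamps, par_umol) {
  if (is.null(light)) return(rep(0, length(timestamps)))
  per <- period_of(timestamps)
  gep <- rep(NA_real_, length(timestamps))
  for (f in light$fits) {
    idx <- per %in% f$periods
    gep[idx] <- predict_gep(par_umol[idx], f$Q, f$GPmax)
  }
  gep
}

#' Model a collar's seasonal budget from its fitted models
#'
#' Predicts hourly GEP (from the seasonal light-response partition and hourly
#' PAR) and hourly ER (from the selected respiration model and hourly
#' temperature / water table, floored at zero — respiration cannot be
#' negative), sums them over the 113-day grid, integrates the collar's
#' accepted and zero-classified CH4 fluxes by trapezoid, and assembles the
#' budget.
#'
#' @param fit one collar's entry from [fit_collar_models()].
#' @param drivers hourly driver data.frame (`timestamp`, `par_umol_m2_s`,
#'   `air_temp_C`, `soil_temp5_C`, `wtl_cm`).
#' @param ch4_fluxes this collar's CH4 rows from [compute_fluxes()].
#' @param wtl_offset_cm collar-specific offset added to the site water-table
#'   series for hourly prediction.
#' @param config pipeline configuration.
#' @return one-row budget data.frame (see [collar_budget()]).
#' @export
model_collar_budget <- function(fit, drivers, ch4_fluxes, wtl_offset_cm = 0,
                                config = default_config()) {
  if (!fit$ok) stop("collar ", fit$collar_id, " is unfittable")
  gep_h <- predict_gep_hourly(fit$light, drivers$timestamp, drivers$par_umol_m2_s)
  er_h <- pmax(predict_er(fit$er, drivers$air_temp_C, drivers$soil_temp5_C,
                          drivers$wtl_cm + wtl_offset_cm), 0)
  gep_total <- integrate_hourly(drivers$timestamp, gep_h, config)
  er_total <- integrate_hourly(drivers$timestamp, er_h, config)
  keep <- ch4_fluxes$qc %in% c("accepted", "zero")
  ch4_total <- interpolate_ch4(ch4_fluxes$time[keep],
                               ch4_fluxes$flux_g_m2_d[keep], config)
  collar_budget(fit$collar_id, gep_total, er_total, ch4_total, config)
}

#' Run the full chamber-to-sector pipeline
#'
#' Chains every stage: QC-labelled fluxes from raw readings, per-collar model
#' fitting and selection, hourly gap-filling and 113-day integration,
#' trapezoidal CH4 budgets, survey-plot classification into cover weights,
#' and the cover-weighted sector summary.
#'
#' @param runs long chamber-reading table (see [compute_fluxes()]).
#' @param wells per-visit soil temperature / water table records.
#' @param drivers hourly driver series.
#' @param collars collar metadata (`collar_id`, `sector_id`, `cover_type`,
#'   `vegetated`, optional `wtl_offset_cm`).
#' @param plots survey plots (`sector_id`, `vascular_pct`, `shrub_pct`,
#'   `open_water`).
#' @param config pipeline configuration.
#' @return list with `fluxes`, `fits`, `budgets` (one row per fitted collar,
#'   with sector and cover type), `weights` (per sector) and `summary`
#'   (per-type and weighted sector rows).
#' @export
run_pipeline <- function(runs, wells, drivers, collars, plots,
                         config = default_config()) {
  fluxes <- compute_fluxes(runs, wells, config)
  fits <- fit_collar_models(fluxes, collars, config)
  budgets <- list()
  for (ci in seq_len(nrow(collars))) {
    cid <- collars$collar_id[ci]
    f <- fits[[cid]]
    if (!f$ok) next
    ch4 <- fluxes[fluxes$collar_id == cid & fluxes$gas == "CH4", ]
    off <- if ("wtl_offset_cm" %in% names(collars)) collars$wtl_offset_cm[ci] else 0
    b <- model_collar_budget(f, drivers, ch4, off, config)
    b$sector_id <- collars$sector_id[ci]
    b$cover_type <- collars$cover_type[ci]
    budgets[[length(budgets) + 1]] <- b
  }
  budgets <- do.call(rbind, budgets)
  types <- classify_plot(plots$vascular_pct, plots$shrub_pct, plots$open_water)
  weights <- lapply(split(types, plots$sector_id), cover_weights)
  list(fluxes = fluxes, fits = fits, budgets = budgets, weights = weights,
       summary = sector_summary(budgets, weights))
}

#' Presentation-rounded sector report
#'
#' Renders the sector summary the way seasonal budget tables are printed:
#' NEE, total C and GWP rounded to integers and CH4 to one decimal, keeping
#' mean and SD columns. Rounding happens only here; machine-readable outputs
#' keep full precision.
#'
#' @param summary sector summary from [sector_summary()] / [run_pipeline()].
#' @return data.frame with rounded presentation columns.
#' @export
run_report <- function(summary) {
  rep <- summary[, c("sector_id", "cover_type", "n", "weight")]
  rep$weight <- round(rep$weight, 2)
  for (f in c("nee_total", "c_total", "gwp")) {
    rep[[sub("_total$", "", f)]] <- round(summary[[paste0(f, "_mean")]])
    rep[[paste0(sub("_total$", "", f), "_sd")]] <- round(summary[[paste0(f, "_sd")]])
  }
  rep$ch4 <- round(summary$ch4_total_mean, 1)
  rep$ch4_sd <- round(summary$ch4_total_sd, 1)
  rep[, c("sector_id", "cover_type", "n", "weight",
          "nee", "nee_sd", "ch4", "ch4_sd", "c", "c_sd", "gwp", "gwp_sd")]
}

#' Write fitted collar models to JSON
#'
#' Serialises, per collar, the chosen light-response partition (parameters
#' and criterion scores of all candidates) and the selected respiration model
#' with its candidate table.
#'
#' @param fits result of [fit_collar_models()].
#' @param path output file path.
#' @export
write_fits_json <- function(fits, path) {
  ser <- lapply(fits, function(f) {
    list(collar_id = f$collar_id, vegetated = f$vegetated, ok = f$ok,
         light = if (!is.null(f$light)) list(
           partition = f$light$partition, aicc = f$light$aicc,
           scores = as.list(f$light$scores),
           fits = lapply(f$light$fits, function(p)
             list(periods = p$periods, Q = p$Q, GPmax = p$GPmax,
                  n = p$n, rmse = p$rmse))),
         er = if (!is.null(f$er)) list(
           form = f$er$form, temp_source = f$er$temp_source,
           uses_wtl = f$er$uses_wtl, coeffs = as.list(f$er$coeffs),
           n = f$er$n, rmse = f$er$rmse,
           selection_score = f$er$selection_score,
           candidates = f$er$candidates))
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Validate pipeline input tables
#'
#' Schema and range checks for the tables the pipeline consumes. Every
#' problem is reported as one row naming the table, the offending row number
#' and column, so malformed inputs fail loudly before any computation.
#'
#' @param runs,drivers,collars,plots input data.frames (any may be omitted).
#' @return data.frame with columns `table`, `row`, `column`, `message`;
#'   zero rows when everything is well-formed.
#' @export
validate_inputs <- function(runs = NULL, drivers = NULL, collars = NULL,
                            plots = NULL) {
  errs <- list()
  add <- function(table, row, column, message)
    errs[[length(errs) + 1]] <<- data.frame(table = table, row = row,
                                            column = column, message = message,
                                            stringsAsFactors = FALSE)
  check_cols <- function(df, need, table) {
    miss <- setdiff(need, names(df))
    for (m in miss) add(table, NA_integer_, m, "missing column")
    length(miss) == 0
  }
  if (!is.null(runs)) {
    need <- c("collar_id", "gas", "start_time", "elapsed_s", "conc_ppm",
              "air_temp_C", "par_umol_m2_s", "chamber_height_m",
              "collar_area_m2", "headspace_adjust_m")
    if (check_cols(runs, need, "runs")) {
      bad_gas <- which(!runs$gas %in% c("CO2", "CH4"))
      for (i in bad_gas) add("runs", i, "gas", "gas must be CO2 or CH4")
      bad_conc <- which(is.na(runs$conc_ppm) | runs$conc_ppm <= 0)
      for (i in bad_conc) add("runs", i, "conc_ppm", "concentration must be positive")
      ts <- tryCatch(as_utc(runs$start_time), error = function(e) NULL)
      if (is.null(ts)) add("runs", NA_integer_, "start_time", "unparseable timestamps")
      bad_par <- which(runs$gas == "CO2" & (is.na(runs$par_umol_m2_s) |
                                              runs$par_umol_m2_s < 0))
      for (i in bad_par) add("runs", i, "par_umol_m2_s",
                             "PAR must be present and non-negative for CO2 runs")
      bad_h <- which(runs$chamber_height_m + runs$headspace_adjust_m <= 0)
      for (i in bad_h) add("runs", i, "headspace_adjust_m",
                           "effective chamber height must be positive")
      key <- interaction(runs$collar_id, runs$gas, runs$start_time, drop = TRUE)
      for (piece in split(seq_len(nrow(runs)), key)) {
        el <- runs$elapsed_s[piece]
        if (length(el) < 2)
          add("runs", piece[1], "elapsed_s", "run has fewer than 2 readings")
        else if (any(diff(el[order(el)]) <= 0))
          add("runs", piece[1], "elapsed_s", "duplicate elapsed times within run")
      }
    }
  }
  if (!is.null(drivers)) {
    need <- c("timestamp", "par_umol_m2_s", "air_temp_C", "soil_temp5_C", "wtl_cm")
    if (check_cols(drivers, need, "drivers")) {
      bad <- which(is.na(drivers$par_umol_m2_s) | drivers$par_umol_m2_s < 0)
      for (i in bad) add("drivers", i, "par_umol_m2_s", "PAR must be non-negative")
    }
  }
  if (!is.null(collars))
    check_cols(collars, c("collar_id", "sector_id", "cover_type", "vegetated"),
               "collars")
  if (!is.null(plots)) {
    need <- c("sector_id", "vascular_pct", "shrub_pct", "open_water")
    if (check_cols(plots, need, "plots")) {
      for (cl in c("vascular_pct", "shrub_pct")) {
        bad <- which(is.na(plots[[cl]]) | plots[[cl]] < 0 | plots[[cl]] > 100)
        for (i in bad) add("plots", i, cl, "percent cover must be in [0, 100]")
      }
    }
  }
  if (length(errs)) do.call(rbind, errs)
  else data.frame(table = character(), row = integer(), column = character(),
                  message = character(), stringsAsFactors = FALSE)
}
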