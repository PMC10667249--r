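#' Classify a survey plot or collar into a major vegetation cover type
#'
#' Open-water plots are their own type. Among the rest, a plot is bare when
#' vascular cover is below 20% (the bare rule is applied first, so a plot
#' with 18% vascular and 21% shrub cover is bare), shrub-dominated when shrub
#' cover exceeds 20%, and herbaceous otherwise. Boundaries: exactly 20%
#' vascular is not bare; exactly 20% shrub is not shrubs.
#'
#' @param vascular_pct,shrub_pct percent cover, 0-100 (vectorised).
#' @param open_water logical, standing open water plot.
#' @return character vector over `"open_water"`, `"bare"`, `"shrubs"`,
#'   `"herbaceous"`.
#' @examples
#' classify_plot(16, 0)   # bare
#' classify_plot(67, 37)  # shrubs
#' classify_plot(47, 5)   # herbaceous
#' @export
classify_plot <- function(vascular_pct, shrub_pct, open_water = FALSE) {
  stopifnot(all(vascular_pct >= 0 & vascular_pct <= 100, na.rm = TRUE),
            all(shrub_pct >= 0 & shrub_pct <= 100, na.rm = TRUE))
  ifelse(open_water, "open_water",
         ifelse(vascular_pct < 20, "bare",
                ifelse(shrub_pct > 20, "shrubs", "herbaceous")))
}

#' Cover-type weights for a sector
#'
#' The relative abundance of each cover type among a sector's survey plots:
#' the count of plots of each type divided by the total number of plots.
#'
#' @param types character vector of plot cover types (one element per plot).
#' @return named numeric vector of proportions summing to 1.
#' @export
cover_weights <- function(types) {
  if (length(types) == 0) stop("a sector needs at least one survey plot")
  tab <- table(types)
  w <- as.numeric(tab) / sum(tab)
  names(w) <- names(tab)
  w
}

#' Cover-weighted sector mean of per-type values
#'
#' @param values named numeric vector of per-cover-type means.
#' @param weights named numeric vector of cover proportions; must cover
#'   exactly the same types and sum to 1.
#' @return the weighted mean.
#' @export
weighted_sector_mean <- function(values, weights) {
  if (!setequal(names(values), names(weights)))
    stop("cover types of values and weights do not match")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  sum(weights[names(values)] * values)
}

#' Mean cover by preferential habitat category and growth form
#'
#' Species observed in the survey plots are mapped to their preferential
#' habitat (peatland, wetland, facultative, other) and growth form (vascular
#' or bryophyte); per sector and category the summed species cover is
#' averaged over all plots of the sector (plots without species of a category
#' contribute zero). Species absent from the lookup are reported with a
#' warning and excluded from the category sums.
#'
#' @param species_cover data.frame with columns `sector_id`, `plot_id`,
#'   `species`, `cover_pct`.
#' @param lookup data.frame with columns `species`, `habitat` (one of
#'   peatland/wetland/facultative/other), `growth_form` (vascular/bryophyte).
#' @return data.frame with `sector_id`, `habitat`, `growth_form`,
#'   `mean_cover_pct`.
#' @export
habitat_summary <- function(species_cover, lookup) {
  plots <- unique(species_cover[, c("sector_id", "plot_id")])
  n_plots <- table(plots$sector_id)
  m <- merge(species_cover, lookup, by = "species", all.x = TRUE)
  unk <- unique(m$species[is.na(m$habitat)])
  if (length(unk)) {
    warning("unclassified species excluded from habitat summary: ",
            paste(unk, collapse = ", "))
    m <- m[!is.na(m$habitat), ]
  }
  if (nrow(m) == 0) {
    return(data.frame(sector_id = character(), habitat = character(),
                      growth_form = character(), mean_cover_pct = numeric()))
  }
  agg <- stats::aggregate(cover_pct ~ sector_id + habitat + growth_form,
                          data = m, FUN = sum)
  agg$mean_cover_pct <- agg$cover_pct / as.numeric(n_plots[as.character(agg$sector_id)])
  agg$cover_pct <- NULL
  agg[order(agg$sector_id, agg$habitat, agg$growth_form), ]
}

#' Vegetation volume index from banded-stick obstruction readings
#'
#' A vertically placed stick painted in bands is read for the percentage of
#' each band obscured by vegetation; several sticks are read per collar and
#' averaged. The index used here is the mean over sticks of the per-stick
#' mean band obstruction (0-100), a relative measure of three-dimensional
#' vegetation density intended as a covariate only.
#'
#' @param stick_readings list with one numeric vector per stick of per-band
#'   percent obscured (0-100).
#' @return index in \[0, 100\].
#' @export
vegetation_volume_index <- function(stick_readings) {
  if (length(stick_readings) == 0) stop("at least one stick reading is required")
  per_stick <- vapply(stick_readings, function(b) {
    if (any(b < 0 | b > 100)) stop("band obstruction values must be in [0, 100]")
    mean(b)
  }, numeric(1))
  mean(per_stick)
}

#' Per-type and cover-weighted sector summary of collar budgets
#'
#' The upscaling step: collar seasonal budgets are grouped by sector and
#' cover type, summarised as mean and standard deviation of NEE, CH4, total C
#' and GWP, and combined into a cover-weighted "ALL" row per sector using the
#' sector's survey-derived cover weights. Weights for cover types without any
#' budgeted collar are dropped and the remainder renormalised (with a
#' warning), so the weighted mean always lies within the range of the
#' per-type means.
#'
#' @param budgets data.frame of collar budgets (as from [collar_budget()])
#'   with additional columns `sector_id` and `cover_type`.
#' @param weights named list: per sector, a named vector of cover-type
#'   proportions (as from [cover_weights()]).
#' @return data.frame in a per-sector layout: one row per cover type with
#'   `n`, mean and sd columns, plus one `ALL` row per sector holding the
#'   weighted means.
#' @export
sector_summary <- function(budgets, weights) {
  fields <- c("nee_total", "ch4_total", "c_total", "gwp")
  out <- list()
  for (sec in sort(unique(budgets$sector_id))) {
    b <- budgets[budgets$sector_id == sec, ]
    w <- weights[[sec]]
    if (is.null(w)) stop("no cover weights for sector ", sec)
    per_type <- lapply(sort(unique(b$cover_type)), function(ct) {
      x <- b[b$cover_type == ct, ]
      row <- data.frame(sector_id = sec, cover_type = ct, n = nrow(x),
                        weight = if (ct %in% names(w)) unname(w[ct]) else NA_real_)
      for (f in fields) {
        row[[paste0(f, "_mean")]] <- mean(x[[f]])
        row[[paste0(f, "_sd")]] <- if (nrow(x) > 1) stats::sd(x[[f]]) else NA_real_
      }
      row
    })
    per_type <- do.call(rbind, per_type)
    w_use <- w[names(w) %in% per_type$cover_type]
    if (length(w_use) < length(w)) {
      warning("sector ", sec, ": dropping cover weights without budgeted collars: ",
              paste(setdiff(names(w), names(w_use)), collapse = ", "))
    }
    if (length(w_use) == 0) stop("sector ", sec, ": no overlap between weights and budgets")
    w_use <- w_use / sum(w_use)
    all_row <- data.frame(sector_id = sec, cover_type = "ALL", n = nrow(b),
                          weight = 1)
    for (f in fields) {
      vals <- stats::setNames(per_type[[paste0(f, "_mean")]], per_type$cover_type)
      all_row[[paste0(f, "_mean")]] <-
        weighted_sector_mean(vals[names(w_use)], w_use)
      sds <- stats::setNames(per_type[[paste0(f, "_sd")]], per_type$cover_type)
      all_row[[paste0(f, "_sd")]] <-
        sum(w_use * sds[names(w_use)], na.rm = TRUE)
    }
    out[[sec]] <- rbind(per_type, all_row)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
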