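#' Rectangular-hyperbola light response
#'
#' GEP = PAR * Q * GPmax / (PAR * Q + GPmax): Q (quantum efficiency) is the
#' initial slope and GPmax the asymptote. Under the uptake-negative sign
#' convention both parameters are negative, GEP is 0 at PAR = 0 and tends to
#' GPmax as PAR grows.
#'
#' @param par_umol PAR photon flux density, umol m^-2 s^-1, >= 0.
#' @param Q quantum efficiency, g CO2 m^-2 d^-1 per umol m^-2 s^-1.
#' @param GPmax asymptotic GEP, g CO2 m^-2 d^-1.
#' @return GEP in g CO2 m^-2 d^-1.
#' @examples
#' predict_gep(500, Q = -0.02, GPmax = -15)  # -6
#' @export
predict_gep <- function(par_umol, Q, GPmax) {
  if (any(par_umol < 0)) stop("PAR must be non-negative")
  denom <- par_umol * Q + GPmax
  if (any(denom == 0))
    stop("light-response pole: PAR * Q + GPmax = 0 (Q and GPmax must share sign)")
  par_umol * Q * GPmax / denom
}

# Small-sample-corrected information criterion from Gaussian residuals.
# k counts the mean parameters plus one for the residual variance.
aicc <- function(rss, n, k) {
  rss <- max(rss, n * 1e-28)           # guard log(0) on exact fits
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the rectangular-hyperbola light response to GEP observations
#'
#' Minimises the sum of squared differences between observed and predicted GEP
#' by Levenberg-Marquardt least squares. Start values are data-driven and
#' deterministic: Q0 is the OLS slope of GEP against PAR over the lowest PAR
#' tertile (falling back to -0.01 if non-negative or undefined) and GPmax0 is
#' 1.2 x the most negative observed GEP.
#'
#' @param par_umol,gep paired observations (PAR in umol m^-2 s^-1, GEP in
#'   g CO2 m^-2 d^-1, uptake negative).
#' @param config pipeline configuration (minimum data requirements).
#' @return list with `Q`, `GPmax`, `n`, `rss`, `rmse`, `ok`. When the data are
#'   insufficient (< `min_gep_n` points or < `min_gep_par_levels` distinct PAR
#'   levels) or the optimiser fails or returns parameters of mixed sign,
#'   `ok` is `FALSE` and the parameters are `NA` (fit-failure signal for
#'   fallback handling).
#' @export
fit_light_response <- function(par_umol, gep, config = default_config()) {
  keep <- !is.na(par_umol) & !is.na(gep)
  par_umol <- par_umol[keep]; gep <- gep[keep]
  fail <- list(Q = NA_real_, GPmax = NA_real_, n = length(gep),
               rss = NA_real_, rmse = NA_real_, ok = FALSE)
  if (length(gep) < config$min_gep_n) return(fail)
  if (length(unique(par_umol)) < config$min_gep_par_levels) return(fail)

  lo <- par_umol <= stats::quantile(par_umol, 1 / 3)
  q0 <- if (sum(lo) >= 2 && stats::var(par_umol[lo]) > 0)
    unname(stats::coef(stats::lm(gep[lo] ~ par_umol[lo]))[2]) else NA_real_
  if (is.na(q0) || q0 >= 0) q0 <- -0.01
  g0 <- 1.2 * min(gep)
  if (g0 >= 0) g0 <- -1

  fit <- tryCatch(
    minpack.lm::nlsLM(gep ~ par_umol * Q * GPmax / (par_umol * Q + GPmax),
                      start = list(Q = q0, GPmax = g0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  if (!(cf[["Q"]] < 0 && cf[["GPmax"]] < 0)) return(fail)
  rss <- sum(stats::resid(fit)^2)
  list(Q = cf[["Q"]], GPmax = cf[["GPmax"]], n = length(gep),
       rss = rss, rmse = sqrt(rss / length(gep)), ok = TRUE)
}

# Season periods: early = May-June, mid = July, late = August-September.
period_of <- function(time) {
  m <- as.integer(format(as_utc(time), "%m"))
  ifelse(m <= 6, "early", ifelse(m == 7, "mid", "late"))
}

# Candidate groupings of the three periods, fewest parts first so that the
# whole-season model wins exact ties on the information criterion.
period_partitions <- function() {
  list(whole     = list(all   = c("early", "mid", "late")),
       early_vs  = list(early = "early", midlate = c("mid", "late")),
       late_vs   = list(earlymid = c("early", "mid"), late = "late"),
       three     = list(early = "early", mid = "mid", late = "late"))
}

#' Choose the seasonal partition for a collar's light-response fits
#'
#' Light-response parameters can drift over the season, so candidate
#' partitions of the season into early (May-June), mid (July) and late
#' (August-September) parts — merged pairwise, split in three, or pooled —
#' are each fitted and scored by a small-sample-corrected information
#' criterion on the pooled residuals (2 parameters per part plus one
#' variance). A candidate is feasible only if every part meets the
#' minimum-data rule. The lowest-criterion feasible candidate wins; ties go
#' to fewer parts.
#'
#' @param gep_obs data.frame with columns `time`, `par_umol_m2_s`, `gep`.
#' @param config pipeline configuration.
#' @return list with `partition` (name), `fits` (one per part, each carrying
#'   its `periods`), `aicc`, and `scores` for all feasible candidates; or
#'   `NULL` when no candidate is feasible (collar unfittable).
#' @export
choose_period_partition <- function(gep_obs, config = default_config()) {
  gep_obs <- gep_obs[!is.na(gep_obs$gep), ]
  per <- period_of(gep_obs$time)
  best <- NULL
  scores <- c()
  for (nm in names(period_partitions())) {
    cand <- period_partitions()[[nm]]
    fits <- list()
    ok <- TRUE
    rss <- 0
    for (part in names(cand)) {
      idx <- per %in% cand[[part]]
      f <- fit_light_response(gep_obs$par_umol_m2_s[idx], gep_obs$gep[idx], config)
      if (!f$ok) { ok <- FALSE; break }
      f$periods <- cand[[part]]
      fits[[part]] <- f
      rss <- rss + f$rss
    }
    if (!ok) next
    k <- 2 * length(cand) + 1
    score <- aicc(rss, nrow(gep_obs), k)
    scores[nm] <- score
    if (is.null(best) || score < best$aicc - 1e-9) {
      best <- list(partition = nm, fits = fits, aicc = score)
    }
  }
  if (is.null(best)) return(NULL)
  best$scores <- scores
  best
}

#' Temperature (and water-table) driven ecosystem respiration
#'
#' Evaluates a fitted respiration model. The linear form is
#' ER = a * T + b * WTL + c with T either air temperature or soil temperature
#' at 5 cm depth and b = 0 when the water-table term was not selected. The
#' exponential form is the Lloyd-Taylor-type relation
#' ER = ERref * exp(E0 * (1/(Tref - T0) - 1/(Tair - T0))) evaluated in Kelvin
#' with Tref = 283.50 K (10.35 C) and T0 = 237.48 K (-35.67 C); ER equals
#' ERref exactly at the reference temperature and increases with temperature
#' for E0 > 0.
#'
#' @param fit a `RespirationFit` list as returned by [fit_er()] (fields
#'   `form`, `temp_source`, `coeffs`, `t_ref_C`, `t0_C`).
#' @param air_temp_C,soil_temp5_C,wtl_cm driver values.
#' @return ER in g CO2 m^-2 d^-1.
#' @export
predict_er <- function(fit, air_temp_C, soil_temp5_C = NULL, wtl_cm = NULL) {
  if (fit$form == "exponential") {
    if (any(air_temp_C <= fit$t0_C))
      stop("air temperature at or below T0: outside the biological-activity domain")
    t_k <- air_temp_C + 273.15
    tref_k <- fit$t_ref_C + 273.15
    t0_k <- fit$t0_C + 273.15
    fit$coeffs[["ERref"]] *
      exp(fit$coeffs[["E0"]] * (1 / (tref_k - t0_k) - 1 / (t_k - t0_k)))
  } else {
    temp <- if (fit$temp_source == "Tair") air_temp_C else soil_temp5_C
    b <- if (fit$uses_wtl) fit$coeffs[["b"]] else 0
    w <- if (fit$uses_wtl) wtl_cm else 0
    fit$coeffs[["a"]] * temp + b * w + fit$coeffs[["c"]]
  }
}

# Build a RespirationFit record.
er_fit_record <- function(form, temp_source, uses_wtl, coeffs, n, rss, config) {
  list(form = form, temp_source = temp_source, uses_wtl = uses_wtl,
       coeffs = coeffs, n = n, rss = rss, rmse = sqrt(rss / n),
       t_ref_C = config$t_ref_C, t0_C = config$t0_C)
}

#' Fit and select a respiration model for one collar
#'
#' Fits the candidate set — the linear form with air or 5 cm soil temperature,
#' each with and without the water-table term, and the exponential
#' Lloyd-Taylor-type form on air temperature (start values ERref0 = mean ER,
#' E0 = 100 K) — and selects by the lowest small-sample-corrected information
#' criterion; exact ties are broken toward fewer parameters and then toward
#' the exponential form. Candidates whose drivers are missing (e.g. no water
#' table data) are skipped.
#'
#' @param er data.frame with columns `er`, `air_temp_C`, `soil_temp5_C`,
#'   `wtl_cm` (the temperature/WTL columns may contain NA; candidates using
#'   them are then dropped).
#' @param config pipeline configuration.
#' @param forms candidate forms to consider: `"linear"`, `"exponential"` or
#'   both (the default). Restricting to one form fits that relationship
#'   without model selection.
#' @return the selected `RespirationFit` (fields `form`, `temp_source`,
#'   `uses_wtl`, `coeffs`, `n`, `rss`, `rmse`, `selection_score`,
#'   `candidates` with every candidate's score), or `NULL` when fewer than
#'   `min_er_n` observations are available (collar unfittable).
#' @export
fit_er <- function(er, config = default_config(),
                   forms = c("linear", "exponential")) {
  forms <- match.arg(forms, several.ok = TRUE)
  er <- er[!is.na(er$er) & !is.na(er$air_temp_C), ]
  if (nrow(er) < config$min_er_n) return(NULL)
  n <- nrow(er)
  cands <- list()

  add_linear <- function(temp_source, uses_wtl) {
    temp <- if (temp_source == "Tair") er$air_temp_C else er$soil_temp5_C
    if (anyNA(temp)) return()
    if (uses_wtl && anyNA(er$wtl_cm)) return()
    df <- if (uses_wtl) data.frame(y = er$er, t = temp, w = er$wtl_cm)
          else data.frame(y = er$er, t = temp)
    fml <- if (uses_wtl) y ~ t + w else y ~ t
    m <- stats::lm(fml, data = df)
    cf <- stats::coef(m)
    coeffs <- c(a = unname(cf[["t"]]),
                b = if (uses_wtl) unname(cf[["w"]]) else 0,
                c = unname(cf[["(Intercept)"]]))
    rec <- er_fit_record("linear", temp_source, uses_wtl, coeffs, n,
                         sum(stats::resid(m)^2), config)
    rec$k <- length(cf) + 1
    cands[[length(cands) + 1]] <<- rec
  }
  if ("linear" %in% forms) {
    add_linear("Tair", FALSE); add_linear("T5", FALSE)
    add_linear("Tair", TRUE);  add_linear("T5", TRUE)
  }

  tref_k <- config$t_ref_C + 273.15
  t0_k <- config$t0_C + 273.15
  d <- data.frame(y = er$er, tk = er$air_temp_C + 273.15)
  expfit <- if (!("exponential" %in% forms)) NULL else tryCatch(
    minpack.lm::nlsLM(y ~ ERref * exp(E0 * (1 / (tref_k - t0_k) - 1 / (tk - t0_k))),
                      data = d,
                      start = list(ERref = mean(er$er), E0 = config$er_e0_start),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(expfit)) {
    cf <- stats::coef(expfit)
    rec <- er_fit_record("exponential", "Tair", FALSE,
                         c(ERref = cf[["ERref"]], E0 = cf[["E0"]]), n,
                         sum(stats::resid(expfit)^2), config)
    rec$k <- 3
    cands[[length(cands) + 1]] <- rec
  }
  if (!length(cands)) return(NULL)

  score <- vapply(cands, function(cc) aicc(cc$rss, n, cc$k), numeric(1))
  k <- vapply(cands, function(cc) cc$k, numeric(1))
  expo <- vapply(cands, function(cc) cc$form == "exponential", logical(1))
  ord <- order(score, k, !expo)          # ties: fewer params, then exponential
  sel <- cands[[ord[1]]]
  sel$selection_score <- score[ord[1]]
  sel$candidates <- data.frame(
    form = vapply(cands, function(cc) cc$form, character(1)),
    temp_source = vapply(cands, function(cc) cc$temp_source, character(1)),
    uses_wtl = vapply(cands, function(cc) cc$uses_wtl, logical(1)),
    aicc = score, k = k)
  sel
}
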