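# Smoothing-spline growth trajectories and absolute/relative growth rates.

#' Fit a smoothing spline to a biomass trajectory
#'
#' Cubic smoothing spline on (day, PFB) with analytic first derivative.
#' Missing PFB values are dropped before fitting. With fewer than four
#' distinct day values all smoothed values and derivatives are `NA` and a
#' warning record is attached (not an error, mirroring standard
#' growth-curve practice).
#'
#' @param days observation days (DAT).
#' @param pfb predicted fresh biomass, g (NA allowed).
#' @param df spline degrees of freedom; default `min(5, n_distinct - 1)`.
#' @return a `pg_growth_spline`: list with `fit` (smooth.spline or NULL),
#'   `days`, `range`, `ok` and `warning`.
#' @export
fit_growth_spline <- function(days, pfb, df = NULL) {
  keep <- is.finite(days) & is.finite(pfb)
  d <- days[keep]; b <- pfb[keep]
  nd <- length(unique(d))
  if (nd < 4) {
    return(structure(list(fit = NULL, days = days, range = range(d, na.rm = TRUE),
                          ok = FALSE,
                          warning = sprintf(
                            "only %d distinct day value(s); smoothed values and derivatives set to NA",
                            nd)),
                     class = "pg_growth_spline"))
  }
  if (is.null(df)) df <- min(5, nd - 1)
  df <- max(2, min(df, nd))
  fit <- smooth.spline(d, b, df = df)
  structure(list(fit = fit, days = days, range = range(d), ok = TRUE,
                 warning = NULL),
            class = "pg_growth_spline")
}

#' Evaluate a growth spline or its derivative
#'
#' @param spline a `pg_growth_spline`.
#' @param at days at which to evaluate.
#' @param deriv 0 for smoothed PFB, 1 for AGR = S'(t).
#' @param extrapolate if `FALSE` (default), evaluation outside the fitted
#'   day range is refused.
#' @return numeric vector (NA-filled if the spline could not be fitted).
#' @export
eval_growth_spline <- function(spline, at, deriv = 0, extrapolate = FALSE) {
  if (!spline$ok) return(rep(NA_real_, length(at)))
  if (!extrapolate &&
      (min(at) < spline$range[1] - 1e-9 || max(at) > spline$range[2] + 1e-9)) {
    pg_stop("range", "evaluation day outside fitted range [",
            spline$range[1], ", ", spline$range[2], "]; extrapolation refused")
  }
  predict(spline$fit, at, deriv = deriv)$y
}

#' Interval absolute growth rate
#'
#' `AGR(tj, tk) = (PFB(tk) - PFB(tj)) / (tk - tj)` in g/d.
#'
#' @param pfb_tj,pfb_tk biomass at the window endpoints, g.
#' @param tj,tk window endpoints, days, `tk > tj`.
#' @export
agr_interval <- function(pfb_tj, pfb_tk, tj, tk) {
  if (any(tk <= tj)) pg_stop("input", "agr_interval: need tk > tj")
  (pfb_tk - pfb_tj) / (tk - tj)
}

#' Interval relative growth rate
#'
#' `RGR(tj, tk) = (ln PFB(tk) - ln PFB(tj)) / (tk - tj)` in g/g/d; constant
#' and equal to the rate parameter under exponential growth.
#'
#' @inheritParams agr_interval
#' @export
rgr_interval <- function(pfb_tj, pfb_tk, tj, tk) {
  if (any(tk <= tj)) pg_stop("input", "rgr_interval: need tk > tj")
  if (any(pfb_tj <= 0) || any(pfb_tk <= 0)) {
    pg_stop("domain", "rgr_interval: PFB must be > 0")
  }
  (log(pfb_tk) - log(pfb_tj)) / (tk - tj)
}

#' Windowed growth rates for all plants
#'
#' Fits a smoothing spline per plant, evaluates smoothed PFB at the window
#' endpoints and applies the interval AGR/RGR formulas. Default windows are
#' 2-6, 5-12 and 2-12 DAT.
#'
#' @param pfb data.frame `plant_id`, `day`, `pfb` (from [predict_biomass()]).
#' @param windows list of `c(tj, tk)` windows, `tk > tj`, endpoints within
#'   the observed day range.
#' @param df spline degrees of freedom (see [fit_growth_spline()]).
#' @param pfb_floor biomass floor applied before logs, g.
#' @return data.frame `plant_id`, `tj`, `tk`, `window`, `AGR`, `RGR` (NA for
#'   plants whose spline could not be fitted).
#' @export
windowed_rates <- function(pfb, windows = list(c(2, 6), c(5, 12), c(2, 12)),
                           df = NULL, pfb_floor = 0.01) {
  check_cols(pfb, c("plant_id", "day", "pfb"), "pfb table")
  for (wd in windows) {
    if (length(wd) != 2 || wd[2] <= wd[1]) {
      pg_stop("input", "degenerate window (", paste(wd, collapse = ", "), ")")
    }
  }
  ids <- unique(pfb$plant_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- pfb[pfb$plant_id == ids[i], ]
    sp <- fit_growth_spline(sub$day, sub$pfb, df = df)
    rows <- lapply(windows, function(wd) {
      if (sp$ok) {
        ends <- pmax(eval_growth_spline(sp, wd), pfb_floor)
        data.frame(plant_id = ids[i], tj = wd[1], tk = wd[2],
                   window = paste0(wd[1], "-", wd[2]),
                   AGR = agr_interval(ends[1], ends[2], wd[1], wd[2]),
                   RGR = rgr_interval(ends[1], ends[2], wd[1], wd[2]),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(plant_id = ids[i], tj = wd[1], tk = wd[2],
                   window = paste0(wd[1], "-", wd[2]),
                   AGR = NA_real_, RGR = NA_real_, stringsAsFactors = FALSE)
      }
    })
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Smoothed growth series for one plant
#'
#' Convenience accessor returning smoothed PFB, AGR(t) = S'(t) and
#' RGR(t) = S'(t)/S(t) at each observed day.
#'
#' @inheritParams windowed_rates
#' @param plant_id plant to extract.
#' @return data.frame `day`, `pfb`, `pfb_smooth`, `AGR`, `RGR`.
#' @export
growth_series <- function(pfb, plant_id, df = NULL, pfb_floor = 0.01) {
  sub <- pfb[pfb$plant_id == plant_id, ]
  if (!nrow(sub)) pg_stop("input", "unknown plant_id: ", plant_id)
  sp <- fit_growth_spline(sub$day, sub$pfb, df = df)
  s <- eval_growth_spline(sp, sub$day, 0)
  d1 <- eval_growth_spline(sp, sub$day, 1)
  data.frame(day = sub$day, pfb = sub$pfb, pfb_smooth = s, AGR = d1,
             RGR = d1 / pmax(s, pfb_floor))
}
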