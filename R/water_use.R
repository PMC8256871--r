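# Water bookkeeping: field capacity, daily/cumulative water use, %FC
# trajectories, and the three water-use indices. Water use as recorded
# includes both transpiration and soil evaporation (no bare-pot correction);
# 1 g of water is treated as 1 ml.

#' Gravimetric field capacity
#'
#' @param dry_weight dry pot weight (pot + dry soil), g.
#' @param saturated_drained_weight weight after capillary saturation and free
#'   drainage, g.
#' @return list with `fc` (water mass held at field capacity, g) and
#'   `target_weight(f)`, a function giving the pot target weight at a
#'   fraction `f` of field capacity.
#' @examples
#' fc <- field_capacity(14000, 17500)
#' fc$fc                    # 3500 g
#' fc$target_weight(0.8)    # 16800 g
#' @export
field_capacity <- function(dry_weight, saturated_drained_weight) {
  if (saturated_drained_weight < dry_weight) {
    pg_stop("range", "field_capacity: saturated weight below dry weight")
  }
  fc <- saturated_drained_weight - dry_weight
  list(fc = fc,
       target_weight = function(f) dry_weight + f * fc)
}

#' Daily and cumulative water use from a watering ledger
#'
#' Water use on day d is the evapotranspiration between waterings:
#' `WU(d) = weight_after(d-1) - weight_before(d)`. Gaps in the day sequence
#' are handled by spreading the observed loss uniformly over the missing
#' days (flagged in `gap_filled`). Negative computed values beyond `tol` are
#' floored at 0 and flagged in `quality_flag`.
#'
#' @param ledger a [pg_ledger].
#' @param tol tolerance (ml) before a negative WU is flagged.
#' @return data.frame `pot_id`, `day`, `WU` (ml/d), `WUCum` (ml),
#'   `gap_filled`, `quality_flag`. `WUCum` is the running sum from the first
#'   ledger day and is non-decreasing.
#' @export
daily_water_use <- function(ledger, tol = 2) {
  out <- list()
  for (pid in unique(ledger$pot_id)) {
    sub <- ledger[ledger$pot_id == pid, ]
    sub <- sub[order(sub$day), ]
    days_all <- seq(min(sub$day), max(sub$day))
    wu <- rep(NA_real_, length(days_all))
    gap <- flag <- rep(FALSE, length(days_all))
    names(wu) <- days_all
    for (i in seq_len(nrow(sub))[-1]) {
      loss <- sub$weight_after_g[i - 1] - sub$weight_before_g[i]
      span <- sub$day[i] - sub$day[i - 1]
      if (loss < -tol) {
        loss <- 0
        flag[days_all %in% ((sub$day[i - 1] + 1):sub$day[i])] <- TRUE
      }
      loss <- max(loss, 0)
      target_days <- (sub$day[i - 1] + 1):sub$day[i]
      wu[as.character(target_days)] <- loss / span
      if (span > 1) gap[days_all %in% target_days] <- TRUE
    }
    wu[is.na(wu)] <- 0
    out[[pid]] <- data.frame(pot_id = pid, day = days_all, WU = wu,
                             WUCum = cumsum(wu), gap_filled = gap,
                             quality_flag = flag, stringsAsFactors = FALSE,
                             row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Percent-of-field-capacity trajectory
#'
#' `%FC(d) = 100 * (weight_before(d) - tare - dry_soil) / FC`.
#'
#' @param ledger a [pg_ledger].
#' @param fc field-capacity water mass, g.
#' @param dry_soil_weight,tare pot constants, g; taken from the ledger's
#'   `pot_constants` attribute when omitted.
#' @return data.frame `pot_id`, `day`, `percent_fc`, `negative_flag`.
#' @export
percent_fc_series <- function(ledger, fc, dry_soil_weight = NULL,
                              tare = NULL) {
  if (fc <= 0) pg_stop("input", "percent_fc_series: fc must be > 0")
  pc <- attr(ledger, "pot_constants")
  df <- as.data.frame(ledger)
  if (is.null(dry_soil_weight) || is.null(tare)) {
    if (is.null(pc)) {
      pg_stop("input", "supply dry_soil_weight and tare or a ledger with pot constants")
    }
    df <- merge(df, pc, by = "pot_id")
    tare_v <- df$tare_g; dry_v <- df$dry_soil_g
  } else {
    tare_v <- tare; dry_v <- dry_soil_weight
  }
  pfc <- 100 * (df$weight_before_g - tare_v - dry_v) / fc
  data.frame(pot_id = df$pot_id, day = df$day, percent_fc = pfc,
             negative_flag = pfc < 0, stringsAsFactors = FALSE)
}

#' Water-use indices
#'
#' Three indices of productive water use:
#' \itemize{
#'   \item `wui_bm`: `1000 * PFB / WUCum`, mg biomass per ml of cumulative
#'     water, so that `wui_bm * WUCum / 1000 = PFB` exactly;
#'   \item `wui_agr`: window AGR per ml of water used within the window,
#'     g/d/ml;
#'   \item `wui_rgr`: window RGR per ml of water used within the window,
#'     g/g/d/ml.
#' }
#'
#' @param pfb predicted fresh biomass on the day, g.
#' @param wucum cumulative water use up to the day, ml (> 0).
#' @param agr,rgr window growth rates.
#' @param wu_interval water used within the window, ml (> 0).
#' @return numeric index value(s).
#' @export
wui_bm <- function(pfb, wucum) {
  if (any(wucum <= 0)) pg_stop("domain", "wui_bm: WUCum must be > 0")
  1000 * pfb / wucum
}

#' @rdname wui_bm
#' @export
wui_agr <- function(agr, wu_interval) {
  if (any(wu_interval <= 0)) pg_stop("domain", "wui_agr: window WU must be > 0")
  agr / wu_interval
}

#' @rdname wui_bm
#' @export
wui_rgr <- function(rgr, wu_interval) {
  if (any(wu_interval <= 0)) pg_stop("domain", "wui_rgr: window WU must be > 0")
  rgr / wu_interval
}

#' Per-plant water-use index table
#'
#' Combines PFB, windowed growth rates and the water series into the three
#' indices per plant and window: `WUI_BM` uses PFB and WUCum at the window
#' end; `WUI_AGR`/`WUI_RGR` divide the window growth rates by the water used
#' within the window.
#'
#' @param pfb data.frame `plant_id`, `day`, `pfb`.
#' @param rates output of [windowed_rates()].
#' @param water output of [daily_water_use()] (pot_id = plant_id).
#' @return data.frame `plant_id`, `window`, `tj`, `tk`, `WUI_BM` (mg/ml),
#'   `WUI_AGR`, `WUI_RGR`.
#' @export
wui_table <- function(pfb, rates, water) {
  out <- rates
  out$WUI_BM <- out$WUI_AGR <- out$WUI_RGR <- NA_real_
  for (i in seq_len(nrow(out))) {
    pid <- out$plant_id[i]; tj <- out$tj[i]; tk <- out$tk[i]
    ws <- water[water$pot_id == pid, ]
    pw <- pfb[pfb$plant_id == pid, ]
    wucum_tk <- ws$WUCum[match(tk, ws$day)]
    wu_win <- sum(ws$WU[ws$day > tj & ws$day <= tk])
    pfb_tk <- pw$pfb[match(tk, pw$day)]
    if (length(wucum_tk) == 1 && is.finite(wucum_tk) && wucum_tk > 0 &&
        length(pfb_tk) == 1 && is.finite(pfb_tk)) {
      out$WUI_BM[i] <- wui_bm(pfb_tk, wucum_tk)
    }
    if (is.finite(wu_win) && wu_win > 0) {
      if (is.finite(out$AGR[i])) out$WUI_AGR[i] <- wui_agr(out$AGR[i], wu_win)
      if (is.finite(out$RGR[i])) out$WUI_RGR[i] <- wui_rgr(out$RGR[i], wu_win)
    }
  }
  out[, c("plant_id", "window", "tj", "tk", "AGR", "RGR",
          "WUI_BM", "WUI_AGR", "WUI_RGR")]
}
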