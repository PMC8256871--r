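# End-to-end protocol orchestration: data acquisition (synthetic or files),
# model comparison and selection, per-day biomass prediction, growth rates,
# water-use indices, heritability and genotype comparison.

fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' @param simulate `NULL` or a [sim_config()] (or list of its arguments) for
#'   a synthetic run.
#' @param inputs `NULL` or list of file paths: `design`, `features`,
#'   `watering`, `biomass` (+ optional `days` for the design).
#' @param resample a [resample_spec()] or list of its arguments.
#' @param families model families to compare.
#' @param growth_windows list of `c(tj, tk)` windows.
#' @param h2_window `c(first, last)` DAT window for heritability (first
#'   three weeks of stress by default).
#' @param wui_window which growth window feeds the genotype comparison.
#' @param alpha significance level for the Duncan test.
#' @param outdir output directory (`NULL`: keep results in memory only).
#' @param seed master seed; every stage derives its own stream from it.
#' @return a `pg_pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(), inputs = NULL,
                            resample = resample_spec(),
                            families = PG_FAMILIES,
                            growth_windows = list(c(2, 6), c(5, 12), c(2, 12)),
                            h2_window = c(1, 21),
                            wui_window = c(2, 12),
                            alpha = 0.05, outdir = NULL, seed = 1L) {
  if (is.null(simulate) && is.null(inputs)) {
    pg_stop("config", "pipeline: supply either a simulate block or input paths")
  }
  if (!is.null(simulate) && !inherits(simulate, "pg_sim_config")) {
    simulate <- do.call(sim_config, simulate)
  }
  if (!inherits(resample, "pg_resample_spec")) {
    resample <- do.call(resample_spec, resample)
  }
  if (!is.null(inputs)) {
    need <- c("design", "features", "watering", "biomass")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) {
      pg_stop("config", "pipeline inputs missing: ",
              paste(miss, collapse = ", "))
    }
  }
  structure(list(simulate = simulate, inputs = inputs, resample = resample,
                 families = toupper(families),
                 growth_windows = growth_windows, h2_window = h2_window,
                 wui_window = wui_window, alpha = alpha, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pg_pipeline_config")
}

daily_wui_traits <- function(pfb, water, design, days) {
  ids <- unique(pfb$plant_id)
  rows <- vector("list", length(ids))
  meta <- as.data.frame(design)
  for (i in seq_along(ids)) {
    gs <- tryCatch(growth_series(pfb, ids[i]), error = function(e) NULL)
    if (is.null(gs)) next
    ws <- water[water$pot_id == ids[i], ]
    d <- intersect(intersect(gs$day, ws$day), days)
    d <- d[d > min(water$day)]
    gi <- match(d, gs$day); wi <- match(d, ws$day)
    ok <- ws$WUCum[wi] > 0 & ws$WU[wi] > 0
    m <- meta[meta$plant_id == ids[i], ]
    rows[[i]] <- data.frame(
      plant_id = ids[i], genotype = m$genotype, treatment = m$treatment,
      replicate = m$replicate, DAT = d,
      WUI_BM = ifelse(ok, 1000 * gs$pfb_smooth[gi] / ws$WUCum[wi], NA),
      WUI_AGR = ifelse(ok, gs$AGR[gi] / ws$WU[wi], NA),
      WUI_RGR = ifelse(ok, gs$RGR[gi] / ws$WU[wi], NA),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the full phenotyping pipeline
#'
#' Executes, in order: data acquisition (synthetic experiment or CSV inputs),
#' model-family evaluation on harvest-day features, model selection, a final
#' 10-fold cross-validation check, per-day biomass prediction, windowed
#' growth rates, water-use series and indices, broad-sense heritability of
#' the daily WUI traits over the configured window, and Duncan genotype
#' comparisons of the windowed traits. Deterministic under a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @return a `pg_run_report` list: `data`, `evaluation`, `summary_tables`,
#'   `selection`, `cv_final`, `pfb`, `rates`, `water`, `wui`, `heritability`,
#'   `comparisons`, `provenance`. When `config$outdir` is set, the report
#'   tables are also written as CSV/JSON files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pg_pipeline_config"))
  log_stage <- function(...) message("[phenogrowth] ", ...)

  # stage 1: data
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- config$seed
    cfg <- do.call(sim_config, unclass(sim)[names(unclass(sim)) %in%
                                              names(formals(sim_config))])
    dat <- simulate_experiment(cfg)
    log_stage("simulated ", nrow(dat$design), " pots x ",
              length(attr(dat$design, "days")), " days")
  } else {
    design <- read_design(config$inputs$design, days = config$inputs$days)
    dat <- list(design = design,
                features = read_feature_table(config$inputs$features),
                ledger = read_watering_ledger(config$inputs$watering, design),
                biomass = read_biomass_table(config$inputs$biomass, design),
                truth = NULL)
    log_stage("loaded ", nrow(dat$design), " pots")
  }

  # stage 2-3: model evaluation and selection
  rs <- config$resample
  rs$seed <- (config$seed * 7 + 1) %% .Machine$integer.max
  evaluation <- evaluate_models(dat$features, dat$biomass, rs,
                                families = config$families)
  selection <- select_model(evaluation)
  log_stage("selected ", selection$family, ": ", selection$rationale)

  # stage 4: final cross-validation check
  jd <- join_harvest(dat$features, dat$biomass)
  cv_final <- crossvalidate_final(selection, jd$X, jd$y,
                                  k = min(10, nrow(jd$X)),
                                  seed = (config$seed * 7 + 2) %%
                                    .Machine$integer.max)

  # stage 5: per-day biomass
  pfb <- predict_biomass(selection$final_model, dat$features)
  log_stage("predicted biomass for ", nrow(pfb), " plant-days")

  # stage 6: growth rates (windows outside the observed day range are dropped)
  days_obs <- range(attr(dat$design, "days"))
  windows <- Filter(function(w) w[1] >= days_obs[1] && w[2] <= days_obs[2],
                    config$growth_windows)
  if (!length(windows)) {
    pg_stop("config", "no growth window fits the observed day range [",
            days_obs[1], ", ", days_obs[2], "]")
  }
  if (length(windows) < length(config$growth_windows)) {
    log_stage("dropped ", length(config$growth_windows) - length(windows),
              " growth window(s) outside the observed day range")
  }
  rates <- windowed_rates(pfb, windows = windows)

  # stage 7: water use and indices
  water <- daily_water_use(dat$ledger)
  wui <- wui_table(pfb, rates, water)

  # stage 8: heritability of daily WUI traits
  h2_days <- seq(config$h2_window[1], config$h2_window[2])
  h2_days <- intersect(h2_days, attr(dat$design, "days"))
  traits <- daily_wui_traits(pfb, water, dat$design, h2_days)
  heritability <- list()
  for (tn in c("WUI_BM", "WUI_AGR", "WUI_RGR")) {
    td <- data.frame(genotype = traits$genotype, treatment = traits$treatment,
                     replicate = traits$replicate, DAT = traits$DAT,
                     value = traits[[tn]], stringsAsFactors = FALSE)
    heritability[[tn]] <- tryCatch(heritability_report(td, tn),
                                   error = function(e) {
                                     log_stage("heritability ", tn,
                                               " failed: ",
                                               conditionMessage(e))
                                     NULL
                                   })
  }

  # stage 9: genotype comparisons (Duncan letters) per treatment
  wlab <- paste0(config$wui_window[1], "-", config$wui_window[2])
  if (!wlab %in% wui$window) wlab <- wui$window[which.max(wui$tk - wui$tj)]
  meta <- as.data.frame(dat$design)
  wsub <- merge(wui[wui$window == wlab, ], meta, by = "plant_id")
  comparisons <- list()
  for (trt in unique(wsub$treatment)) {
    sub <- wsub[wsub$treatment == trt, ]
    comparisons[[trt]] <- lapply(
      setNames(nm = c("AGR", "RGR", "WUI_BM", "WUI_AGR", "WUI_RGR")),
      function(tn) duncan_mrt(sub[[tn]], sub$genotype, alpha = config$alpha))
  }

  cfg_for_hash <- config; cfg_for_hash$outdir <- NULL
  report <- structure(list(
    data = dat, evaluation = evaluation,
    summary_tables = summary_table(evaluation), selection = selection,
    cv_final = cv_final, pfb = pfb, rates = rates, water = water, wui = wui,
    heritability = heritability, comparisons = comparisons,
    provenance = list(seed = config$seed,
                      config_hash = fnv1a_hash(cfg_for_hash),
                      package_version = as.character(
                        utils::packageVersion("phenogrowth")))),
    class = "pg_run_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(report$data$features, file.path(outdir, "features.csv"))
  write.csv(report$pfb, file.path(outdir, "pfb.csv"), row.names = FALSE)
  write.csv(report$rates, file.path(outdir, "growth.csv"), row.names = FALSE)
  write.csv(report$water, file.path(outdir, "water.csv"), row.names = FALSE)
  write.csv(report$wui, file.path(outdir, "wui.csv"), row.names = FALSE)
  for (m in names(report$summary_tables)) {
    tb <- report$summary_tables[[m]]
    write.csv(cbind(model = rownames(tb), tb),
              file.path(outdir, paste0("table1_", m, ".csv")),
              row.names = FALSE)
  }
  h2 <- lapply(report$heritability, function(h) {
    if (is.null(h)) return(NULL)
    list(H2_standard = h$H2_standard, H2_cullis = h$H2_cullis,
         H2_piepho = h$H2_piepho)
  })
  payload <- list(
    selection = list(family = report$selection$family,
                     complexity = report$selection$complexity,
                     rationale = report$selection$rationale),
    cv_final = list(cv_ss = report$cv_final$cv_ss,
                    p_value = report$cv_final$f_test$p.value),
    heritability = h2,
    provenance = report$provenance)
  jsonlite::write_json(payload, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' Rank genotypes by a derived trait
#'
#' @param report a `pg_run_report`.
#' @param trait one of `"AGR"`, `"RGR"`, `"WUI_BM"`, `"WUI_AGR"`,
#'   `"WUI_RGR"`.
#' @param treatment treatment subset to rank within.
#' @return data.frame `genotype`, `mean`, `n`, `letters`, sorted by
#'   decreasing mean (ties: stable by genotype id).
#' @export
rank_genotypes <- function(report, trait, treatment) {
  stopifnot(inherits(report, "pg_run_report"))
  cmp <- report$comparisons[[treatment]]
  if (is.null(cmp)) pg_stop("lookup", "no comparisons for treatment '",
                            treatment, "'")
  d <- cmp[[trait]]
  if (is.null(d)) pg_stop("lookup", "unknown trait '", trait, "'")
  out <- as.data.frame(d)
  names(out)[names(out) == "group"] <- "genotype"
  out
}
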