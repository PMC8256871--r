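# Synthetic pot-phenotyping experiments with known ground truth.
#
# The generator emulates the layout of a greenhouse pot trial: G genotypes x
# 2 water treatments x R replicate pots, imaged daily. Latent shoot biomass
# follows logistic growth (exponential mode available for analytic growth-rate
# checks); stressed pots grow at a reduced rate; watering tops pots up to a
# %-field-capacity target weight; image features are noisy allometric
# transforms of latent biomass.

#' Simulation configuration
#'
#' Defaults mirror a 24-genotype, 2-treatment, 3-replicate trial observed
#' daily for 26 days (0..25 DAT) with pots of 14 kg dry soil holding 3.5 kg
#' of water at field capacity, watered to 80% (well-watered) or 50%
#' (water-stressed) of field capacity.
#'
#' @param n_genotypes,n_reps,n_days experiment dimensions; days run 0..n_days-1.
#' @param growth_model `"logistic"` or `"exponential"`.
#' @param base_rate intrinsic growth rate, d^-1.
#' @param initial_biomass_g,max_biomass_g logistic start and asymptote, g.
#' @param treatment_growth_multiplier multiplier in (0, 1] applied to the
#'   growth rate of water-stressed pots.
#' @param genotype_rate_sd SD of per-genotype log growth-rate effects.
#' @param residual_sd per plant-day lognormal noise SD on the biomass signal
#'   (fraction of signal).
#' @param feature_noise_sd additional per-feature lognormal noise SD.
#' @param transpiration_coeff ml water per g biomass per day.
#' @param evaporation_ml_per_day soil surface evaporation, ml/d.
#' @param fc_target named list, watering targets as fraction of field
#'   capacity per treatment.
#' @param tare_g,dry_soil_g,fc_water_g pot constants, g.
#' @param planted_genotype,planted_effect optionally force one genotype's
#'   log-rate effect to `planted_effect` (in units of `genotype_rate_sd`),
#'   e.g. +3 to plant a clearly superior genotype for recovery tests.
#' @param seed integer RNG seed; a fixed seed gives identical output.
#' @return a `pg_sim_config` list.
#' @export
sim_config <- function(n_genotypes = 24, n_reps = 3, n_days = 26,
                       growth_model = c("logistic", "exponential"),
                       base_rate = log(7) / 25,
                       initial_biomass_g = 5, max_biomass_g = 40,
                       treatment_growth_multiplier = 0.45,
                       genotype_rate_sd = 0.15,
                       residual_sd = 0.05, feature_noise_sd = 0.05,
                       transpiration_coeff = 10, evaporation_ml_per_day = 50,
                       fc_target = list(well_watered = 0.8,
                                        water_stressed = 0.5),
                       tare_g = 500, dry_soil_g = 14000, fc_water_g = 3500,
                       planted_genotype = NULL, planted_effect = NULL,
                       seed = 1L) {
  growth_model <- match.arg(growth_model)
  cfg <- as.list(environment())
  num <- c("n_genotypes", "n_reps", "n_days", "base_rate", "initial_biomass_g",
           "max_biomass_g", "treatment_growth_multiplier",
           "transpiration_coeff", "evaporation_ml_per_day", "tare_g",
           "dry_soil_g", "fc_water_g")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      pg_stop("config", "sim_config: ", f, " must be a positive scalar")
    }
  }
  for (f in c("genotype_rate_sd", "residual_sd", "feature_noise_sd")) {
    if (cfg[[f]] < 0) pg_stop("config", "sim_config: ", f, " must be >= 0")
  }
  if (cfg$treatment_growth_multiplier > 1) {
    pg_stop("config", "sim_config: treatment_growth_multiplier must be in (0, 1]")
  }
  if (any(unlist(fc_target) <= 0) || any(unlist(fc_target) > 1)) {
    pg_stop("config", "sim_config: fc_target fractions must be in (0, 1]")
  }
  if (cfg$initial_biomass_g >= cfg$max_biomass_g) {
    pg_stop("config", "sim_config: initial biomass must be below the asymptote")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pg_sim_config")
}

latent_biomass <- function(cfg, rate, days) {
  B0 <- cfg$initial_biomass_g
  if (cfg$growth_model == "exponential") {
    return(B0 * exp(rate * days))
  }
  K <- cfg$max_biomass_g
  K / (1 + ((K - B0) / B0) * exp(-rate * days))
}

# allometric feature links: projected areas scale as B^(2/3), linear sizes as
# B^(1/3), perimeters as sqrt(area); shape ratios are roughly constant.
feature_links <- function(B, twf, view) {
  area_coef <- c(top = 900, side0 = 700, side90 = 720)[[view]]
  lin_coef <- c(top = 55, side0 = 60, side90 = 60)[[view]]
  area <- area_coef * B^(2 / 3)
  height <- lin_coef * B^(1 / 3)
  width <- 0.9 * lin_coef * B^(1 / 3)
  perim <- 4.5 * sqrt(area)
  solidity <- 0.7
  list(
    area = area,
    hull_area = area / solidity,
    perimeter = perim,
    hull_perimeter = 0.85 * perim,
    width = width,
    height = height,
    caliper = 1.25 * pmax(width, height),
    compactness = 4 * pi * area / perim^2,
    eccentricity = 0.6,
    centroid_y = 1200 - 0.5 * height,
    solidity = solidity,
    aspect_ratio = width / height,
    extent = area / (width * height),
    eq_diameter = 2 * sqrt(area / pi),
    # NIR mean gray: inversely affine in tissue-water fraction (drier = brighter)
    mean_gray = pmin(255, pmax(0, 320 - 170 * twf))
  )
}

#' Simulate a complete pot-phenotyping experiment
#'
#' Generates the experiment design, a daily image-feature table, a watering
#' ledger, a harvest-day biomass table and the latent ground truth.
#'
#' Latent biomass of pot p (genotype g, treatment t) on day d is
#' `B(d) = K / (1 + ((K - B0)/B0) * exp(-r * d))` with
#' `r = base_rate * exp(u_g) * m_t`, where `u_g ~ N(0, genotype_rate_sd^2)`
#' and `m_t` is 1 for well-watered pots and `treatment_growth_multiplier`
#' for stressed pots. Daily water use is `transpiration_coeff * B(d) +
#' evaporation + noise`; pots are watered back to their %FC target weight.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `design` ([pg_design]), `features`
#'   ([pg_features]), `ledger` ([pg_ledger]), `biomass` ([pg_biomass]) and
#'   `truth` (list: per-pot latent `biomass` matrix pots x days,
#'   `biomass_observed` = latent biomass with the per-observation signal
#'   noise applied, per-pot `rate`, `genotype_effects`, daily `water_use`
#'   matrix, `twf` tissue-water fraction matrix, and the `config`).
#' @examples
#' sim <- simulate_experiment(sim_config(n_genotypes = 4, n_days = 8, seed = 7))
#' nrow(sim$features)  # 4 genotypes x 2 treatments x 3 reps x 8 days
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "pg_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genotypes; R <- cfg$n_reps
  days <- seq_len(cfg$n_days) - 1L
  genos <- sprintf("G%02d", seq_len(G))
  treats <- c("well_watered", "water_stressed")

  u_g <- rnorm(G, 0, cfg$genotype_rate_sd)
  names(u_g) <- genos
  if (!is.null(cfg$planted_genotype)) {
    idx <- if (is.character(cfg$planted_genotype)) {
      match(cfg$planted_genotype, genos)
    } else as.integer(cfg$planted_genotype)
    u_g[idx] <- cfg$planted_effect * max(cfg$genotype_rate_sd, 1e-8)
  }

  plants <- expand.grid(replicate = seq_len(R), treatment = treats,
                        genotype = genos, stringsAsFactors = FALSE)
  plants <- plants[, c("genotype", "treatment", "replicate")]
  plants$plant_id <- sprintf("%s_%s_r%d", plants$genotype,
                             ifelse(plants$treatment == "well_watered", "C", "S"),
                             plants$replicate)
  design <- pg_design(plants, days)
  n_p <- nrow(plants)

  mult <- ifelse(plants$treatment == "water_stressed",
                 cfg$treatment_growth_multiplier, 1)
  rate <- cfg$base_rate * exp(u_g[plants$genotype]) * mult
  B <- t(vapply(rate, function(r) latent_biomass(cfg, r, days),
                numeric(length(days))))
  dimnames(B) <- list(plants$plant_id, days)

  # tissue-water fraction: declines with soil moisture target and stress time
  fc_frac <- vapply(plants$treatment, function(tr) cfg$fc_target[[tr]],
                    numeric(1))
  twf <- outer(0.3 * fc_frac + 0.56, rep(1, length(days))) -
    outer(ifelse(plants$treatment == "water_stressed", 1, 0),
          0.002 * days)

  # feature table -------------------------------------------------------------
  signal_noise <- matrix(exp(rnorm(n_p * length(days), 0, cfg$residual_sd)),
                         n_p, length(days))
  B_obs <- B * signal_noise
  reg <- pg_feature_registry()
  feat <- data.frame(plant_id = rep(plants$plant_id, each = length(days)),
                     day = rep(days, n_p), stringsAsFactors = FALSE)
  for (v in reg$views) {
    links <- feature_links(as.vector(t(B_obs)), as.vector(t(twf)), v)
    for (nm in names(links)) {
      noise <- exp(rnorm(nrow(feat), 0, cfg$feature_noise_sd))
      feat[[paste(nm, v, sep = ".")]] <- links[[nm]] * noise
    }
  }
  features <- pg_features(feat)

  # watering ledger ------------------------------------------------------------
  target_w <- cfg$tare_g + cfg$dry_soil_g + fc_frac * cfg$fc_water_g
  wu_true <- matrix(0, n_p, length(days), dimnames = dimnames(B))
  rows <- vector("list", n_p)
  for (i in seq_len(n_p)) {
    before <- after <- water <- numeric(length(days))
    w_after_prev <- target_w[i]
    before[1] <- after[1] <- target_w[i]; water[1] <- 0
    for (j in seq_along(days)[-1]) {
      use <- cfg$transpiration_coeff * B[i, j - 1] +
        cfg$evaporation_ml_per_day +
        rnorm(1, 0, 0.02 * cfg$evaporation_ml_per_day)
      use <- min(max(use, 0), w_after_prev - cfg$tare_g - cfg$dry_soil_g)
      wu_true[i, j] <- use
      before[j] <- w_after_prev - use
      water[j] <- max(0, target_w[i] - before[j])
      after[j] <- before[j] + water[j]
      w_after_prev <- after[j]
    }
    rows[[i]] <- data.frame(pot_id = plants$plant_id[i], day = days,
                            weight_before_g = before, weight_after_g = after,
                            water_added_ml = water, stringsAsFactors = FALSE)
  }
  pot_constants <- data.frame(pot_id = plants$plant_id, tare_g = cfg$tare_g,
                              dry_soil_g = cfg$dry_soil_g,
                              stringsAsFactors = FALSE)
  ledger <- pg_ledger(do.call(rbind, rows), pot_constants = pot_constants)

  # harvest biomass -------------------------------------------------------------
  fw <- B[, length(days)] * exp(rnorm(n_p, 0, cfg$residual_sd))
  biomass <- pg_biomass(data.frame(plant_id = plants$plant_id,
                                   fresh_weight_g = fw,
                                   dry_weight_g = 0.15 * fw,
                                   harvest_day = days[length(days)],
                                   stringsAsFactors = FALSE))

  list(design = design, features = features, ledger = ledger,
       biomass = biomass,
       truth = list(biomass = B, biomass_observed = B_obs,
                    rate = setNames(rate, plants$plant_id),
                    genotype_effects = u_g, water_use = wu_true, twf = twf,
                    config = cfg))
}

#' Render synthetic plant-view images
#'
#' Draws a green elliptical blob of the requested projected area over a
#' uniform background for the RGB views, and the matching NIR views in which
#' foreground pixels carry the requested mean gray level. The foreground is
#' rasterised by taking exactly the requested number of pixels closest (in
#' scaled ellipse distance) to the blob centre, so drawn area matches the
#' request to the pixel.
#'
#' @param state list with elements `area` (named numeric, requested projected
#'   area in px per view: top, side0, side90), `aspect` (height/width ratio of
#'   the side-view blob, default 2) and `mean_gray` (target NIR foreground
#'   gray, 8-bit scale).
#' @param canvas_size integer c(height, width) in px.
#' @param salt_noise number of isolated foreground pixels to sprinkle over
#'   the background (0 = clean image).
#' @return named list of six images: `rgb_top`, `rgb_side0`, `rgb_side90`
#'   (h x w x 3 arrays in [0,1]) and `nir_top`, `nir_side0`, `nir_side90`
#'   (h x w matrices in [0,1]; multiply by 255 for the 8-bit scale).
#' @export
render_plant_images <- function(state, canvas_size = c(256, 256),
                                salt_noise = 0) {
  h <- canvas_size[1]; w <- canvas_size[2]
  if (any(unlist(state$area) > 0.95 * h * w)) {
    pg_stop("size", "render: requested area exceeds canvas")
  }
  aspect <- if (is.null(state$aspect)) 2 else state$aspect
  gray <- if (is.null(state$mean_gray)) 180 else state$mean_gray
  out <- list()
  for (v in c("top", "side0", "side90")) {
    area <- round(state$area[[v]])
    mask <- matrix(FALSE, h, w)
    if (area > 0) {
      asp <- if (v == "top") 1 else aspect
      b <- sqrt(area * asp / pi); a <- area / (pi * b)  # semi-axes, pi*a*b=area
      cy <- h / 2; cx <- w / 2
      yy <- matrix(seq_len(h), h, w) - cy
      xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
      d <- (xx / a)^2 + (yy / b)^2
      thr <- sort(as.vector(d), partial = area)[area]
      mask[d <= thr] <- TRUE
      # exact pixel count even with ties at the threshold
      if (sum(mask) > area) {
        drop <- which(mask & d == thr)
        mask[drop[seq_len(sum(mask) - area)]] <- FALSE
      }
    }
    if (salt_noise > 0) {
      bg <- which(!mask)
      mask_salt <- sample(bg, min(salt_noise, length(bg)))
    } else mask_salt <- integer(0)
    rgb <- array(0, c(h, w, 3))
    rgb[, , 1] <- 0.95; rgb[, , 2] <- 0.95; rgb[, , 3] <- 0.95
    for (idx in list(which(mask), mask_salt)) {
      r1 <- rgb[, , 1]; g1 <- rgb[, , 2]; b1 <- rgb[, , 3]
      r1[idx] <- 0.1; g1[idx] <- 0.7; b1[idx] <- 0.15
      rgb[, , 1] <- r1; rgb[, , 2] <- g1; rgb[, , 3] <- b1
    }
    nir <- matrix(0.35, h, w)
    nir[mask] <- gray / 255
    out[[paste0("rgb_", v)]] <- rgb
    out[[paste0("nir_", v)]] <- nir
  }
  out
}
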