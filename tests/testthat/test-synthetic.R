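# Ground-truth properties of the synthetic experiment generator.

test_that("default experiment has the study layout: 24x2x3 pots, 26 days", {
  sim <- small_sim(n_genotypes = 24, n_days = 26, seed = 1)
  expect_equal(nrow(sim$features), 24 * 2 * 3 * 26)  # 3744 plant-days
  expect_equal(nrow(sim$design), 144)
  expect_equal(ncol(geometry_columns(sim$features)) - 2, 42)
})

test_that("a fixed seed reproduces the experiment exactly", {
  a <- simulate_experiment(sim_config(n_genotypes = 4, n_days = 8, seed = 42))
  b <- simulate_experiment(sim_config(n_genotypes = 4, n_days = 8, seed = 42))
  expect_identical(a$features, b$features)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$truth$biomass, b$truth$biomass)
})

test_that("latent trajectories follow the logistic closed form", {
  cfg <- sim_config(n_genotypes = 3, n_days = 10, genotype_rate_sd = 0,
                    residual_sd = 0, feature_noise_sd = 0, seed = 5)
  sim <- simulate_experiment(cfg)
  days <- 0:9
  B0 <- cfg$initial_biomass_g; K <- cfg$max_biomass_g
  for (pid in rownames(sim$truth$biomass)[c(1, 4)]) {
    r <- sim$truth$rate[pid]
    expect_equal(as.numeric(sim$truth$biomass[pid, ]),
                 K / (1 + ((K - B0) / B0) * exp(-r * days)),
                 tolerance = 1e-12)
  }
  expect_true(all(diff(t(sim$truth$biomass)) >= 0))  # non-decreasing
})

test_that("noise-free features are exact monotone functions of biomass", {
  sim <- simulate_experiment(sim_config(n_genotypes = 3, n_days = 8,
                                        residual_sd = 0, feature_noise_sd = 0,
                                        seed = 2))
  B <- as.vector(t(sim$truth$biomass))
  expect_equal(sim$features$area.top, 900 * B^(2 / 3), tolerance = 1e-10)
  expect_equal(sim$features$height.side0, 60 * B^(1 / 3), tolerance = 1e-10)
  # identical genotype trajectories in expectation when rate SD is 0
  sim0 <- simulate_experiment(sim_config(n_genotypes = 4, n_days = 6,
                                         genotype_rate_sd = 0, seed = 3))
  rates <- sim0$truth$rate
  trt <- as.data.frame(sim0$design)$treatment
  expect_equal(length(unique(round(rates[trt == "well_watered"], 12))), 1)
})

test_that("exponential mode gives analytically constant RGR equal to r", {
  cfg <- sim_config(n_genotypes = 2, n_days = 12,
                    growth_model = "exponential", base_rate = 0.1,
                    genotype_rate_sd = 0, treatment_growth_multiplier = 1,
                    residual_sd = 0, feature_noise_sd = 0, seed = 7)
  sim <- simulate_experiment(cfg)
  B <- sim$truth$biomass[1, ]
  expect_equal(unname(rgr_interval(B["2"], B["9"], 2, 9)), 0.1,
               tolerance = 1e-12)
  expect_equal(unname(rgr_interval(B["0"], B["11"], 0, 11)), 0.1,
               tolerance = 1e-12)
})

test_that("watering ledger is internally consistent with generative water use", {
  sim <- small_sim()
  led <- as.data.frame(sim$ledger)
  expect_true(all(abs((led$weight_after_g - led$weight_before_g) -
                        led$water_added_ml) < 1e-9))
  wu <- daily_water_use(sim$ledger)
  for (pid in rownames(sim$truth$water_use)[c(1, 10)]) {
    rec <- wu$WU[wu$pot_id == pid][-1]
    expect_equal(rec, unname(sim$truth$water_use[pid, -1]),
                 tolerance = 1e-9)
  }
})

test_that("rendered blobs hit the requested area and NIR gray", {
  st <- list(area = list(top = 1234, side0 = 800, side90 = 650),
             mean_gray = 200)
  imgs <- render_plant_images(st)
  for (v in c("top", "side0", "side90")) {
    green <- imgs[[paste0("rgb_", v)]][, , 2] > 0.5 &
      imgs[[paste0("rgb_", v)]][, , 1] < 0.5
    expect_true(abs(sum(green) - st$area[[v]]) <= 0.02 * st$area[[v]])
    nir <- imgs[[paste0("nir_", v)]]
    expect_equal(mean(nir[green]) * 255, 200, tolerance = 1)
  }
  empty <- render_plant_images(list(area = list(top = 0, side0 = 0,
                                                side90 = 0)))
  expect_equal(sum(empty$rgb_top[, , 2] > 0.5 & empty$rgb_top[, , 1] < 0.5), 0)
  expect_error(render_plant_images(list(area = list(top = 1e6, side0 = 1,
                                                    side90 = 1))),
               "exceeds canvas")
})
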