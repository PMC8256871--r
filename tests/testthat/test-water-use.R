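# Water bookkeeping, %FC trajectories and water-use indices.

test_that("field capacity arithmetic and default targets", {
  fc <- field_capacity(14000, 17500)
  expect_equal(fc$fc, 3500)
  expect_equal(fc$target_weight(0.8), 16800)
  expect_equal(fc$target_weight(0.5), 15750)
  expect_equal(fc$target_weight(0), 14000)
  expect_error(field_capacity(14000, 13000), "below dry weight")
})

test_that("daily water use is the weight loss between waterings", {
  led <- pg_ledger(data.frame(
    pot_id = "p1", day = 0:2,
    weight_before_g = c(5000, 4850, 5000),
    weight_after_g = c(5000, 5000, 5000),
    water_added_ml = c(0, 150, 0)))
  wu <- daily_water_use(led)
  expect_equal(wu$WU, c(0, 150, 0))
  expect_equal(wu$WUCum, c(0, 150, 150))
  expect_true(all(diff(wu$WUCum) >= 0))
})

test_that("day gaps spread losses uniformly and negatives are floored", {
  led <- pg_ledger(data.frame(
    pot_id = "p1", day = c(0, 3),
    weight_before_g = c(5000, 4700),
    weight_after_g = c(5000, 5000),
    water_added_ml = c(0, 300)))
  wu <- daily_water_use(led)
  expect_equal(wu$WU[wu$day %in% 1:3], rep(100, 3))
  expect_true(all(wu$gap_filled[wu$day %in% 1:3]))

  neg <- pg_ledger(data.frame(
    pot_id = "p1", day = 0:1,
    weight_before_g = c(5000, 5050),
    weight_after_g = c(5000, 5050),
    water_added_ml = c(0, 0)), tol = 60)
  wn <- daily_water_use(neg, tol = 2)
  expect_equal(wn$WU[2], 0)
  expect_true(wn$quality_flag[2])
})

test_that("%FC inverts the target-weight formula and tracks the simulation", {
  led <- pg_ledger(data.frame(
    pot_id = "p1", day = 0,
    weight_before_g = 500 + 14000 + 0.8 * 3500,
    weight_after_g = 500 + 14000 + 0.8 * 3500, water_added_ml = 0))
  pfc <- percent_fc_series(led, fc = 3500, dry_soil_weight = 14000,
                           tare = 500)
  expect_equal(pfc$percent_fc, 80)

  sim <- small_sim()
  pfc2 <- percent_fc_series(sim$ledger, fc = 3500)
  meta <- as.data.frame(sim$design)
  joined <- merge(pfc2, meta, by.x = "pot_id", by.y = "plant_id")
  ww <- joined[joined$treatment == "well_watered" & joined$day > 0, ]
  expect_true(all(abs(ww$percent_fc - 80) < 10))   # held near target
  ws <- joined[joined$treatment == "water_stressed" & joined$day > 0, ]
  expect_true(all(abs(ws$percent_fc - 50) < 10))
})

test_that("withheld watering gives a monotone decreasing %FC", {
  w <- 500 + 14000 + 3500 * c(0.8, 0.73, 0.66, 0.6)
  led <- pg_ledger(data.frame(pot_id = "p1", day = 0:3,
                              weight_before_g = w, weight_after_g = w,
                              water_added_ml = 0))
  pfc <- percent_fc_series(led, fc = 3500, dry_soil_weight = 14000,
                           tare = 500)
  expect_true(all(diff(pfc$percent_fc) < 0))
})

test_that("WUI definitions and the exact biomass identity", {
  expect_equal(wui_bm(0.5, 100), 5)      # mg per ml
  expect_equal(wui_agr(2, 100), 0.02)
  expect_equal(wui_rgr(0.1, 50), 0.002)
  expect_error(wui_bm(1, 0), "WUCum")
  set.seed(14)
  pfb <- runif(100, 0.1, 50); wucum <- runif(100, 10, 5000)
  expect_equal(wui_bm(pfb, wucum) * wucum / 1000, pfb, tolerance = 1e-12)
})

test_that("control pots use more cumulative water than stressed pots", {
  sim <- small_sim()
  wu <- daily_water_use(sim$ledger)
  final <- wu[wu$day == max(wu$day), ]
  meta <- as.data.frame(sim$design)
  j <- merge(final, meta, by.x = "pot_id", by.y = "plant_id")
  expect_gt(mean(j$WUCum[j$treatment == "well_watered"]),
            mean(j$WUCum[j$treatment == "water_stressed"]))
})
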