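# Segmentation and geometric/NIR feature extraction on constructed fixtures.

green_on_white <- function(h, w, mask_fn) {
  rgb <- array(0.95, c(h, w, 3))
  idx <- which(mask_fn(matrix(seq_len(h), h, w),
                       matrix(seq_len(w), h, w, byrow = TRUE)))
  for (ch in c(1, 3)) { p <- rgb[, , ch]; p[idx] <- 0.1; rgb[, , ch] <- p }
  p <- rgb[, , 2]; p[idx] <- 0.7; rgb[, , 2] <- p
  rgb
}

test_that("segmentation classifies by nearest reference colour", {
  blank <- array(0.95, c(64, 64, 3))
  m <- segment_plant(blank, seg_params())
  expect_true(m$empty)
  expect_identical(extract_geometric_features(m)$area, NA_real_)
  expect_identical(nir_mean_gray(matrix(0.5, 64, 64), m), NA_real_)

  rect <- green_on_white(64, 64, function(y, x) y >= 20 & y < 40 &
                           x >= 30 & x < 40)
  m2 <- segment_plant(rect, seg_params())
  expect_equal(m2$pixel_count, 200)
  f <- extract_geometric_features(m2)
  expect_equal(f$area, 200)
  expect_equal(f$width, 10)
  expect_equal(f$height, 20)
  expect_true(f$area <= f$hull_area)
  expect_equal(f$extent, 1)
})

test_that("erosion/dilation removes isolated speckles but keeps the blob", {
  imgs <- render_plant_images(list(area = list(top = 1234, side0 = 10,
                                               side90 = 10), mean_gray = 180),
                              salt_noise = 50)
  raw <- segment_plant(imgs$rgb_top, seg_params())
  expect_gt(raw$pixel_count, 1234)  # speckles present before morphology
  opened <- segment_plant(imgs$rgb_top,
                          seg_params(erosion_radius = 1, dilation_radius = 1))
  expect_lte(abs(opened$pixel_count - 1234), 0.02 * 1234)
})

test_that("compactness and eccentricity behave on a rasterised disk", {
  st <- list(area = list(top = round(pi * 20^2), side0 = 50, side90 = 50))
  m <- segment_plant(render_plant_images(st)$rgb_top, seg_params())
  f <- extract_geometric_features(m)
  expect_gte(f$compactness, 0.9)
  expect_lte(f$compactness, 1)
  expect_lt(f$eccentricity, 0.2)
  expect_equal(f$eq_diameter, 2 * sqrt(f$area / pi), tolerance = 1e-12)
})

test_that("area never exceeds hull area on random masks", {
  set.seed(8)
  for (i in 1:10) {
    rgb <- green_on_white(48, 48, function(y, x)
      matrix(runif(48 * 48) < 0.1, 48, 48))
    m <- segment_plant(rgb, seg_params())
    if (m$empty) next
    f <- extract_geometric_features(m)
    expect_lte(f$area, f$hull_area + 1e-9)
    expect_gt(f$compactness, 0)
    expect_lte(f$compactness, 1)
  }
})

test_that("NIR mean gray averages foreground intensities", {
  rect <- green_on_white(32, 32, function(y, x) y <= 16)
  m <- segment_plant(rect, seg_params())
  expect_equal(nir_mean_gray(matrix(200, 32, 32), m), 200)
  half <- matrix(100, 32, 32); half[9:16, ] <- 200
  expect_equal(nir_mean_gray(half, m), 150)
  # drier plants are brighter in the simulator
  dry <- simulate_experiment(sim_config(n_genotypes = 2, n_days = 4,
                                        fc_target = list(well_watered = 0.8,
                                                         water_stressed = 0.4),
                                        seed = 1))
  meta <- as.data.frame(dry$design)
  gr <- merge(dry$features, meta, by = "plant_id")
  expect_gt(mean(gr$mean_gray.top[gr$treatment == "water_stressed"]),
            mean(gr$mean_gray.top[gr$treatment == "well_watered"]))
})

test_that("segmentation ignores pixels outside the ROI", {
  base <- green_on_white(60, 60, function(y, x) y >= 25 & y <= 34 &
                           x >= 25 & x <= 34)
  noisy <- base
  set.seed(3)
  for (ch in 1:3) {
    p <- noisy[, , ch]
    p[1:10, ] <- runif(600)   # garbage strictly above the ROI
    noisy[, , ch] <- p
  }
  pars <- seg_params(roi = c(15, 60, 1, 60))
  m1 <- segment_plant(base, pars)
  m2 <- segment_plant(noisy, pars)
  expect_identical(m1$mask, m2$mask)
})

test_that("build_feature_table pivots views wide and keeps missing views", {
  reg <- pg_feature_registry()
  recs <- expand.grid(plant_id = c("P1", "P2"), day = c(1, 2, 3),
                      view = reg$views, stringsAsFactors = FALSE)
  for (f in reg$geometric) recs[[f]] <- runif(nrow(recs), 1, 100)
  recs$mean_gray <- runif(nrow(recs), 100, 200)
  recs <- recs[!(recs$plant_id == "P2" & recs$day == 3 &
                   recs$view == "side90"), ]
  ft <- build_feature_table(recs)
  expect_equal(nrow(ft), 6)
  expect_equal(ncol(geometry_columns(ft)) - 2, 42)
  row <- ft[ft$plant_id == "P2" & ft$day == 3, ]
  expect_true(is.na(row$area.side90))
  expect_false(is.na(row$area.top))
  dup <- rbind(recs, recs[1, ])
  expect_error(build_feature_table(dup), "duplicate")
})

test_that("feature extraction is deterministic for identical images", {
  st <- list(area = list(top = 900, side0 = 700, side90 = 650),
             mean_gray = 190)
  imgs <- render_plant_images(st)
  f1 <- extract_geometric_features(segment_plant(imgs$rgb_top, seg_params()))
  f2 <- extract_geometric_features(segment_plant(imgs$rgb_top, seg_params()))
  expect_identical(f1, f2)
})
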