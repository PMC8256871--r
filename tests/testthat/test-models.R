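# Metrics, the eight regression families, resampled evaluation and selection.

test_that("metrics match hand-computed values and edge cases", {
  m <- compute_metrics(c(2, 4, 6, 8), c(3, 3, 7, 7))
  expect_equal(m$MAE, 1)           # |residuals| all 1
  expect_equal(m$RMSE, 1)
  expect_equal(m$R2, 0.8)          # SSres 4 / SStot 20
  expect_equal(m$R2_cor, 0.8)

  p <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(p$MAE, 0); expect_equal(p$RMSE, 0); expect_equal(p$R2, 1)

  e <- compute_metrics(c(0, 0, 0, 0), c(1, -1, 1, -1))
  expect_equal(e$MAE, 1); expect_equal(e$RMSE, 1)
  expect_true(is.na(e$R2))         # zero-variance actual: undefined signal
  expect_error(compute_metrics(1, 1), "length")
})

test_that("RMSE >= MAE with equality only for equal-magnitude residuals", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    a <- rnorm(n); p <- a + rnorm(n)
    m <- compute_metrics(a, p)
    expect_gte(m$RMSE, m$MAE - 1e-12)
  }
  eq <- compute_metrics(c(5, 6, 7), c(4, 7, 8))   # residuals 1, -1, -1
  expect_equal(eq$RMSE, eq$MAE)
})

test_that("LM reproduces a realisable linear function; rank deficiency flagged", {
  set.seed(5)
  X <- matrix(rnorm(200), 40, 5)
  y <- as.vector(X %*% (1:5)) + 2
  fit <- fit_model(model_spec("LM"), X, y)
  expect_lt(max(abs(predict(fit, X) - y)) / max(abs(y)), 1e-8)
  expect_false(fit$rank_deficient)

  Xs <- matrix(rnorm(60), 6, 10)   # p > n
  fit2 <- fit_model(model_spec("LM"), Xs, rnorm(6))
  expect_true(fit2$rank_deficient)
  expect_true(all(is.finite(predict(fit2, Xs))))
})

test_that("PLS and PCR at full components reproduce OLS predictions", {
  set.seed(6)
  X <- matrix(rnorm(100 * 10), 100, 10)
  y <- as.vector(X %*% rnorm(10)) + rnorm(100)
  ols <- predict(fit_model(model_spec("LM"), X, y), X)
  pls <- predict(fit_model(model_spec("PLS"), X, y,
                           tuning = data.frame(ncomp = 10)), X)
  pcr <- predict(fit_model(model_spec("PC"), X, y,
                           tuning = data.frame(ncomp = 10)), X)
  expect_lt(max(abs(pls - ols)) / max(abs(ols)), 1e-8)
  expect_lt(max(abs(pcr - ols)) / max(abs(ols)), 1e-8)
})

test_that("stepwise keeps informative predictors and MARS fits a hinge", {
  set.seed(7)
  X <- matrix(rnorm(150 * 8), 150, 8)
  y <- 3 * X[, 2] - 2 * X[, 5] + rnorm(150, 0, 0.1)
  sm <- fit_model(model_spec("SM"), X, y)
  expect_true(all(c(2, 5) %in% sm$fit$cols))
  expect_gt(cor(predict(sm, X), y)^2, 0.99)

  xh <- seq(-3, 3, length.out = 200)
  Xh <- cbind(xh, rnorm(200))
  yh <- 2 * pmax(xh - 0.4, 0) + rnorm(200, 0, 0.05)
  mars <- fit_model(model_spec("MARS"), Xh, yh,
                    tuning = data.frame(max_terms = 9))
  expect_gt(cor(predict(mars, Xh), yh)^2, 0.97)
})

test_that("evaluate_models produces the documented resample counts and is deterministic", {
  sim <- small_sim()
  rs <- resample_spec(k = 10, repeats = 5, seed = 11)
  ev <- evaluate_models(sim$features, sim$biomass, rs, families = c("LM", "PLS"))
  expect_equal(ev$n_resamples, 50)                 # 10-fold x 5 repeats
  expect_equal(nrow(ev$per_family$PLS$metrics), 50)
  expect_true(all(ev$per_family$PLS$metrics$RMSE >=
                    ev$per_family$PLS$metrics$MAE - 1e-12))

  bs <- evaluate_models(sim$features, sim$biomass,
                        resample_spec("bootstrap", n_boot = 25, seed = 11),
                        families = "LM")
  expect_equal(bs$n_resamples, 25)

  ev2 <- evaluate_models(sim$features, sim$biomass, rs,
                         families = c("LM", "PLS"))
  expect_identical(ev$per_family$PLS$metrics, ev2$per_family$PLS$metrics)

  st <- summary_table(ev)
  expect_named(st, c("MAE", "RMSE", "R2"))
  expect_equal(colnames(st$RMSE),
               c("Min.", "1st Qu.", "Median", "Mean", "3rd Qu.", "Max."))
  for (m in st) {
    expect_true(all(m[["Min."]] <= m[["Median"]] &
                      m[["Median"]] <= m[["Max."]]))
  }
  expect_error(evaluate_models(sim$features, sim$biomass,
                               resample_spec(k = 500), families = "LM"),
               "fewer observations")
})

test_that("LM beats RF on linear low-noise data; selector prefers parsimony", {
  # score the families directly on a linear generative model
  rs <- make_lowrank_data(n = 90, p = 10, rank = 10, noise = 0.05, seed = 13)
  X <- rs$X; y <- rs$y
  set.seed(4)
  folds <- rep_len(1:5, 90)
  rmse <- function(fam) {
    e <- vapply(1:5, function(f) {
      tr <- which(folds != f); te <- which(folds == f)
      m <- fit_model(model_spec(fam), X[tr, ], y[tr])
      sqrt(mean((y[te] - predict(m, X[te, ]))^2))
    }, numeric(1))
    median(e)
  }
  expect_lt(rmse("LM"), rmse("RF"))

  # two-family selection on rank-3 collinear features
  d3 <- make_lowrank_data(n = 100, p = 42, rank = 3, noise = 0.3, seed = 21)
  sel <- local({
    ftab <- d3$X
    colnames(ftab) <- pg_feature_columns(geometry_only = TRUE)
    feats <- pg_features(cbind(data.frame(plant_id = paste0("P", 1:100),
                                          day = 9), as.data.frame(ftab)))
    bm <- pg_biomass(data.frame(plant_id = paste0("P", 1:100),
                                fresh_weight_g = d3$y - min(d3$y) + 1,
                                dry_weight_g = 0,
                                harvest_day = 9))
    ev <- evaluate_models(feats, bm, resample_spec(k = 5, repeats = 2,
                                                   seed = 2),
                          families = c("LM", "PC", "PLS"))
    select_model(ev)
  })
  expect_true(sel$family %in% c("PLS", "PC"))
  expect_lte(sel$complexity, 6)   # low-rank structure found with few components

  one <- local({
    sim <- small_sim()
    ev <- evaluate_models(sim$features, sim$biomass,
                          resample_spec(k = 5, repeats = 1, seed = 3),
                          families = "PLS")
    select_model(ev)
  })
  expect_equal(one$family, "PLS")
})

test_that("final k-fold cross-validation partitions, refits and tests", {
  set.seed(9)
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- as.vector(X %*% c(1, 2, 3)) + 5
  cv <- crossvalidate_final(model_spec("LM"), X, y, k = 12, seed = 1)
  expect_equal(nrow(cv$predictions), 12)
  expect_equal(sort(unique(cv$predictions$fold)), 1:12)  # leave-one-out
  expect_lt(cv$cv_ss, 1e-12)                             # realisable function

  cv1 <- crossvalidate_final(model_spec("LM"), X, y, k = 4, seed = 7)
  cv2 <- crossvalidate_final(model_spec("LM"), X, y, k = 4, seed = 7)
  expect_identical(cv1$predictions$fold, cv2$predictions$fold)
  expect_error(crossvalidate_final(model_spec("LM"), X, y, k = 13), "exceeds")

  set.seed(10)
  Xn <- matrix(rnorm(60 * 3), 60, 3)
  yn <- as.vector(Xn %*% c(1, -1, 2)) + rnorm(60, 0, 0.3)
  cvn <- crossvalidate_final(model_spec("LM"), Xn, yn, k = 10, seed = 2)
  expect_lt(cvn$f_test$p.value, 1e-10)
})

test_that("predict_biomass clips negatives and rejects missing predictors", {
  sim <- small_sim()
  ev <- evaluate_models(sim$features, sim$biomass,
                        resample_spec(k = 5, repeats = 1, seed = 5),
                        families = "LM")
  model <- ev$per_family$LM$final_model
  pfb <- predict_biomass(model, sim$features)
  expect_equal(nrow(pfb), nrow(sim$features))
  expect_true(all(pfb$pfb >= 0.01))

  broken <- sim$features[, setdiff(names(sim$features), "area.top")]
  class(broken) <- class(sim$features)
  expect_error(predict_biomass(model, broken), "area.top")

  # force a negative raw prediction via an offset model
  model2 <- model
  model2$fit$beta[1] <- model2$fit$beta[1] - 1e6
  pfb2 <- predict_biomass(model2, sim$features)
  expect_true(all(pfb2$clipped))
  expect_true(all(pfb2$pfb == 0.01))
})

test_that("training R2 exceeds mean resampled R2 on most simulated datasets", {
  set.seed(31)
  wins <- 0
  for (i in 1:15) {
    d <- make_lowrank_data(n = 60, p = 10, rank = 10, noise = 1, seed = 300 + i)
    X <- d$X; y <- d$y
    fit <- fit_model(model_spec("LM"), X, y)
    train_r2 <- cor(predict(fit, X), y)^2
    folds <- sample(rep_len(1:5, 60))
    cv_r2 <- mean(vapply(1:5, function(f) {
      tr <- which(folds != f); te <- which(folds == f)
      m <- fit_model(model_spec("LM"), X[tr, ], y[tr])
      cor(predict(m, X[te, ]), y[te])^2
    }, numeric(1)))
    if (train_r2 >= cv_r2) wins <- wins + 1
  }
  expect_gte(wins, 13)   # anti-overfitting sanity: ~90% of datasets
})
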