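# Resampled comparison of the eight model families, model selection, final
# cross-validation check, and per-day biomass prediction.

#' Resampling specification
#'
#' @param scheme `"repeated_kfold"` (default: 10-fold cross-validation
#'   repeated 5 times, 50 resamples) or `"bootstrap"` (25 bootstrap
#'   replicates scored on out-of-bag rows).
#' @param k folds (>= 2); `repeats` repetitions; `n_boot` bootstrap count.
#' @param seed integer seed controlling fold assignment.
#' @return a `pg_resample_spec`.
#' @export
resample_spec <- function(scheme = c("repeated_kfold", "bootstrap"),
                          k = 10, repeats = 5, n_boot = 25, seed = 1L) {
  scheme <- match.arg(scheme)
  if (k < 2) pg_stop("config", "resample_spec: k must be >= 2")
  if (repeats < 1) pg_stop("config", "resample_spec: repeats must be >= 1")
  structure(list(scheme = scheme, k = as.integer(k),
                 repeats = as.integer(repeats), n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "pg_resample_spec")
}

make_resamples <- function(spec, n) {
  if (spec$scheme == "repeated_kfold") {
    if (n < spec$k) {
      pg_stop("resample", "fewer observations (", n, ") than folds (",
              spec$k, ")")
    }
    out <- list()
    for (r in seq_len(spec$repeats)) {
      fold <- sample(rep_len(seq_len(spec$k), n))
      for (f in seq_len(spec$k)) {
        test <- which(fold == f)
        out[[length(out) + 1]] <- list(train = setdiff(seq_len(n), test),
                                       test = test)
      }
    }
    out
  } else {
    lapply(seq_len(spec$n_boot), function(b) {
      tr <- sample.int(n, n, replace = TRUE)
      te <- setdiff(seq_len(n), unique(tr))
      if (!length(te)) te <- sample.int(n, max(1, round(n / 3)))
      list(train = tr, test = te)
    })
  }
}

# held-out predictions for every tuning-grid row, in one pass per family
grid_predictions <- function(family, Xtr, ytr, Xte, grid) {
  pp <- preproc_fit(Xtr)
  Ztr <- preproc_apply(pp, Xtr)
  Zte <- preproc_apply(pp, Xte)
  nte <- nrow(Zte)
  switch(family,
    LM = matrix(ols_predict(ols_fit(Ztr, ytr), Zte), nte, 1),
    SM = matrix(stepwise_predict(stepwise_fit(Ztr, ytr), Zte), nte, 1),
    PLS = {
      fit <- pls_fit(Ztr, ytr, max(grid$ncomp))
      vapply(grid$ncomp, function(k) pls_predict(fit, Zte, k), numeric(nte))
    },
    PC = {
      fit <- pcr_fit(Ztr, ytr, max(grid$ncomp))
      vapply(grid$ncomp, function(k) pcr_predict(fit, Zte, k), numeric(nte))
    },
    ELASTICNET = {
      out <- matrix(NA_real_, nte, nrow(grid))
      for (a in unique(grid$alpha)) {
        rows <- which(grid$alpha == a)
        lams <- vapply(grid$lambda_frac[rows], function(fr)
          glmnet_lambda(Ztr, ytr, fr), numeric(1))
        fit <- glmnet::glmnet(Ztr, ytr, alpha = a,
                              lambda = sort(lams, decreasing = TRUE),
                              standardize = FALSE)
        out[, rows] <- vapply(lams, function(l)
          as.vector(predict(fit, Zte, s = l, exact = FALSE)), numeric(nte))
      }
      out
    },
    RF = vapply(grid$mtry, function(m) {
      as.vector(predict(randomForest::randomForest(
        Ztr, ytr, ntree = 300, mtry = min(m, ncol(Ztr))), Zte))
    }, numeric(nte)),
    GBM = {
      out <- matrix(NA_real_, nte, nrow(grid))
      for (d in unique(grid$max_depth)) {
        rows <- which(grid$max_depth == d)
        nmax <- max(grid$nrounds[rows])
        fit <- xgboost::xgboost(x = Ztr, y = ytr, nrounds = nmax,
                                max_depth = d, learning_rate = 0.1,
                                nthreads = 1, verbosity = 0,
                                objective = "reg:squarederror")
        for (i in rows) {
          out[, i] <- as.vector(predict(fit, Zte,
                                        iterationrange = c(1, grid$nrounds[i] + 1)))
        }
      }
      out
    },
    MARS = vapply(grid$max_terms, function(mt) {
      mars_predict(mars_fit(Ztr, ytr, max_terms = mt), Zte)
    }, numeric(nte))
  )
}

join_harvest <- function(features, biomass, geometry_only = TRUE) {
  ft <- if (geometry_only) geometry_columns(features) else
    as.data.frame(features)
  df <- merge(as.data.frame(biomass)[, c("plant_id", "fresh_weight_g",
                                         "harvest_day")],
              ft, by = "plant_id")
  df <- df[df$day == df$harvest_day, ]
  if (!nrow(df)) pg_stop("input", "no feature rows at the harvest day")
  pred_cols <- setdiff(names(df), c("plant_id", "fresh_weight_g",
                                    "harvest_day", "day"))
  list(X = as.matrix(df[, pred_cols, drop = FALSE]),
       y = df$fresh_weight_g, plant_id = df$plant_id, pred_cols = pred_cols)
}

#' Evaluate model families under resampling
#'
#' Joins harvest-day image features (geometry-only columns) with measured
#' fresh biomass and scores each requested family on held-out resample
#' predictions. Hyperparameters are tuned on the same resamples (best mean
#' held-out RMSE across the family's grid); preprocessing is re-estimated
#' inside every training split.
#'
#' @param features a [pg_features] table.
#' @param biomass a [pg_biomass] table.
#' @param resample a [resample_spec()].
#' @param families character vector of families (default: all eight).
#' @param geometry_only restrict predictors to the 42 geometric columns.
#' @return a `pg_model_evaluation`: per-family resample metric vectors
#'   (`MAE`, `RMSE`, `R2` = squared observed/predicted correlation, and
#'   `R2_ss` = 1 - SSres/SStot), best tuning, complexity, the refit final
#'   model, and six-number summary tables in the Min/1st Qu./Median/Mean/
#'   3rd Qu./Max layout.
#' @export
evaluate_models <- function(features, biomass, resample = resample_spec(),
                            families = PG_FAMILIES, geometry_only = TRUE) {
  families <- toupper(families)
  bad <- setdiff(families, PG_FAMILIES)
  if (length(bad)) pg_stop("config", "unknown families: ",
                           paste(bad, collapse = ", "))
  jd <- join_harvest(features, biomass, geometry_only)
  X <- jd$X; y <- jd$y
  set.seed(resample$seed)
  resamples <- make_resamples(resample, nrow(X))
  per_family <- list()
  for (fam in families) {
    grid <- default_grid(fam, X)
    pred_list <- vector("list", length(resamples))
    for (i in seq_along(resamples)) {
      rs <- resamples[[i]]
      pred_list[[i]] <- grid_predictions(fam, X[rs$train, , drop = FALSE],
                                         y[rs$train],
                                         X[rs$test, , drop = FALSE], grid)
    }
    # tune: mean held-out RMSE per grid row
    rmse_grid <- vapply(seq_len(nrow(grid)), function(gidx) {
      mean(vapply(seq_along(resamples), function(i) {
        a <- y[resamples[[i]]$test]
        sqrt(mean((a - pred_list[[i]][, gidx])^2))
      }, numeric(1)))
    }, numeric(1))
    best_g <- which.min(rmse_grid)
    met <- t(vapply(seq_along(resamples), function(i) {
      a <- y[resamples[[i]]$test]
      m <- compute_metrics(a, pred_list[[i]][, best_g])
      c(MAE = m$MAE, RMSE = m$RMSE, R2 = m$R2_cor, R2_ss = m$R2)
    }, numeric(4)))
    final <- fit_model(model_spec(fam), X, y,
                       tuning = grid[best_g, , drop = FALSE])
    final$feature_names <- jd$pred_cols
    per_family[[fam]] <- list(metrics = as.data.frame(met),
                              best_tuning = grid[best_g, , drop = FALSE],
                              complexity = final$complexity,
                              final_model = final)
  }
  structure(list(per_family = per_family, resample = resample,
                 n_resamples = length(resamples),
                 feature_names = jd$pred_cols, n = nrow(X)),
            class = "pg_model_evaluation")
}

#' Six-number summary tables of a model evaluation
#'
#' @param evaluation a `pg_model_evaluation`.
#' @return named list of data.frames (`MAE`, `RMSE`, `R2`), one row per
#'   family, columns Min./1st Qu./Median/Mean/3rd Qu./Max.
#' @export
summary_table <- function(evaluation) {
  out <- list()
  for (metric in c("MAE", "RMSE", "R2")) {
    rows <- t(vapply(evaluation$per_family, function(pf) {
      s <- summary(pf$metrics[[metric]])
      as.numeric(s)[1:6]
    }, numeric(6)))
    colnames(rows) <- c("Min.", "1st Qu.", "Median", "Mean", "3rd Qu.", "Max.")
    out[[metric]] <- as.data.frame(round(rows, 4))
  }
  out
}

#' Select the final model family
#'
#' Families are ranked by mean resample RMSE (ties: mean MAE, then -mean R2).
#' Among families whose mean RMSE lies within one resample standard error of
#' the best family's, the one with the smallest complexity (components/
#' selected terms/parameters) is preferred -- a parsimony rule that favours a
#' component-based family reaching near-minimal error with few components.
#'
#' @param evaluation a `pg_model_evaluation`.
#' @param parsimony apply the one-standard-error parsimony rule.
#' @return a `pg_selection`: list with `family`, `spec` ([model_spec()] with
#'   the winning tuning), `tuning`, `complexity`, `candidates` and a
#'   `rationale` string.
#' @export
select_model <- function(evaluation, parsimony = TRUE) {
  pf <- evaluation$per_family
  stats <- data.frame(
    family = names(pf),
    mean_rmse = vapply(pf, function(x) mean(x$metrics$RMSE), numeric(1)),
    mean_mae = vapply(pf, function(x) mean(x$metrics$MAE), numeric(1)),
    mean_r2 = vapply(pf, function(x) mean(x$metrics$R2, na.rm = TRUE),
                     numeric(1)),
    complexity = vapply(pf, function(x) x$complexity, numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(stats$mean_rmse, stats$mean_mae, -stats$mean_r2)
  stats <- stats[ord, ]
  best <- stats[1, ]
  se <- sd(pf[[best$family]]$metrics$RMSE) /
    sqrt(nrow(pf[[best$family]]$metrics))
  cand <- stats[stats$mean_rmse <= best$mean_rmse + se, ]
  pick <- if (parsimony) cand[order(cand$complexity, cand$mean_rmse), ][1, ]
    else best
  rationale <- sprintf(
    "best mean RMSE %.4f (%s, SE %.4f); %d candidate(s) within 1 SE; chose %s (complexity %d) as the most parsimonious",
    best$mean_rmse, best$family, se, nrow(cand), pick$family,
    as.integer(pick$complexity))
  structure(list(family = pick$family,
                 spec = model_spec(pick$family),
                 tuning = pf[[pick$family]]$best_tuning,
                 complexity = pick$complexity,
                 final_model = pf[[pick$family]]$final_model,
                 candidates = cand$family, table = stats,
                 rationale = rationale),
            class = "pg_selection")
}

#' Final k-fold cross-validation check of the selected model
#'
#' Randomly partitions the data into `k` folds, refits the model on the
#' remainder of each fold, and reports per-fold and pooled cross-validation
#' residual sums of squares plus an F-test of the observed ~ predicted
#' regression.
#'
#' @param spec a [model_spec()] (or a `pg_selection`).
#' @param X,y predictor matrix and response.
#' @param k folds; `k = n` gives leave-one-out.
#' @param tuning hyperparameter row passed to [fit_model()].
#' @param seed fold-assignment seed.
#' @return list with `predictions` (data.frame row, fold, actual, predicted),
#'   `fold_ss`, `cv_ss` (pooled residual SS), `cv_ms`, and `f_test`
#'   (statistic, df, p.value of the observed~predicted regression).
#' @export
crossvalidate_final <- function(spec, X, y, k = 10, tuning = NULL,
                                seed = 1L) {
  if (inherits(spec, "pg_selection")) {
    tuning <- spec$tuning; spec <- spec$spec
  }
  X <- as.matrix(X); n <- nrow(X)
  if (k > n) pg_stop("resample", "k (", k, ") exceeds n (", n, ")")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- setdiff(seq_len(n), te)
    m <- fit_model(spec, X[tr, , drop = FALSE], y[tr], tuning = tuning)
    pred[te] <- predict(m, X[te, , drop = FALSE])
  }
  fold_ss <- vapply(seq_len(k), function(f)
    sum((y[fold == f] - pred[fold == f])^2), numeric(1))
  fit <- lm(y ~ pred)
  fstat <- suppressWarnings(summary(fit))$fstatistic
  pval <- if (is.null(fstat)) NA_real_ else
    pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  list(predictions = data.frame(row = seq_len(n), fold = fold, actual = y,
                                predicted = pred),
       fold_ss = fold_ss, cv_ss = sum(fold_ss), cv_ms = sum(fold_ss) / n,
       f_test = list(statistic = unname(fstat[1]), df = unname(fstat[2:3]),
                     p.value = unname(pval)))
}

#' Predict per-day fresh biomass (PFB)
#'
#' Applies a fitted model to every (plant, day) row of a feature table.
#' Negative raw predictions are clipped to `floor` and flagged.
#'
#' @param model a `pg_model` whose `feature_names` are present in `features`.
#' @param features a [pg_features] table.
#' @param floor clipping floor, g (guards later log-based growth rates).
#' @return data.frame `plant_id`, `day`, `pfb` (g), `clipped` (logical).
#' @export
predict_biomass <- function(model, features, floor = 0.01) {
  stopifnot(inherits(model, "pg_model"))
  cols <- model$feature_names
  if (is.null(cols)) pg_stop("input", "model lacks recorded feature names")
  miss <- setdiff(cols, names(features))
  if (length(miss)) {
    pg_stop("schema", "features missing model predictor column(s): ",
            paste(head(miss, 5), collapse = ", "))
  }
  raw <- predict(model, as.matrix(as.data.frame(features)[, cols]))
  clipped <- raw < floor
  data.frame(plant_id = features$plant_id, day = features$day,
             pfb = pmax(raw, floor), clipped = clipped,
             stringsAsFactors = FALSE)
}
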