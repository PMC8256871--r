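# The eight biomass-prediction model families and their fitting backends.
#
# Families: LM (ordinary least squares), SM (forward-backward stepwise by an
# AIC penalty), PC (principal-component regression), PLS (partial least
# squares, NIPALS), ELASTICNET (glmnet), RF (random forest), GBM (gradient
# boosting via xgboost) and MARS (forward hinge-basis growth with backward
# pruning by generalised cross-validation).

PG_FAMILIES <- c("LM", "SM", "PC", "PLS", "ELASTICNET", "RF", "GBM", "MARS")

#' Model specification
#'
#' @param family one of `"LM"`, `"SM"`, `"PC"`, `"PLS"`, `"ELASTICNET"`,
#'   `"RF"`, `"GBM"`, `"MARS"`.
#' @param tuning_grid optional data.frame of hyperparameter candidates (one
#'   row per candidate); `NULL` uses the documented default grid.
#' @return a `pg_model_spec`.
#' @export
model_spec <- function(family, tuning_grid = NULL) {
  family <- toupper(family)
  if (!family %in% PG_FAMILIES) {
    pg_stop("config", "unknown model family '", family, "' (expected one of ",
            paste(PG_FAMILIES, collapse = ", "), ")")
  }
  if (!is.null(tuning_grid) && nrow(tuning_grid) == 0) {
    pg_stop("config", "model_spec: empty tuning grid")
  }
  structure(list(family = family, tuning_grid = tuning_grid),
            class = "pg_model_spec")
}

# default hyperparameter grids (documented in the methods vignette)
default_grid <- function(family, X) {
  p <- ncol(X); n <- nrow(X)
  switch(family,
    LM = data.frame(dummy = 0),
    SM = data.frame(dummy = 0),
    PC = data.frame(ncomp = seq_len(min(20, p, n - 2))),
    PLS = data.frame(ncomp = seq_len(min(20, p, n - 2))),
    ELASTICNET = expand.grid(alpha = c(0.1, 0.55, 1),
                             lambda_frac = 10^seq(-4, -0.5, length.out = 8)),
    RF = data.frame(mtry = unique(pmax(1, round(p * c(1 / 3, 2 / 3, 1))))),
    GBM = expand.grid(max_depth = 1:3, nrounds = c(100, 300)),
    MARS = data.frame(max_terms = c(9, 15))
  )
}

# ---- preprocessing ---------------------------------------------------------

preproc_fit <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  Ximp <- X
  for (j in seq_len(ncol(X))) Ximp[is.na(Ximp[, j]), j] <- mu[j]
  ctr <- colMeans(Ximp)
  scl <- apply(Ximp, 2, sd)
  scl[scl < 1e-12] <- 1
  list(impute = mu, center = ctr, scale = scl)
}

preproc_apply <- function(pp, X) {
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- pp$impute[j]
  sweep(sweep(X, 2, pp$center), 2, pp$scale, "/")
}

# ---- family backends -------------------------------------------------------
# each backend works on the preprocessed (imputed/centred/scaled) matrix

ols_fit <- function(Z, y) {
  # least squares; least-norm (pseudo-inverse) fallback when rank-deficient
  Z1 <- cbind(1, Z)
  qrz <- qr(Z1)
  rank_def <- qrz$rank < ncol(Z1)
  beta <- if (rank_def) {
    sv <- svd(Z1)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  } else {
    qr.coef(qrz, y)
  }
  list(beta = as.vector(beta), rank_deficient = rank_def)
}

ols_predict <- function(fit, Z) as.vector(cbind(1, Z) %*% fit$beta)

rss_of <- function(Z1, y) {
  f <- .lm.fit(Z1, y)
  sum(f$residuals^2)
}

stepwise_fit <- function(Z, y, max_steps = 30) {
  # forward-backward selection minimising n*log(RSS/n) + 2*k
  n <- length(y)
  aic_of <- function(cols) {
    Z1 <- cbind(1, Z[, cols, drop = FALSE])
    n * log(max(rss_of(Z1, y), 1e-12) / n) + 2 * (length(cols) + 1)
  }
  sel <- integer(0)
  best <- aic_of(sel)
  for (step in seq_len(max_steps)) {
    cand <- list()
    for (j in setdiff(seq_len(ncol(Z)), sel)) {
      cand[[length(cand) + 1]] <- list(cols = c(sel, j))
    }
    for (j in sel) {
      cand[[length(cand) + 1]] <- list(cols = setdiff(sel, j))
    }
    if (!length(cand)) break
    aics <- vapply(cand, function(cc) aic_of(cc$cols), numeric(1))
    if (min(aics) >= best - 1e-8) break
    sel <- cand[[which.min(aics)]]$cols
    best <- min(aics)
  }
  beta <- qr.coef(qr(cbind(1, Z[, sel, drop = FALSE])), y)
  list(cols = sel, beta = as.vector(beta))
}

stepwise_predict <- function(fit, Z) {
  as.vector(cbind(1, Z[, fit$cols, drop = FALSE]) %*% fit$beta)
}

pls_fit <- function(Z, y, ncomp) {
  # NIPALS PLS1 on centred-scaled Z and centred y
  ybar <- mean(y); yc <- y - ybar
  p <- ncol(Z)
  ncomp <- min(ncomp, p, nrow(Z) - 1)
  W <- P <- matrix(0, p, ncomp)
  qv <- xvar <- numeric(ncomp)
  Xd <- Z; yd <- yc
  k_eff <- 0
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- Xd %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    pp <- crossprod(Xd, tt) / tt2
    qq <- sum(yd * tt) / tt2
    W[, k] <- w; P[, k] <- pp; qv[k] <- qq
    xvar[k] <- tt2 * sum(pp^2)   # ||t_k p_k'||_F^2, X variance captured
    Xd <- Xd - tt %*% t(pp)
    yd <- yd - tt * qq
    k_eff <- k
  }
  W <- W[, seq_len(k_eff), drop = FALSE]
  P <- P[, seq_len(k_eff), drop = FALSE]
  qv <- qv[seq_len(k_eff)]
  # coefficient path for 1..k_eff components
  betas <- matrix(0, p, k_eff)
  for (k in seq_len(k_eff)) {
    Wk <- W[, 1:k, drop = FALSE]
    betas[, k] <- Wk %*% solve(crossprod(P[, 1:k, drop = FALSE], Wk),
                               qv[1:k])
  }
  list(betas = betas, ybar = ybar, ncomp = k_eff,
       x_var_explained = cumsum(xvar[seq_len(k_eff)]) / sum(Z^2))
}

pls_predict <- function(fit, Z, ncomp = fit$ncomp) {
  k <- min(ncomp, fit$ncomp)
  as.vector(Z %*% fit$betas[, k] + fit$ybar)
}

pcr_fit <- function(Z, y, ncomp) {
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  keep <- which(pc$sdev > pc$sdev[1] * 1e-9)
  ncomp <- min(ncomp, length(keep), nrow(Z) - 2)
  sc <- pc$x[, seq_len(ncomp), drop = FALSE]
  fit <- lm.fit(cbind(1, sc), y)
  var_explained <- cumsum(pc$sdev^2)[seq_len(ncomp)] / sum(pc$sdev^2)
  list(rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
       coefs = fit$coefficients, ncomp = ncomp,
       x_var_explained = var_explained)
}

pcr_predict <- function(fit, Z, ncomp = fit$ncomp) {
  k <- min(ncomp, fit$ncomp)
  sc <- Z %*% fit$rotation[, seq_len(k), drop = FALSE]
  as.vector(cbind(1, sc) %*% fit$coefs[seq_len(k + 1)])
}

# ---- MARS: forward hinge-basis growth + GCV backward pruning ----------------

mars_basis <- function(X, terms) {
  B <- matrix(1, nrow(X), 1)
  for (tm in terms) {
    v <- X[, tm$var]
    B <- cbind(B, if (tm$dir > 0) pmax(v - tm$knot, 0) else pmax(tm$knot - v, 0))
  }
  B
}

mars_gcv <- function(rss, n, m, penalty = 2) {
  cost <- m + penalty * (m - 1) / 2
  if (cost >= n) return(Inf)
  (rss / n) / (1 - cost / n)^2
}

mars_fit <- function(Z, y, max_terms = 15, n_knots = 7) {
  n <- nrow(Z); p <- ncol(Z)
  knots <- lapply(seq_len(p), function(j) {
    unique(quantile(Z[, j], probs = seq(0.1, 0.9, length.out = n_knots),
                    names = FALSE, type = 7))
  })
  terms <- list()
  B <- matrix(1, n, 1)
  rss <- rss_of(B, y)
  while (length(terms) + 2 <= max_terms) {
    best <- NULL
    for (j in seq_len(p)) {
      for (t in knots[[j]]) {
        h1 <- pmax(Z[, j] - t, 0); h2 <- pmax(t - Z[, j], 0)
        r <- rss_of(cbind(B, h1, h2), y)
        if (is.null(best) || r < best$rss) {
          best <- list(rss = r, var = j, knot = t)
        }
      }
    }
    if (is.null(best) || best$rss > rss * (1 - 1e-6)) break
    terms <- c(terms, list(list(var = best$var, knot = best$knot, dir = 1),
                           list(var = best$var, knot = best$knot, dir = -1)))
    B <- mars_basis(Z, terms)
    rss <- best$rss
  }
  # backward pruning by GCV
  keep <- seq_along(terms)
  best_keep <- keep
  best_gcv <- mars_gcv(rss_of(mars_basis(Z, terms[keep]), y), n,
                       length(keep) + 1)
  cur <- keep
  while (length(cur) > 0) {
    gcvs <- vapply(seq_along(cur), function(i) {
      sub <- cur[-i]
      mars_gcv(rss_of(mars_basis(Z, terms[sub]), y), n, length(sub) + 1)
    }, numeric(1))
    i <- which.min(gcvs)
    cur <- cur[-i]
    if (gcvs[i] < best_gcv) {
      best_gcv <- gcvs[i]; best_keep <- cur
    }
  }
  terms <- terms[best_keep]
  B <- mars_basis(Z, terms)
  beta <- qr.coef(qr(B), y)
  beta[is.na(beta)] <- 0
  list(terms = terms, beta = as.vector(beta))
}

mars_predict <- function(fit, Z) {
  as.vector(mars_basis(Z, fit$terms) %*% fit$beta)
}

# ---- unified fit/predict ----------------------------------------------------

#' Fit a biomass-prediction model
#'
#' Fits one of the eight families on a feature matrix. Preprocessing
#' (training-set mean imputation of missing cells, centring, scaling) is
#' estimated here and stored with the model, so prediction on new data reuses
#' training-set statistics only (no leakage).
#'
#' @param spec a [model_spec()].
#' @param X numeric feature matrix (rows = pots).
#' @param y fresh biomass, g.
#' @param tuning one-row data.frame of hyperparameters; `NULL` picks the
#'   default grid's midpoint.
#' @return a `pg_model` with elements `family`, `tuning`, `complexity`
#'   (components/terms/parameters used) and the backend fit.
#' @export
fit_model <- function(spec, X, y, tuning = NULL) {
  stopifnot(inherits(spec, "pg_model_spec"))
  X <- as.matrix(X)
  if (nrow(X) < 5) pg_stop("input", "fit_model: need n >= 5")
  if (nrow(X) != length(y)) pg_stop("input", "fit_model: X/y size mismatch")
  if (is.null(tuning)) {
    grid <- if (is.null(spec$tuning_grid)) default_grid(spec$family, X) else
      spec$tuning_grid
    tuning <- grid[ceiling(nrow(grid) / 2), , drop = FALSE]
  }
  pp <- preproc_fit(X)
  Z <- preproc_apply(pp, X)
  fam <- spec$family
  fit <- switch(fam,
    LM = ols_fit(Z, y),
    SM = stepwise_fit(Z, y),
    PC = pcr_fit(Z, y, tuning$ncomp),
    PLS = pls_fit(Z, y, tuning$ncomp),
    ELASTICNET = {
      lam <- glmnet_lambda(Z, y, tuning$lambda_frac)
      glmnet::glmnet(Z, y, alpha = tuning$alpha, lambda = lam,
                     standardize = FALSE)
    },
    RF = randomForest::randomForest(Z, y, ntree = 300,
                                    mtry = min(tuning$mtry, ncol(Z))),
    GBM = xgboost::xgboost(x = Z, y = y, nrounds = tuning$nrounds,
                           max_depth = tuning$max_depth, learning_rate = 0.1,
                           nthreads = 1, verbosity = 0,
                           objective = "reg:squarederror"),
    MARS = mars_fit(Z, y, max_terms = tuning$max_terms)
  )
  complexity <- switch(fam,
    LM = ncol(Z),
    SM = length(fit$cols),
    PC = fit$ncomp,
    PLS = fit$ncomp,
    ELASTICNET = sum(as.vector(coef(fit)) != 0) - 1,
    RF = ncol(Z) * 10,    # ensemble: effectively unbounded parameter count
    GBM = ncol(Z) * 10,
    MARS = length(fit$terms)
  )
  structure(list(family = fam, tuning = tuning, preproc = pp, fit = fit,
                 complexity = complexity,
                 rank_deficient = isTRUE(fit$rank_deficient)),
            class = "pg_model")
}

glmnet_lambda <- function(Z, y, frac) {
  lmax <- max(abs(crossprod(Z, y - mean(y)))) / length(y)
  max(lmax, 1e-8) * frac
}

#' @export
predict.pg_model <- function(object, newdata, ...) {
  Z <- preproc_apply(object$preproc, as.matrix(newdata))
  switch(object$family,
    LM = ols_predict(object$fit, Z),
    SM = stepwise_predict(object$fit, Z),
    PC = pcr_predict(object$fit, Z),
    PLS = pls_predict(object$fit, Z),
    ELASTICNET = as.vector(predict(object$fit, Z)),
    RF = as.vector(predict(object$fit, Z)),
    GBM = as.vector(predict(object$fit, Z)),
    MARS = mars_predict(object$fit, Z)
  )
}

#' @export
print.pg_model <- function(x, ...) {
  cat("<pg_model> family ", x$family, ", complexity ", x$complexity, "\n",
      sep = "")
  invisible(x)
}
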