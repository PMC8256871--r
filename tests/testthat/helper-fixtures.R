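# Shared fixtures built in code at test time.

# small synthetic experiment, memoised per (size, seed) within a test run
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function(n_genotypes = 6, n_days = 14, seed = 3, ...) {
  key <- paste(n_genotypes, n_days, seed, deparse(list(...)), collapse = "|")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_experiment(
      sim_config(n_genotypes = n_genotypes, n_days = n_days, seed = seed, ...))
  }
  .sim_cache[[key]]
}

# pfb table from the simulator's noisy latent biomass (bypasses modelling)
truth_pfb <- function(sim, observed = TRUE) {
  B <- if (observed) sim$truth$biomass_observed else sim$truth$biomass
  data.frame(plant_id = rep(rownames(B), each = ncol(B)),
             day = rep(as.integer(colnames(B)), nrow(B)),
             pfb = as.vector(t(B)), stringsAsFactors = FALSE)
}

# rank-3 latent-factor dataset with p collinear features, for model selection
make_lowrank_data <- function(n = 120, p = 42, rank = 3, noise = 0.3,
                              seed = 1) {
  set.seed(seed)
  Fmat <- matrix(rnorm(n * rank), n, rank)
  L <- matrix(rnorm(rank * p), rank, p)
  X <- Fmat %*% L + matrix(rnorm(n * p, 0, 0.05), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  beta <- rnorm(rank, 0, 1.5)
  y <- Fmat %*% beta + rnorm(n, 0, noise)
  list(X = X, y = as.vector(y))
}

# independent brute-force Duncan letters: literal all-pairs protected test
# plus insert-absorb letter assignment (no shared code with duncan_mrt)
duncan_bruteforce <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  fit <- lm(values ~ factor(groups))
  mse <- sum(residuals(fit)^2) / fit$df.residual
  dfe <- fit$df.residual
  means <- sort(tapply(values, groups, mean), decreasing = TRUE)
  # stable tie-break by name, matching the implementation's ordering contract
  means <- means[order(-means, names(means))]
  ns <- tapply(values, groups, length)[names(means)]
  k <- length(means)
  nh <- k / sum(1 / ns)
  crit <- function(r) {
    p <- (1 - alpha)^(r - 1)
    q <- suppressWarnings(qtukey(p, r, dfe))
    if (!is.finite(q)) {
      q <- uniroot(function(x) ptukey(x, r, dfe) - p, c(1e-3, 100))$root
    }
    q * sqrt(mse / nh)
  }
  sig <- matrix(FALSE, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a >= b) next
    significant <- (means[a] - means[b]) >= crit(b - a + 1)
    if (significant) {
      # protection: not significant if inside any non-significant wider span
      for (i in seq_len(a)) for (j in b:k) {
        if ((means[i] - means[j]) < crit(j - i + 1)) significant <- FALSE
      }
    }
    sig[a, b] <- sig[b, a] <- significant
  }
  # insert-absorb letter assignment
  cols <- list(seq_len(k))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    if (!sig[a, b]) next
    for (ci in seq_along(cols)) {
      if (all(c(a, b) %in% cols[[ci]])) {
        cols[[length(cols) + 1]] <- setdiff(cols[[ci]], a)
        cols[[ci]] <- setdiff(cols[[ci]], b)
      }
    }
    # absorb duplicated/contained columns
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] %in% cols[[cj]])) keep[ci] <- FALSE
    }
    cols <- cols[keep]
  }
  ord <- order(vapply(cols, min, numeric(1)))
  cols <- cols[ord]
  lett <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, function(cc) i %in% cc, logical(1)))],
          collapse = "")
  }, character(1))
  data.frame(group = names(means), mean = as.numeric(means), letters = lett,
             stringsAsFactors = FALSE)
}
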