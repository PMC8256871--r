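# GLM ANOVA with normality-driven log transform, and the Duncan multiple
# range test with a compact letter display.

#' ANOVA for a derived trait
#'
#' Fits a linear model and reports a Type-II sums-of-squares ANOVA table.
#' Residual normality is checked with a Shapiro-Wilk test at `alpha_norm`;
#' when rejected the response is log(x + offset)-transformed and the model
#' refitted (recorded in the result).
#'
#' @param data data.frame containing the model variables.
#' @param formula model formula, e.g. `value ~ genotype + treatment`.
#' @param alpha_norm normality-test level triggering the log transform.
#' @param log_offset offset added before the log.
#' @return list with `table` (ANOVA), `model` (lm), `log_transformed`,
#'   `shapiro_p`, `mse`, `df_error`.
#' @export
anova_glm <- function(data, formula, alpha_norm = 0.05, log_offset = 0) {
  mf <- lm(formula, data = data)
  if (mf$df.residual < 1) pg_stop("input", "anova_glm: zero residual df")
  res <- residuals(mf)
  if (sd(res) < 1e-12) pg_stop("degenerate", "anova_glm: constant response")
  samp <- if (length(res) > 4999) sample(res, 4999) else res
  sw <- shapiro.test(samp)$p.value
  transformed <- FALSE
  if (sw < alpha_norm) {
    resp <- all.vars(formula)[1]
    y <- data[[resp]]
    if (min(y, na.rm = TRUE) + log_offset > 0) {
      data[[".log_y"]] <- log(y + log_offset)
      fml2 <- stats::update(formula, .log_y ~ .)
      mf <- lm(fml2, data = data)
      transformed <- TRUE
    }
  }
  tab <- car::Anova(mf, type = 2)
  list(table = tab, model = mf, log_transformed = transformed,
       shapiro_p = sw, mse = sum(residuals(mf)^2) / mf$df.residual,
       df_error = mf$df.residual)
}

qtukey_safe <- function(p, nmeans, df) {
  q <- suppressWarnings(qtukey(p, nmeans, df))
  if (is.finite(q)) return(q)
  # qtukey can fail to converge for large nmeans; invert ptukey instead
  stats::uniroot(function(x) stats::ptukey(x, nmeans, df) - p,
                 lower = 1e-3, upper = 100, tol = 1e-8)$root
}

duncan_ranges <- function(k, df, alpha, se) {
  # critical range for a span of r ordered means: studentized-range quantile
  # at Duncan's protected level 1-(1-alpha)^(r-1)
  vapply(2:k, function(r) {
    qtukey_safe((1 - alpha)^(r - 1), r, df) * se
  }, numeric(1))
}

#' Duncan multiple range test with compact letter display
#'
#' Groups are sorted by mean; the difference of the means spanning r ordered
#' positions is compared with the critical range
#' `R_r = q(1-(1-alpha)^(r-1); r, df) * sqrt(MSE / n_h)` (harmonic mean n for
#' unequal group sizes, flagged). Duncan's protection applies: a pair inside
#' a span whose range is non-significant is itself non-significant. Letters
#' are assigned so that any two groups sharing a letter are not significantly
#' different; the display is order-consistent (a letter covers a contiguous
#' run of ordered means).
#'
#' @param values numeric trait values.
#' @param groups group labels (e.g. genotype).
#' @param alpha significance level.
#' @param mse,df_error error mean square and df from an ANOVA; computed from
#'   a one-way fit of `values ~ groups` when omitted.
#' @return a `pg_duncan`: data.frame `group`, `mean`, `n`, `letters`, sorted
#'   by decreasing mean (ties broken by group label), with attributes
#'   `ranges`, `alpha`, `mse`, `df_error`, `unequal_n`.
#' @export
duncan_mrt <- function(values, groups, alpha = 0.05, mse = NULL,
                       df_error = NULL) {
  groups <- as.character(groups)
  keep <- is.finite(values)
  values <- values[keep]; groups <- groups[keep]
  if (length(unique(groups)) < 1) pg_stop("input", "duncan_mrt: no groups")
  if (is.null(mse) || is.null(df_error)) {
    if (length(unique(groups)) == 1) {
      mse <- var(values); df_error <- length(values) - 1
    } else {
      fit <- lm(values ~ factor(groups))
      mse <- sum(residuals(fit)^2) / fit$df.residual
      df_error <- fit$df.residual
    }
  }
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ord <- order(-means, names(means))
  means <- means[ord]; ns <- ns[ord]
  k <- length(means)
  if (k == 1) {
    out <- data.frame(group = names(means), mean = as.numeric(means),
                      n = as.integer(ns), letters = "a",
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("pg_duncan", "data.frame"),
                     ranges = numeric(0), alpha = alpha, mse = mse,
                     df_error = df_error, unequal_n = FALSE))
  }
  unequal <- length(unique(ns)) > 1
  nh <- k / sum(1 / ns)             # harmonic mean group size
  se <- sqrt(mse / nh)
  ranges <- duncan_ranges(k, df_error, alpha, se)   # ranges[r-1] = R_r

  # raw span test: span (i, j) non-significant if mean_i - mean_j < R_(j-i+1)
  raw_ns <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      raw_ns[i, j] <- (means[i] - means[j]) < ranges[j - i]
    }
  }
  # protection: pair (a, b) non-significant if contained in any raw
  # non-significant span
  nonsig <- matrix(FALSE, k, k)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      hit <- FALSE
      for (i in seq_len(a)) {
        if (any(raw_ns[i, b:k])) { hit <- TRUE; break }
      }
      nonsig[a, b] <- hit
    }
  }
  # letters: maximal contiguous non-significant intervals
  reach <- vapply(seq_len(k), function(i) {
    r <- i
    while (r < k && nonsig[i, r + 1]) r <- r + 1L
    as.integer(r)
  }, integer(1))
  intervals <- list()
  for (i in seq_len(k)) {
    iv <- c(i, reach[i])
    if (length(intervals) == 0 ||
        intervals[[length(intervals)]][2] < iv[2]) {
      intervals[[length(intervals) + 1]] <- iv
    }
  }
  lett <- rep("", k)
  for (li in seq_along(intervals)) {
    iv <- intervals[[li]]
    idx <- iv[1]:iv[2]
    lett[idx] <- paste0(lett[idx], letters[(li - 1) %% 26 + 1])
  }
  out <- data.frame(group = names(means), mean = as.numeric(means),
                    n = as.integer(ns), letters = lett,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("pg_duncan", "data.frame"), ranges = ranges,
            alpha = alpha, mse = mse, df_error = df_error,
            unequal_n = unequal)
}
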