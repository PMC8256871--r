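# REML variance components and broad-sense heritability on a genotype-mean
# basis: the standard ratio, the Cullis BLUP-difference estimator and the
# Piepho BLUE-difference estimator.

term_var <- function(vc_df, grp) {
  i <- match(grp, vc_df$grp)
  if (is.na(i)) 0 else vc_df$vcov[i]
}

# prediction-error variance of the genotype BLUPs via the mixed-model
# equations: PEV = sigma_e^2 * [C^-1]_gg with
# C = [[X'X, X'Z], [Z'X, Z'Z + sigma_e^2 G^-1]]
blup_pev <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2e <- vc$vcov[vc$grp == "Residual"]
  X <- lme4::getME(fit, "X")
  Z <- lme4::getME(fit, "Z")
  flist <- lme4::getME(fit, "flist")
  asgn <- attr(flist, "assign")
  terms <- names(flist)[asgn]           # random term per block, in Z order
  nlev <- vapply(flist, function(f) nlevels(f), integer(1))[asgn]
  col_term <- rep(terms, nlev)
  gvar <- vapply(col_term, function(tm) term_var(vc, tm), numeric(1))
  keep <- which(gvar > max(gvar, s2e) * 1e-9)
  Z <- Z[, keep, drop = FALSE]
  gvar <- gvar[keep]
  col_term <- col_term[keep]
  Xd <- as.matrix(X)
  ZtX <- as.matrix(Matrix::crossprod(Z, Xd))
  C <- rbind(cbind(crossprod(Xd), t(ZtX)),
             cbind(ZtX, as.matrix(Matrix::crossprod(Z)) +
                     diag(s2e / gvar, length(gvar))))
  Cinv <- solve(C)
  gcols <- ncol(Xd) + which(col_term == "genotype")
  pev <- s2e * Cinv[gcols, gcols, drop = FALSE]
  rownames(pev) <- colnames(pev) <- colnames(Z)[col_term == "genotype"]
  pev
}

mean_pairwise_diff_var <- function(V) {
  g <- nrow(V)
  if (g < 2) return(NA_real_)
  2 * (mean(diag(V)) - (sum(V) - sum(diag(V))) / (g * (g - 1)))
}

build_h2_formulas <- function(df) {
  has <- function(v) length(unique(df[[v]])) > 1
  fixed <- c(if (has("replicate")) "replicate",
             if (has("treatment")) "treatment",
             if (has("DAT")) "DAT")
  rand_int <- c(if (has("treatment")) "(1 | genotype:treatment)",
                if (has("DAT")) "(1 | genotype:DAT)",
                if (has("treatment") && has("DAT")) "(1 | genotype:treatment:DAT)")
  rhs_fixed <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  list(
    blup = as.formula(paste("value ~", rhs_fixed, "+ (1 | genotype)",
                            if (length(rand_int))
                              paste("+", paste(rand_int, collapse = " + "))
                            else "")),
    blue = as.formula(paste("value ~ 0 + genotype +",
                            rhs_fixed,
                            if (length(rand_int))
                              paste("+", paste(rand_int, collapse = " + "))
                            else "")),
    blue_mixed = length(rand_int) > 0
  )
}

#' REML variance components and genotype BLUPs/BLUEs for a derived trait
#'
#' Fits two companion mixed models by REML: one with genotype random (for
#' the genotypic variance and BLUPs) and one with genotype fixed (for BLUEs).
#' Replication, treatment and days-after-treatment (DAT, categorical) enter
#' as fixed effects when they vary; genotype x treatment, genotype x DAT and
#' genotype x treatment x DAT enter as random interactions, as all of them
#' contribute to the phenotypic variance of a repeated daily trait.
#'
#' @param trait data.frame with columns `genotype`, `replicate`, `value` and
#'   optionally `treatment`, `DAT` (constant columns are dropped from the
#'   model).
#' @return a `pg_varcomp`: list with `sigma_g2`, `sigma_e2`, `components`
#'   (named variances incl. interactions), `vdblup` / `vdblue` (mean variance
#'   of a difference of two genotypic BLUPs / BLUEs), `blups`, `blues`,
#'   `n_levels` (replicates, treatments, DAT levels) and `formulas`.
#' @export
fit_variance_components <- function(trait) {
  check_cols(trait, c("genotype", "replicate", "value"), "trait table")
  df <- as.data.frame(trait)
  df <- df[is.finite(df$value), ]
  if (length(unique(df$genotype)) < 2) {
    pg_stop("input", "need >= 2 genotypes")
  }
  if (max(table(df$genotype)) < 2) {
    pg_stop("input", "need >= 2 observations per genotype")
  }
  df$genotype <- factor(df$genotype)
  df$replicate <- factor(df$replicate)
  if (!"treatment" %in% names(df)) df$treatment <- "all"
  if (!"DAT" %in% names(df)) df$DAT <- 0L
  df$treatment <- factor(df$treatment)
  df$DAT <- factor(df$DAT)
  fml <- build_h2_formulas(df)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit_blup <- suppressMessages(suppressWarnings(
    lme4::lmer(fml$blup, data = df, REML = TRUE, control = ctrl)))
  fit_blue <- if (fml$blue_mixed) {
    suppressMessages(suppressWarnings(
      lme4::lmer(fml$blue, data = df, REML = TRUE, control = ctrl)))
  } else {
    lm(fml$blue, data = df)
  }

  vc <- as.data.frame(lme4::VarCorr(fit_blup))
  comps <- setNames(vc$vcov, vc$grp)
  sigma_g2 <- max(0, term_var(vc, "genotype"))
  sigma_e2 <- term_var(vc, "Residual")

  pev <- blup_pev(fit_blup)
  vdblup <- mean_pairwise_diff_var(pev)

  # BLUEs: genotype fixed (cell-mean coding), variance of pairwise contrasts
  Vb <- as.matrix(vcov(fit_blue))
  gidx <- grep("^genotype", rownames(Vb))
  Vg <- Vb[gidx, gidx, drop = FALSE]
  vdblue <- mean_pairwise_diff_var(Vg)

  blups <- lme4::ranef(fit_blup)$genotype
  blues <- if (fml$blue_mixed) lme4::fixef(fit_blue)[gidx] else
    coef(fit_blue)[gidx]

  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 components = comps, vdblup = vdblup, vdblue = vdblue,
                 blups = setNames(blups[[1]], rownames(blups)),
                 blues = setNames(as.numeric(blues),
                                  sub("^genotype", "", rownames(Vb)[gidx])),
                 n_levels = list(reps = length(unique(df$replicate)),
                                 treatments = nlevels(df$treatment),
                                 dat = nlevels(df$DAT)),
                 formulas = fml),
            class = "pg_varcomp")
}

#' Standard broad-sense heritability
#'
#' `H2 = sigma_g^2 / sigma_p^2` where the phenotypic variance is composed on
#' a genotype-mean basis: each interaction and the residual variance is
#' divided by the number of levels over which genotype means are averaged
#' (treatments, DAT levels and replicates).
#'
#' @param vc a `pg_varcomp` from [fit_variance_components()].
#' @return H-squared in [0, 1] (`NA` if the phenotypic variance is zero).
#' @export
h2_standard <- function(vc) {
  nl <- vc$n_levels
  comps <- vc$components
  gv <- function(nm) if (nm %in% names(comps)) max(0, comps[[nm]]) else 0
  sigma_p2 <- vc$sigma_g2 +
    gv("genotype:treatment") / nl$treatments +
    gv("genotype:DAT") / nl$dat +
    gv("genotype:treatment:DAT") / (nl$treatments * nl$dat) +
    vc$sigma_e2 / (nl$treatments * nl$dat * nl$reps)
  if (sigma_p2 <= 0) return(NA_real_)
  vc$sigma_g2 / sigma_p2
}

#' Cullis broad-sense heritability
#'
#' `H2 = 1 - vdBLUP / (2 sigma_g^2)` with `vdBLUP` the mean variance of a
#' difference of two genotypic BLUPs; clamped to [0, 1]; defined as 0 when
#' the genotypic variance is 0.
#'
#' @param sigma_g2 genotypic variance (or a `pg_varcomp`).
#' @param vdblup mean BLUP-difference variance (ignored when a `pg_varcomp`
#'   is supplied).
#' @export
h2_cullis <- function(sigma_g2, vdblup = NULL) {
  if (inherits(sigma_g2, "pg_varcomp")) {
    vdblup <- sigma_g2$vdblup; sigma_g2 <- sigma_g2$sigma_g2
  }
  if (sigma_g2 <= 0) return(0)
  min(1, max(0, 1 - vdblup / (2 * sigma_g2)))
}

#' Piepho broad-sense heritability
#'
#' `H2 = sigma_g^2 / (sigma_g^2 + vdBLUE / 2)` with `vdBLUE` the mean
#' variance of a difference of two genotypic BLUEs.
#'
#' @param sigma_g2 genotypic variance (or a `pg_varcomp`).
#' @param vdblue mean BLUE-difference variance.
#' @export
h2_piepho <- function(sigma_g2, vdblue = NULL) {
  if (inherits(sigma_g2, "pg_varcomp")) {
    vdblue <- sigma_g2$vdblue; sigma_g2 <- sigma_g2$sigma_g2
  }
  if (sigma_g2 < 0) pg_stop("input", "h2_piepho: sigma_g2 must be >= 0")
  denom <- sigma_g2 + vdblue / 2
  if (denom <= 0) return(NA_real_)
  min(1, max(0, sigma_g2 / denom))
}

#' Heritability report for a trait
#'
#' Convenience wrapper: fits the variance components and returns all three
#' broad-sense heritability estimates.
#'
#' @inheritParams fit_variance_components
#' @param trait_name label for the report.
#' @return a `pg_h2` list: `trait`, `H2_standard`, `H2_cullis`, `H2_piepho`,
#'   `varcomp`.
#' @export
heritability_report <- function(trait, trait_name = "trait") {
  vc <- fit_variance_components(trait)
  structure(list(trait = trait_name,
                 H2_standard = h2_standard(vc),
                 H2_cullis = h2_cullis(vc),
                 H2_piepho = h2_piepho(vc),
                 varcomp = vc),
            class = "pg_h2")
}

#' @export
print.pg_h2 <- function(x, ...) {
  cat("<pg_h2> ", x$trait, ": standard ", round(x$H2_standard, 3),
      ", Cullis ", round(x$H2_cullis, 3), ", Piepho ",
      round(x$H2_piepho, 3), "\n", sep = "")
  invisible(x)
}
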