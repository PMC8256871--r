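# Variance components and the three broad-sense heritability estimators.

fake_vc <- function(sigma_g2, sigma_e2, reps = 3, treatments = 1, dat = 1,
                    vdblup = NA, vdblue = NA) {
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 components = c(genotype = sigma_g2, Residual = sigma_e2),
                 vdblup = vdblup, vdblue = vdblue,
                 n_levels = list(reps = reps, treatments = treatments,
                                 dat = dat)),
            class = "pg_varcomp")
}

sim_oneway <- function(sigma_g2, seed, n_geno = 24, reps = 3,
                       sigma_e2 = 1) {
  set.seed(seed)
  g <- sprintf("G%02d", seq_len(n_geno))
  df <- expand.grid(genotype = g, replicate = seq_len(reps),
                    stringsAsFactors = FALSE)
  ge <- rnorm(n_geno, 0, sqrt(sigma_g2)); names(ge) <- g
  df$value <- 10 + ge[df$genotype] + rnorm(nrow(df), 0, sqrt(sigma_e2))
  df
}

test_that("heritability formulas match hand-computed fixtures", {
  # standard: sigma_g2 3, sigma_p2 = 3 + 3/3 = 4 -> 0.75
  expect_equal(h2_standard(fake_vc(3, 3)), 0.75)
  expect_equal(h2_standard(fake_vc(0, 3)), 0)
  # Cullis: 1 - vdBLUP / (2 sigma_g2)
  expect_equal(h2_cullis(2, 1), 0.75)
  expect_equal(h2_cullis(2, 0), 1)
  expect_equal(h2_cullis(0, 5), 0)
  # Piepho: sigma_g2 / (sigma_g2 + vdBLUE/2)
  expect_equal(h2_piepho(3, 2), 0.75)
  expect_equal(h2_piepho(0, 2), 0)
  expect_equal(h2_piepho(3, 1e-12), 1, tolerance = 1e-9)
  # clamping and monotonicity in sigma_g2
  expect_lte(h2_cullis(0.1, 5), 1)
  expect_gte(h2_cullis(0.1, 5), 0)
  h <- vapply(c(0.5, 1, 2, 4), function(s) h2_cullis(s, 1), numeric(1))
  expect_true(all(diff(h) >= 0))
})

test_that("variance components need at least two genotypes and replicates", {
  df <- sim_oneway(1, 1)
  expect_error(fit_variance_components(df[df$genotype == "G01", ]),
               ">= 2 genotypes")
  expect_error(
    fit_variance_components(df[!duplicated(df$genotype), ]),
    "observations per genotype")
})

test_that("REML recovers the genotypic variance on balanced data", {
  ests <- vapply(1:12, function(s) {
    fit_variance_components(sim_oneway(sigma_g2 = 7 / 9, seed = 400 + s))$sigma_g2
  }, numeric(1))
  expect_lt(abs(median(ests) - 7 / 9) / (7 / 9), 0.35)
  # null case at large per-genotype n: estimates collapse toward zero
  null_small <- vapply(1:12, function(s) {
    vc <- fit_variance_components(sim_oneway(0, 500 + s, reps = 10))
    vc$sigma_g2 < 0.05 * vc$sigma_e2
  }, logical(1))
  expect_gte(mean(null_small), 0.8)
})

test_that("three estimators agree on balanced designs near the target H2", {
  h2s <- vapply(1:10, function(s) {
    h <- heritability_report(sim_oneway(7 / 9, 600 + s))
    c(h$H2_standard, h$H2_cullis, h$H2_piepho)
  }, numeric(3))
  expect_lt(abs(median(h2s[1, ]) - 0.7), 0.15)
  expect_lt(median(abs(h2s[1, ] - h2s[2, ])), 0.05)
  expect_lt(median(abs(h2s[2, ] - h2s[3, ])), 0.05)
  expect_true(all(h2s >= 0 & h2s <= 1))
})

test_that("H2 approaches 1 as residual noise vanishes", {
  h <- heritability_report(sim_oneway(1, 3, sigma_e2 = 1e-4))
  expect_gt(h$H2_standard, 0.99)
  expect_gt(h$H2_cullis, 0.99)
  expect_gt(h$H2_piepho, 0.99)
})

test_that("the full factorial model with treatment and DAT fits and composes", {
  set.seed(77)
  g <- sprintf("G%02d", 1:10)
  df <- expand.grid(genotype = g, treatment = c("C", "S"), replicate = 1:3,
                    DAT = 1:4, stringsAsFactors = FALSE)
  ge <- rnorm(10, 0, 1); names(ge) <- g
  gt <- matrix(rnorm(20, 0, 0.5), 10, 2, dimnames = list(g, c("C", "S")))
  df$value <- ge[df$genotype] + gt[cbind(df$genotype, df$treatment)] +
    rnorm(nrow(df), 0, 1)
  vc <- fit_variance_components(df)
  expect_true(vc$sigma_g2 > 0)
  expect_true("genotype:treatment" %in% names(vc$components))
  h2 <- h2_standard(vc)
  expect_true(h2 >= 0 && h2 <= 1)
  # interaction variance dilutes H2 below the no-interaction ratio
  expect_lt(h2, vc$sigma_g2 / (vc$sigma_g2 + vc$sigma_e2 / 24) + 0.2)
})
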