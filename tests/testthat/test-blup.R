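test_that("variance components solve the EMS system and agree with REML", {
  skip_if_not_installed("lme4")
  for (seed in c(11, 12)) {
    cfg <- synth_config(G = 8, E = 3, R = 3, seed = seed, n_donors = 0)
    met <- generate_met(cfg)$met
    an <- pooled_anova(met, "Y")
    vc <- variance_components(an)

    # linear-system oracle on brute-force mean squares
    sol <- oracle_vc_linear(met)
    expect_equal(vc$sigma2_g, sol[["sigma2_g"]], tolerance = 1e-10)
    expect_equal(vc$sigma2_ge, sol[["sigma2_ge"]], tolerance = 1e-10)
    expect_equal(vc$sigma2_e, sol[["sigma2_e"]], tolerance = 1e-10)

    # REML equivalence on balanced data (to lme4 convergence accuracy)
    d <- as.data.frame(met); d$repf <- factor(d$rep)
    fit <- lme4::lmer(value ~ env + env:repf + (1 | genotype) +
                        (1 | genotype:env),
                      data = d, REML = TRUE)
    v <- as.data.frame(lme4::VarCorr(fit))
    vv <- setNames(v$vcov, v$grp)
    expect_equal(vc$sigma2_g, vv[["genotype"]], tolerance = 1e-4)
    expect_equal(vc$sigma2_ge, vv[["genotype:env"]], tolerance = 1e-4)
    expect_equal(vc$sigma2_e, vv[["Residual"]], tolerance = 1e-4)
  }
})

test_that("equal mean squares give zero genetic variances, with clamp flags", {
  an <- as_met_anova(data.frame(source = c("GEN", "ENV:GEN", "Residuals"),
                                df = c(5, 10, 24), MS = c(4, 4, 4)),
                     design = c(G = 6, E = 3, R = 3))
  vc <- variance_components(an)
  expect_equal(vc$sigma2_g, 0)
  expect_equal(vc$sigma2_ge, 0)
  expect_equal(vc$sigma2_e, 4)
  an2 <- as_met_anova(data.frame(source = c("GEN", "ENV:GEN", "Residuals"),
                                 df = c(5, 10, 24), MS = c(1, 8, 2)),
                      design = c(G = 6, E = 3, R = 3))
  vc2 <- variance_components(an2)
  expect_true("sigma2_g" %in% vc2$clamped)
  expect_equal(vc2$sigma2_g, 0)
})

test_that("variance components recover simulated truth on average", {
  set.seed(23)
  est <- replicate(120, {
    cfg <- synth_config(G = 30, E = 3, R = 3, mu = 50, sigma_g = 2,
                        sigma_ge_noise = 1, sigma_e = 1, lambda = 0,
                        n_donors = 0, seed = sample.int(1e6, 1))
    vc <- variance_components(pooled_anova(generate_met(cfg)$met, "Y"))
    c(vc$sigma2_g, vc$sigma2_ge, vc$sigma2_e)
  })
  means <- rowMeans(est)
  expect_equal(means[1], 4, tolerance = 0.15)
  expect_equal(means[2], 1, tolerance = 0.15)
  expect_equal(means[3], 1, tolerance = 0.15)
})

test_that("BLUP shrinks toward the grand mean and matches the MME oracle", {
  cfg <- synth_config(G = 10, E = 3, R = 3, seed = 31, n_donors = 0)
  met <- generate_met(cfg)$met
  an <- pooled_anova(met, "Y")
  vc <- variance_components(an)
  m <- cell_means(met, "Y")
  bl <- blup_predicted_means(vc, m)

  shrink <- attr(bl, "shrink")
  expect_gte(shrink, 0); expect_lte(shrink, 1)
  mu <- attr(an, "grand_mean")
  # predictions lie between the grand mean and the observed means
  expect_true(all(
    (bl$predicted_mean - mu) * (bl$observed_mean - mu) >= -1e-12))
  expect_true(all(abs(bl$predicted_mean - mu) <= abs(bl$observed_mean - mu) + 1e-12))
  # same ranking as observed means
  expect_equal(order(bl$predicted_mean), order(bl$observed_mean))
  expect_equal(cor(bl$predicted_mean, bl$observed_mean, method = "spearman"), 1)

  # Henderson mixed-model-equation oracle
  u <- oracle_mme_blup(met, vc)
  expect_equal(bl$blup_effect, unname(u[bl$genotype]), tolerance = 1e-6)
})

test_that("BLUP limiting cases: total shrinkage and no shrinkage", {
  m <- structure(matrix(c(10, 20, 30, 40, 50, 60), nrow = 3,
                        dimnames = list(c("a", "b", "c"), c("e1", "e2"))),
                 class = c("means_matrix", "matrix", "array"))
  vc0 <- structure(list(sigma2_g = 0, sigma2_ge = 1, sigma2_e = 1,
                        grand_mean = 35, design = list(G = 3, E = 2, R = 2),
                        clamped = "sigma2_g"),
                   class = "variance_components")
  bl0 <- blup_predicted_means(vc0, m)
  expect_equal(bl0$predicted_mean, rep(35, 3))

  vc1 <- structure(list(sigma2_g = 4, sigma2_ge = 0, sigma2_e = 0,
                        grand_mean = 35, design = list(G = 3, E = 2, R = 2),
                        clamped = character(0)),
                   class = "variance_components")
  bl1 <- blup_predicted_means(vc1, m)
  expect_equal(bl1$predicted_mean, unname(rowMeans(m)))

  vc_all0 <- structure(list(sigma2_g = 0, sigma2_ge = 0, sigma2_e = 0,
                            grand_mean = 35, design = list(G = 3, E = 2, R = 2),
                            clamped = character(0)),
                       class = "variance_components")
  bl2 <- blup_predicted_means(vc_all0, m)
  expect_true(isTRUE(attr(bl2, "degenerate")))
  expect_equal(bl2$predicted_mean, rep(35, 3))
})

test_that("heritability, accuracy and CV follow their closed forms", {
  vc <- structure(list(sigma2_g = 6, sigma2_ge = 0, sigma2_e = 0,
                       grand_mean = 20, design = list(G = 5, E = 3, R = 3),
                       clamped = character(0)),
                  class = "variance_components")
  gs <- genetic_stats(vc)
  expect_equal(gs$H2, 1)
  expect_equal(gs$As, 1)
  vc$sigma2_e <- 4
  gs2 <- genetic_stats(vc)
  expect_equal(gs2$CV, 10)
  expect_equal(gs2$H2, 6 / (6 + 4 / 9), tolerance = 1e-12)
  vc$grand_mean <- 0
  expect_error(genetic_stats(vc), "domain error")
})

test_that("selection accuracy is near 1 in a high-heritability regime", {
  set.seed(41)
  as_vals <- replicate(30, {
    cfg <- synth_config(G = 32, E = 3, R = 3, sigma_g = 25, sigma_e = 2,
                        sigma_ge_noise = 0.5, n_donors = 0,
                        seed = sample.int(1e6, 1))
    vc <- variance_components(pooled_anova(generate_met(cfg)$met, "Y"))
    genetic_stats(vc)$As
  })
  expect_true(all(as_vals >= 0.95))
})

test_that("H2 recovery stays within 0.1 of planted truth on average", {
  set.seed(47)
  errs <- replicate(100, {
    cfg <- synth_config(seed = sample.int(1e6, 1), n_donors = 0)
    tr <- generate_met(cfg)
    vc <- variance_components(pooled_anova(tr$met, "Y"))
    genetic_stats(vc)$H2 - tr$truth$H2
  })
  expect_lt(abs(mean(errs)), 0.1)
})

test_that("WAASB vanishes for additive data and matches the weighted-sum oracle", {
  addit <- make_met(G = 5, E = 3, R = 3, fun = function(i, j, r) 10 * i + j)
  an <- pooled_anova(addit, "Y")
  vc <- variance_components(an)
  expect_equal(as.vector(waasb(addit, vc, "Y")), rep(0, 5), tolerance = 1e-8)

  # random fixture with a genuine planted interaction
  cfg <- synth_config(G = 6, E = 4, R = 3, sigma_g = 4, sigma_ge_noise = 2,
                      sigma_e = 2, lambda = 60, interaction_rank = 1,
                      n_donors = 0, seed = 51)
  met <- generate_met(cfg)$met
  vc2 <- variance_components(pooled_anova(met, "Y"))
  expect_gt(vc2$sigma2_ge, 0)
  w <- waasb(met, vc2, "Y")
  # direct oracle: shrunk double-centered matrix, explicit svd, weighted sum
  m <- cell_means(met, "Y")
  cen <- sweep(unclass(m), 1, rowMeans(m))
  cen <- sweep(cen, 2, colMeans(m)) + mean(m)
  B <- vc2$sigma2_ge / (vc2$sigma2_ge + vc2$sigma2_e / 3) * cen
  sv <- svd(B)
  lam <- sv$d[1:3]^2
  wts <- 100 * lam / sum(lam)
  sc <- abs(sv$u[, 1:3] %*% diag(sqrt(sv$d[1:3])))
  expect_equal(as.vector(w), drop(sc %*% wts) / sum(wts), tolerance = 1e-8)
})

test_that("WAASB is invariant to axis sign flips and genotype relabeling", {
  met <- make_met(G = 6, E = 3, R = 3, seed = 52)
  vc <- variance_components(pooled_anova(met, "Y"))
  w <- waasb(met, vc, "Y")
  d <- as.data.frame(met)
  perm <- rev(sort(unique(d$genotype)))
  d$genotype <- setNames(perm, sort(unique(d$genotype)))[d$genotype]
  w2 <- waasb(met_table(d, percent_traits = character(0)), vc, "Y")
  expect_equal(unname(w2[perm]), unname(w[sort(unique(met$genotype))]),
               tolerance = 1e-10)
})

test_that("quadrants follow the mean/WAASB thresholds with ties to quadrant IV", {
  mu <- 50; mw <- 2
  expect_equal(unname(quadrant_classify(c(55, 55, 45, 45), c(1, 3, 1, 3),
                                        mu, mw)),
               c("IV", "II", "III", "I"))
  # genotype exactly on both thresholds
  expect_equal(unname(quadrant_classify(50, 2, mu, mw)), "IV")
  # affine rescaling of the trait axis applied to values and threshold
  m <- c(55, 45, 52, 41); w <- c(1, 3, 2.5, 0.5)
  q1 <- quadrant_classify(m, w, 50, 2)
  q2 <- quadrant_classify(3 * m + 7, w, 3 * 50 + 7, 2)
  expect_equal(q1, q2)
})

test_that("blup_waasb wrapper returns a coherent bundle", {
  cfg <- synth_config(G = 8, E = 3, R = 3, seed = 61, n_donors = 0)
  met <- generate_met(cfg)$met
  b <- blup_waasb(met, "Y")
  expect_named(b$stats, c("H2", "As", "CV"))
  expect_equal(length(b$waasb), 8)
  expect_true(all(b$quadrant %in% c("I", "II", "III", "IV")))
  expect_equal(cor(b$blup$predicted_mean, b$blup$observed_mean,
                   method = "spearman"), 1)
})
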