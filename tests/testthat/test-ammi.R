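test_that("pooled ANOVA matches the brute-force SS oracle on random data", {
  for (seed in 1:3) {
    met <- make_met(G = 6, E = 3, R = 3, seed = seed)
    an <- pooled_anova(met, "Y")
    ss <- oracle_anova_ss(met)
    expect_equal(setNames(an$SS, an$source), ss, tolerance = 1e-10)
    expect_equal(an$df, c(2, 6, 5, 10, 30))
    expect_equal(an$MS, an$SS / an$df)
    expect_equal(sum(an$pctSS), 100, tolerance = 1e-8)
    # SS additivity against the raw total
    d <- as.data.frame(met)
    expect_equal(sum(an$SS), sum((d$value - mean(d$value))^2), tolerance = 1e-8)
  }
})

test_that("pooled ANOVA degenerates correctly on constant and additive data", {
  const <- make_met(G = 4, E = 3, R = 3, fun = function(i, j, r) 5)
  an <- pooled_anova(const, "Y")
  expect_equal(an$SS, rep(0, 5), tolerance = 1e-18)

  addit <- make_met(G = 4, E = 3, R = 3, fun = function(i, j, r) 10 * i)
  an2 <- pooled_anova(addit, "Y")
  ss <- setNames(an2$SS, an2$source)
  expect_equal(ss[["ENV:GEN"]], 0, tolerance = 1e-16)
  expect_equal(ss[["ENV"]], 0, tolerance = 1e-16)
  expect_gt(ss[["GEN"]], 0)
  expect_equal(ss[["GEN"]] / sum(ss), 1, tolerance = 1e-12)
})

test_that("pooled ANOVA SS are invariant to a global shift", {
  met <- make_met(G = 5, E = 3, R = 2, seed = 4)
  an <- pooled_anova(met, "Y")
  d <- as.data.frame(met)
  d$value <- d$value + 1000
  an2 <- pooled_anova(met_table(d, percent_traits = character(0)), "Y")
  expect_equal(an$SS, an2$SS, tolerance = 1e-6)
})

test_that("pooled ANOVA rejects unbalanced or replicate-free designs", {
  met <- make_met(G = 3, E = 2, R = 2)
  d <- as.data.frame(met)[-1, ]
  suppressWarnings(unb <- met_table(d, percent_traits = character(0)))
  expect_error(pooled_anova(unb, "Y"), "design error")
  one_rep <- make_met(G = 3, E = 2, R = 1)
  expect_error(pooled_anova(one_rep, "Y"), "design error")
})

test_that("AMMI decomposition reconstructs the centered matrix and matches the eigen oracle", {
  for (seed in 1:5) {
    met <- make_met(G = 4, E = 3, R = 3, seed = seed + 10)
    an <- pooled_anova(met, "Y")
    m <- cell_means(met, "Y")
    fit <- ammi_decompose(m, an)

    # centering identity
    expect_equal(unname(rowSums(fit$centered)), rep(0, 4), tolerance = 1e-10)
    expect_equal(unname(colSums(fit$centered)), rep(0, 3), tolerance = 1e-10)

    # reconstruction sum_k sqrt(lambda_k) alpha_k gamma_k'
    rec <- fit$scores_g %*% (sqrt(fit$eigenvalues) * t(fit$scores_e))
    expect_equal(rec, fit$centered, tolerance = 1e-10, ignore_attr = TRUE)

    # orthonormal score vectors
    expect_equal(crossprod(fit$scores_g), diag(2), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(crossprod(fit$scores_e), diag(2), tolerance = 1e-10,
                 ignore_attr = TRUE)

    # theta matches eigen oracle, descending, sums to 100
    expect_equal(fit$theta_pct, oracle_eigen_theta(m), tolerance = 1e-8)
    expect_false(is.unsorted(rev(fit$theta_pct)))
    expect_equal(sum(fit$theta_pct), 100, tolerance = 1e-6)

    # replicate-scale eigenvalue sum equals the interaction SS
    expect_equal(3 * sum(fit$eigenvalues),
                 an$SS[an$source == "ENV:GEN"], tolerance = 1e-8)
  }
})

test_that("a rank-1 interaction loads entirely on the first axis", {
  a <- c(-1, 0, 1) / sqrt(2); b <- c(1, -1, 0, 0) * 2
  met <- make_met(G = 4, E = 3, R = 2,
                  fun = function(i, j, r) 50 + 3 * i + b[i] * a[j])
  an <- pooled_anova(met, "Y")
  fit <- ammi_decompose(cell_means(met, "Y"), an)
  expect_equal(fit$theta_pct[1], 100, tolerance = 1e-8)
  expect_equal(fit$eigenvalues[-1], rep(0, length(fit$eigenvalues) - 1),
               tolerance = 1e-8)
})

test_that("axis sign convention puts the largest environment loading positive", {
  met <- make_met(G = 8, E = 3, R = 3, seed = 21)
  fit <- ammi_decompose(cell_means(met, "Y"), pooled_anova(met, "Y"))
  for (k in seq_along(fit$eigenvalues)) {
    expect_gt(fit$scores_e[which.max(abs(fit$scores_e[, k])), k], 0)
  }
})

test_that("Gollob axis tests use G+E-1-2k df and the published-style layout", {
  met <- make_met(G = 10, E = 3, R = 3, seed = 2)
  fit <- ammi_decompose(cell_means(met, "Y"), pooled_anova(met, "Y"))
  expect_equal(fit$pc_tests$df, c(10 + 3 - 1 - 2, 10 + 3 - 1 - 4))
  expect_equal(fit$pc_tests$SS, 3 * fit$eigenvalues, tolerance = 1e-10)
  # n_significant bounded by the cap and at least 1
  expect_gte(fit$n_significant, 1)
  expect_lte(fit$n_significant, 2)
})

test_that("sequential F_R axis test is close to nominal size under the pure-noise null", {
  set.seed(71)
  nrep <- 400
  rej <- logical(nrep)
  for (i in seq_len(nrep)) {
    cfg <- synth_config(G = 10, E = 3, R = 3, sigma_g = 5, sigma_ge_noise = 0,
                        sigma_e = 5, lambda = 0, n_donors = 0, seed = 40000 + i)
    met <- generate_met(cfg)$met
    fit <- ammi_decompose(cell_means(met, "Y"), pooled_anova(met, "Y"),
                          test = "fr")
    rej[i] <- fit$pc_tests$p[1] < 0.05
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("signal/noise partition reproduces the printed arithmetic and clamps at zero", {
  an <- as_met_anova(data.frame(source = c("GEN", "ENV:GEN", "Residuals"),
                                df = c(31, 62, 186),
                                MS = c(8931.10, 432.50, 29.10)),
                     design = c(G = 32, E = 3, R = 3))
  p <- partition_signal_noise(an)
  expect_equal(p$GSI_noise_SS, 1804.20, tolerance = 1e-10)
  expect_equal(p$GSI_signal_SS, 62 * 432.50 - 1804.20, tolerance = 1e-10)
  expect_equal(round(p$pct_signal, 2), 93.27)
  expect_equal(p$pct_signal + p$pct_noise, 100, tolerance = 1e-10)

  an0 <- as_met_anova(data.frame(source = c("ENV:GEN", "Residuals"),
                                 df = c(10, 40), MS = c(3, 0)),
                      design = c(G = 6, E = 3, R = 3))
  p0 <- partition_signal_noise(an0)
  expect_equal(p0$GSI_noise_SS, 0)
  expect_equal(p0$pct_signal, 100)

  an_neg <- as_met_anova(data.frame(source = c("ENV:GEN", "Residuals"),
                                    df = c(10, 40), MS = c(1, 50)),
                         design = c(G = 6, E = 3, R = 3))
  expect_warning(pneg <- partition_signal_noise(an_neg), "clamped")
  expect_equal(pneg$GSI_signal_SS, 0)
  expect_true(pneg$clamped)

  expect_error(partition_signal_noise(
    as_met_anova(data.frame(source = "GEN", df = 3, MS = 1),
                 design = c(G = 4, E = 2, R = 2))), "contract error")
})

test_that("a pure-noise interaction carries little estimated signal", {
  set.seed(19)
  pcts <- replicate(200, {
    cfg <- synth_config(G = 32, E = 3, R = 3, sigma_g = 5, sigma_ge_noise = 0,
                        sigma_e = 5, lambda = 0, n_donors = 0,
                        seed = sample.int(1e6, 1))
    an <- pooled_anova(generate_met(cfg)$met, "Y")
    p <- suppressWarnings(partition_signal_noise(an))
    p$pct_signal
  })
  expect_lt(mean(pcts), 10)
})

test_that("biplot coordinates collapse to the PC1 = 0 line for additive data", {
  met <- make_met(G = 4, E = 3, R = 2, fun = function(i, j, r) 10 * i + j)
  fit <- ammi_decompose(cell_means(met, "Y"), pooled_anova(met, "Y"))
  co <- ammi1_coordinates(fit, cell_means(met, "Y"))
  expect_equal(co$IPCA1, rep(0, nrow(co)), tolerance = 1e-6)
  expect_true(all(co$stable))
})

test_that("biplot flags the environment farthest from the origin", {
  met <- make_met(G = 8, E = 3, R = 3, seed = 33)
  m <- cell_means(met, "Y")
  fit <- ammi_decompose(m, pooled_anova(met, "Y"))
  co <- ammi1_coordinates(fit, m)
  env <- co[co$type == "environment", ]
  expect_equal(attr(co, "farthest_environment"),
               env$entity[which.max(abs(env$IPCA1))])
})

test_that("flipping an axis sign flips genotype and environment scores together", {
  met <- make_met(G = 5, E = 4, R = 2, seed = 8)
  m <- cell_means(met, "Y")
  fit <- ammi_decompose(m, pooled_anova(met, "Y"))
  # all products sqrt(lambda_k) alpha gamma' are invariant by construction:
  # negate axis 1 on both sides and verify reconstruction unchanged
  g2 <- fit$scores_g; e2 <- fit$scores_e
  g2[, 1] <- -g2[, 1]; e2[, 1] <- -e2[, 1]
  rec <- g2 %*% (sqrt(fit$eigenvalues) * t(e2))
  expect_equal(rec, fit$centered, tolerance = 1e-10, ignore_attr = TRUE)
})
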