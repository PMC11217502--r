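# shared fixtures and independent oracles used across test files

# balanced long table with values supplied by `fun(i, j, r)` or drawn randomly
make_met <- function(G = 4, E = 3, R = 3, fun = NULL, trait = "Y", seed = 1) {
  set.seed(seed)
  d <- expand.grid(genotype = sprintf("g%02d", seq_len(G)),
                   env = sprintf("e%d", seq_len(E)),
                   rep = seq_len(R),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$trait <- trait
  d$value <- if (is.null(fun)) {
    rnorm(nrow(d), 50, 5)
  } else {
    mapply(fun, match(d$genotype, unique(d$genotype)),
           match(d$env, unique(d$env)), d$rep)
  }
  met_table(d, percent_traits = character(0))
}

# brute-force balanced two-way-with-nested-blocks SS from group means
oracle_anova_ss <- function(met, trait = "Y") {
  d <- as.data.frame(met[met$trait == trait, ])
  G <- length(unique(d$genotype)); E <- length(unique(d$env))
  R <- length(unique(d$rep))
  gm <- mean(d$value)
  y_j <- tapply(d$value, d$env, mean)
  y_jr <- tapply(d$value, list(d$env, d$rep), mean)
  y_i <- tapply(d$value, d$genotype, mean)
  y_ij <- tapply(d$value, list(d$genotype, d$env), mean)
  ss_env <- G * R * sum((y_j - gm)^2)
  ss_rep <- G * sum((sweep(y_jr, 1, y_j))^2)
  ss_gen <- E * R * sum((y_i - gm)^2)
  ss_ge <- R * sum((sweep(sweep(y_ij, 1, y_i), 2, y_j) + gm)^2)
  cellm <- y_ij[cbind(d$genotype, d$env)]
  # within-cell SS minus the block (replicate-within-environment) SS
  ss_res <- sum((d$value - cellm)^2) - ss_rep
  c(ENV = ss_env, `REP(ENV)` = ss_rep, GEN = ss_gen, `ENV:GEN` = ss_ge,
    Residuals = ss_res)
}

# eigen-decomposition route to the interaction axes (independent of svd path)
oracle_eigen_theta <- function(means) {
  cen <- sweep(unclass(means), 1, rowMeans(means))
  cen <- sweep(cen, 2, colMeans(means)) + mean(means)
  ev <- eigen(crossprod(cen), symmetric = TRUE)$values
  ev <- ev[ev > max(ev[1], 1) * 1e-12]
  100 * ev / sum(ev)
}

# Henderson mixed-model-equation BLUP of genotype effects, dense linear algebra
oracle_mme_blup <- function(met, vc, trait = "Y") {
  d <- as.data.frame(met[met$trait == trait, ])
  d$ge <- interaction(d$genotype, d$env)
  X <- model.matrix(~ factor(env) * factor(rep), d)   # fixed: env, rep(env)
  Z1 <- model.matrix(~ genotype - 1, d)
  Z2 <- model.matrix(~ ge - 1, d)
  Z <- cbind(Z1, Z2)
  q1 <- ncol(Z1); q2 <- ncol(Z2)
  Ginv <- diag(c(rep(vc$sigma2_e / vc$sigma2_g, q1),
                 rep(vc$sigma2_e / vc$sigma2_ge, q2)))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + Ginv))
  rhs <- c(crossprod(X, d$value), crossprod(Z, d$value))
  sol <- qr.solve(C, rhs, tol = 1e-12)
  u1 <- sol[(ncol(X) + 1):(ncol(X) + q1)]
  names(u1) <- sub("^genotype", "", colnames(Z1))
  u1
}

# EMS linear-system oracle for variance components: solve E[MS] = A s2
oracle_vc_linear <- function(met, trait = "Y") {
  ss <- oracle_anova_ss(met, trait)
  d <- as.data.frame(met[met$trait == trait, ])
  G <- length(unique(d$genotype)); E <- length(unique(d$env))
  R <- length(unique(d$rep))
  ms <- ss / c(E - 1, E * (R - 1), G - 1, (G - 1) * (E - 1), E * (G - 1) * (R - 1))
  # rows: MS(GEN), MS(ENV:GEN), MS(Residuals); cols: s2_g, s2_ge, s2_e
  A <- rbind(c(R * E, R, 1),
             c(0,     R, 1),
             c(0,     0, 1))
  sol <- solve(A, ms[c("GEN", "ENV:GEN", "Residuals")])
  names(sol) <- c("sigma2_g", "sigma2_ge", "sigma2_e")
  sol
}
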