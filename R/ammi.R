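#' Pooled analysis of variance over environments
#'
#' Combined ANOVA for a balanced RCBD repeated over environments (seasons),
#' the additive half of the AMMI model. Sources are ENV, REP(ENV) (blocks
#' nested in environments), GEN, the ENV:GEN interaction, and Residuals.
#' ENV is tested against REP(ENV); GEN and ENV:GEN against Residuals.
#'
#' @param x A balanced [met_table()].
#' @param trait Trait to analyse.
#' @return A data.frame of class `met_anova` with columns `source`, `df`,
#'   `SS`, `MS`, `F`, `p`, `pctSS` (percentage of total SS) and attributes
#'   `design`, `grand_mean`, `trait`.
#' @export
pooled_anova <- function(x, trait) {
  stopifnot(inherits(x, "met_table"))
  sub <- x[x$trait == trait, , drop = FALSE]
  d <- .met_design(sub)
  if (!d$balanced) stop("design error: unbalanced table; pooled ANOVA requires ",
                        "a complete balanced design", call. = FALSE)
  if (d$G < 2L || d$E < 2L) stop("design error: need G >= 2 and E >= 2",
                                 call. = FALSE)
  if (d$R < 2L) stop("design error: R = 1 leaves no residual degrees of freedom",
                     call. = FALSE)
  sub$gen <- factor(sub$genotype)
  sub$envf <- factor(sub$env)
  sub$repf <- factor(sub$rep)
  fit <- stats::aov(value ~ envf + envf:repf + gen + envf:gen, data = sub)
  tab <- summary(fit)[[1L]]
  rn <- trimws(rownames(tab))
  ss <- stats::setNames(tab[["Sum Sq"]], rn)
  df <- stats::setNames(tab[["Df"]], rn)
  pick <- function(nm) {
    i <- match(nm, names(ss))
    if (is.na(i)) stop("contract error: missing ANOVA term ", nm, call. = FALSE)
    i
  }
  src <- c("ENV", "REP(ENV)", "GEN", "ENV:GEN", "Residuals")
  idx <- vapply(c("envf", "envf:repf", "gen", "envf:gen", "Residuals"),
                pick, integer(1L))
  out <- data.frame(source = src, df = df[idx], SS = ss[idx],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$MS <- out$SS / out$df
  ms <- stats::setNames(out$MS, out$source)
  fval <- c(ms[["ENV"]] / ms[["REP(ENV)"]],
            ms[["REP(ENV)"]] / ms[["Residuals"]],
            ms[["GEN"]] / ms[["Residuals"]],
            ms[["ENV:GEN"]] / ms[["Residuals"]],
            NA_real_)
  dfe <- stats::setNames(out$df, out$source)
  fden <- c(dfe[["REP(ENV)"]], dfe[["Residuals"]], dfe[["Residuals"]],
            dfe[["Residuals"]], NA_real_)
  out$F <- fval
  out$p <- stats::pf(fval, out$df, fden, lower.tail = FALSE)
  out$pctSS <- 100 * out$SS / sum(out$SS)
  structure(out,
            design = d,
            grand_mean = mean(sub$value),
            trait = trait,
            class = c("met_anova", "data.frame"))
}

.anova_row <- function(anova, source, col) {
  i <- match(source, anova$source)
  if (is.na(i)) stop("contract error: ANOVA table lacks source '", source, "'",
                     call. = FALSE)
  anova[[col]][i]
}

#' Assemble a `met_anova` from published degrees of freedom and mean squares
#'
#' Builds the ANOVA object consumed by [partition_signal_noise()] and
#' [variance_components()] directly from a printed ANOVA layout (source, df,
#' MS), for re-deriving inter-table arithmetic when raw plot data are not
#' available.
#'
#' @param df_ms data.frame with columns `source`, `df`, `MS` (sources as in
#'   [pooled_anova()]).
#' @param design Named list or vector with `G`, `E`, `R`.
#' @param grand_mean Optional grand mean (needed only by BLUP-side consumers).
#' @return A `met_anova` data.frame.
#' @export
as_met_anova <- function(df_ms, design, grand_mean = NA_real_) {
  stopifnot(all(c("source", "df", "MS") %in% names(df_ms)))
  out <- data.frame(source = as.character(df_ms$source),
                    df = as.numeric(df_ms$df),
                    SS = as.numeric(df_ms$df) * as.numeric(df_ms$MS),
                    MS = as.numeric(df_ms$MS),
                    F = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  out$pctSS <- 100 * out$SS / sum(out$SS)
  structure(out,
            design = list(G = as.integer(design[["G"]]),
                          E = as.integer(design[["E"]]),
                          R = as.integer(design[["R"]]),
                          balanced = TRUE),
            grand_mean = grand_mean,
            trait = attr(df_ms, "trait", exact = TRUE),
            class = c("met_anova", "data.frame"))
}

#' AMMI decomposition of the genotype-by-environment interaction
#'
#' Double-centers the cell-means matrix (subtract genotype means and
#' environment means, add back the grand mean) and takes its SVD. Each
#' interaction principal component axis (IPCA) k contributes the
#' multiplicative term sqrt(lambda_k) * alpha_ik * gamma_jk to cell (i, j),
#' with orthonormal genotype scores alpha and environment scores gamma.
#' On the replicate scale the interaction SS equals R times the sum of the
#' eigenvalues. Per-axis significance uses an F test on Gollob degrees of
#' freedom (G + E - 1 - 2k) against the pooled residual mean square;
#' the more conservative sequential F_R test is available as an alternative.
#'
#' @param means A [cell_means()] matrix.
#' @param anova The matching [pooled_anova()] table (supplies the residual MS
#'   and the design).
#' @param alpha Significance level for counting significant axes.
#' @param max_significant Upper cap on the number of axes counted significant
#'   (stability indices conventionally use the first two).
#' @param test `"gollob"` (per-axis F with Gollob df) or `"fr"` (sequential
#'   F_R test of the axes beyond k - 1).
#' @return List of class `ammi_fit`: `eigenvalues` (descending), `scores_g`
#'   (G x K orthonormal), `scores_e` (E x K orthonormal), `theta_pct`
#'   (percent of interaction SS per axis), `pc_tests` (df/SS/F/p per axis),
#'   `n_significant`, `R`, `centered` (the double-centered matrix).
#' @export
ammi_decompose <- function(means, anova, alpha = 0.05, max_significant = 2L,
                           test = c("gollob", "fr")) {
  stopifnot(inherits(means, "means_matrix") || is.matrix(means))
  test <- match.arg(test)
  G <- nrow(means); E <- ncol(means)
  if (G < 2L || E < 2L) stop("design error: need G >= 2 and E >= 2", call. = FALSE)
  d <- attr(anova, "design")
  R <- if (!is.null(d)) d$R else attr(means, "R")
  K <- min(G - 1L, E - 1L)

  cen <- sweep(means, 1L, rowMeans(means))
  cen <- sweep(cen, 2L, colMeans(means))
  cen <- cen + mean(means)
  cen <- unclass(cen)

  sv <- svd(cen, nu = K, nv = K)
  dvals <- sv$d[seq_len(K)]
  u <- sv$u; v <- sv$v
  # deterministic sign: largest-|loading| environment positive on each axis
  for (k in seq_len(K)) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) {
      v[, k] <- -v[, k]
      u[, k] <- -u[, k]
    }
  }
  rownames(u) <- rownames(means); rownames(v) <- colnames(means)
  lambda <- dvals^2
  total <- sum(lambda)
  theta <- if (total > 0) 100 * lambda / total else rep(0, K)

  ms_res <- .anova_row(anova, "Residuals", "MS")
  df_res <- .anova_row(anova, "Residuals", "df")
  pc_ss <- R * lambda
  df_gollob <- G + E - 1 - 2 * seq_len(K)
  if (test == "gollob") {
    Fv <- (pc_ss / df_gollob) / ms_res
    pv <- stats::pf(Fv, df_gollob, df_res, lower.tail = FALSE)
    df_used <- df_gollob
  } else {
    # F_R: SS remaining after the first k-1 axes, on the remaining Gollob df
    gsi_df <- (G - 1) * (E - 1)
    rem_ss <- R * (total - cumsum(c(0, lambda))[seq_len(K)])
    rem_df <- gsi_df - cumsum(c(0, df_gollob))[seq_len(K)]
    Fv <- (rem_ss / rem_df) / ms_res
    pv <- stats::pf(Fv, rem_df, df_res, lower.tail = FALSE)
    df_used <- rem_df
  }
  if (ms_res == 0) { Fv[] <- NA_real_; pv[] <- NA_real_ }
  n_sig <- sum(pv < alpha, na.rm = TRUE)
  n_sig <- max(1L, min(n_sig, max_significant, K))

  structure(list(eigenvalues = lambda,
                 scores_g = u,
                 scores_e = v,
                 theta_pct = theta,
                 pc_tests = data.frame(pc = seq_len(K), df = df_used,
                                       SS = pc_ss, F = Fv, p = pv),
                 n_significant = n_sig,
                 R = R,
                 centered = cen,
                 trait = attr(means, "trait", exact = TRUE)),
            class = "ammi_fit")
}

#' @export
print.ammi_fit <- function(x, ...) {
  cat("AMMI decomposition", if (!is.null(x$trait)) paste0(" (", x$trait, ")"),
      ": ", length(x$eigenvalues), " interaction axes\n", sep = "")
  cat("  % of interaction SS: ",
      paste(sprintf("PC%d %.2f", seq_along(x$theta_pct), x$theta_pct),
            collapse = ", "), "\n", sep = "")
  cat("  significant axes (counted): ", x$n_significant, "\n", sep = "")
  invisible(x)
}

#' IPCA scores on the conventional biplot scaling
#'
#' Returns genotype or environment axis scores scaled by the square root of
#' the singular value (symmetric scaling), the convention used for AMMI1
#' biplot coordinates.
#'
#' @param fit An [ammi_decompose()] result.
#' @param entity `"genotype"` or `"environment"`.
#' @return Matrix of scaled scores (entities x axes).
#' @export
ipca_scores <- function(fit, entity = c("genotype", "environment")) {
  entity <- match.arg(entity)
  s <- if (entity == "genotype") fit$scores_g else fit$scores_e
  sweep(s, 2L, sqrt(sqrt(fit$eigenvalues)), "*")
}

#' Partition the interaction sum of squares into signal and noise
#'
#' The noise share of the genotype-by-season interaction SS is estimated as
#' its degrees of freedom times the residual (error) mean square; the signal
#' share is the remainder, clamped at zero.
#'
#' @param anova A [pooled_anova()] or [as_met_anova()] table containing
#'   `ENV:GEN` and `Residuals` rows.
#' @return List of class `signal_noise`: `GSI_SS`, `GSI_noise_SS`,
#'   `GSI_signal_SS`, `pct_signal`, `pct_noise`, `clamped`.
#' @export
partition_signal_noise <- function(anova) {
  gsi_ss <- .anova_row(anova, "ENV:GEN", "SS")
  gsi_df <- .anova_row(anova, "ENV:GEN", "df")
  ms_res <- .anova_row(anova, "Residuals", "MS")
  noise <- gsi_df * ms_res
  signal <- gsi_ss - noise
  clamped <- signal < 0
  if (clamped) {
    warning("estimated interaction noise exceeds the interaction SS; ",
            "signal clamped to 0", call. = FALSE)
    signal <- 0
  }
  structure(list(GSI_SS = gsi_ss,
                 GSI_noise_SS = noise,
                 GSI_signal_SS = signal,
                 pct_signal = 100 * signal / gsi_ss,
                 pct_noise = 100 * noise / gsi_ss,
                 clamped = clamped),
            class = "signal_noise")
}

#' @export
print.signal_noise <- function(x, ...) {
  cat(sprintf("Interaction SS %.2f = signal %.2f (%.2f%%) + noise %.2f (%.2f%%)%s\n",
              x$GSI_SS, x$GSI_signal_SS, x$pct_signal,
              x$GSI_noise_SS, x$pct_noise,
              if (x$clamped) " [signal clamped at 0]" else ""))
  invisible(x)
}

#' AMMI1 biplot coordinates
#'
#' One point per genotype and per environment: the marginal mean on the
#' abscissa and the first IPCA score (symmetric sqrt-singular-value scaling)
#' on the ordinate. Entities whose |IPCA1| falls below `stability_band` are
#' flagged as lying on the zero-PC1 line, i.e. broadly adapted.
#'
#' @param fit An [ammi_decompose()] result.
#' @param means The [cell_means()] matrix the fit was computed from.
#' @param stability_band Half-width of the near-zero PC1 band used for the
#'   `stable` flag.
#' @return data.frame with columns `entity`, `type`, `mean`, `IPCA1`,
#'   `stable`; attribute `farthest_environment` names the environment with
#'   the largest |IPCA1| (the strongest interaction forces).
#' @export
ammi1_coordinates <- function(fit, means, stability_band = 0.5) {
  if (length(fit$eigenvalues) < 1L) stop("design error: no interaction axes",
                                         call. = FALSE)
  s1 <- sqrt(sqrt(fit$eigenvalues[1L]))
  gsc <- fit$scores_g[, 1L] * s1
  esc <- fit$scores_e[, 1L] * s1
  out <- data.frame(
    entity = c(rownames(means), colnames(means)),
    type = rep(c("genotype", "environment"), c(nrow(means), ncol(means))),
    mean = c(rowMeans(means), colMeans(means)),
    IPCA1 = c(gsc, esc),
    stringsAsFactors = FALSE)
  out$stable <- abs(out$IPCA1) < stability_band
  attr(out, "farthest_environment") <- colnames(means)[which.max(abs(esc))]
  out
}
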