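#' Variance components for the balanced two-way replicated design
#'
#' Method-of-moments (expected mean squares) estimates for the entry-mean
#' mixed model with random genotype and random genotype-by-environment
#' effects:
#' sigma2_e = MS(Residuals); sigma2_ge = (MS(ENV:GEN) - sigma2_e) / R;
#' sigma2_g = (MS(GEN) - MS(ENV:GEN)) / (R * E). On balanced data these
#' coincide with REML. Negative estimates are clamped to zero and flagged.
#'
#' @param anova A [pooled_anova()] table (carries the design and grand mean).
#' @param design Optional override: named list/vector with `G`, `E`, `R`.
#' @return List of class `variance_components`: `sigma2_g`, `sigma2_ge`,
#'   `sigma2_e`, `grand_mean`, `design`, `clamped` (character vector of
#'   clamped components).
#' @export
variance_components <- function(anova, design = NULL) {
  if (is.null(design)) design <- attr(anova, "design")
  if (is.null(design)) stop("contract error: no design available", call. = FALSE)
  R <- as.numeric(design[["R"]]); E <- as.numeric(design[["E"]])
  ms_e <- .anova_row(anova, "Residuals", "MS")
  ms_ge <- .anova_row(anova, "ENV:GEN", "MS")
  ms_g <- .anova_row(anova, "GEN", "MS")
  clamped <- character(0)
  s2_ge <- (ms_ge - ms_e) / R
  if (s2_ge < 0) { s2_ge <- 0; clamped <- c(clamped, "sigma2_ge") }
  s2_g <- (ms_g - ms_ge) / (R * E)
  if (s2_g < 0) { s2_g <- 0; clamped <- c(clamped, "sigma2_g") }
  structure(list(sigma2_g = s2_g, sigma2_ge = s2_ge, sigma2_e = ms_e,
                 grand_mean = attr(anova, "grand_mean", exact = TRUE),
                 design = list(G = as.integer(design[["G"]]),
                               E = as.integer(design[["E"]]),
                               R = as.integer(design[["R"]])),
                 clamped = clamped),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components: sigma2_g = %.4g, sigma2_ge = %.4g, sigma2_e = %.4g\n",
              x$sigma2_g, x$sigma2_ge, x$sigma2_e))
  if (length(x$clamped)) cat("  clamped at 0:", paste(x$clamped, collapse = ", "), "\n")
  invisible(x)
}

.blup_shrink <- function(vc) {
  E <- vc$design$E; R <- vc$design$R
  denom <- vc$sigma2_g + vc$sigma2_ge / E + vc$sigma2_e / (E * R)
  if (denom == 0) 0 else vc$sigma2_g / denom
}

#' BLUP predicted genotype means
#'
#' Shrinks each observed across-environment genotype mean toward the grand
#' mean by the entry-mean reliability
#' shrink = sigma2_g / (sigma2_g + sigma2_ge/E + sigma2_e/(E*R)).
#' On balanced data this is the BLUP of the genotype effect plus the grand
#' mean, and preserves the ranking of the observed means.
#'
#' @param vc A [variance_components()] result.
#' @param means The [cell_means()] matrix.
#' @return data.frame of class `blup_means`: `genotype`, `observed_mean`,
#'   `blup_effect`, `predicted_mean`; attribute `shrink`. When all variance
#'   components are zero the predictions equal the grand mean and the result
#'   carries attribute `degenerate = TRUE`.
#' @export
blup_predicted_means <- function(vc, means) {
  mu <- vc$grand_mean
  if (is.null(mu) || is.na(mu)) mu <- mean(means)
  obs <- rowMeans(means)
  shrink <- .blup_shrink(vc)
  eff <- shrink * (obs - mu)
  out <- data.frame(genotype = rownames(means), observed_mean = obs,
                    blup_effect = eff, predicted_mean = mu + eff,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "shrink") <- shrink
  if (vc$sigma2_g == 0 && vc$sigma2_ge == 0 && vc$sigma2_e == 0) {
    attr(out, "degenerate") <- TRUE
  }
  class(out) <- c("blup_means", "data.frame")
  out
}

#' Heritability, selection accuracy and coefficient of variation
#'
#' Broad-sense heritability on the entry-mean basis,
#' H2 = sigma2_g / (sigma2_g + sigma2_ge/E + sigma2_e/(E*R)); selection
#' accuracy As = sqrt(H2) (correlation between predicted and true genotypic
#' values under the model); residual coefficient of variation
#' CV = 100 * sqrt(sigma2_e) / grand mean.
#'
#' @param vc A [variance_components()] result.
#' @return List with `H2`, `As`, `CV`.
#' @export
genetic_stats <- function(vc) {
  H2 <- .blup_shrink(vc)
  mu <- vc$grand_mean
  if (is.null(mu) || is.na(mu) || mu == 0) {
    stop("domain error: CV undefined for grand mean 0 (or unknown)", call. = FALSE)
  }
  list(H2 = H2, As = sqrt(H2), CV = 100 * sqrt(vc$sigma2_e) / mu)
}

#' Weighted average of absolute scores from the BLUP-scale interaction (WAASB)
#'
#' Forms the matrix of predicted genotype-by-environment interaction effects
#' (the double-centered cell means shrunk by
#' sigma2_ge / (sigma2_ge + sigma2_e/R), their BLUP on balanced data), takes
#' its SVD, and averages each genotype's absolute axis scores weighted by the
#' percentage of interaction variance each axis explains:
#' WAASB_i = sum_k |s_ik| w_k / sum_k w_k over all axes. Lower WAASB means
#' more stable. Scores use the symmetric sqrt-singular-value scaling.
#'
#' @param x A balanced [met_table()].
#' @param vc A [variance_components()] result for the same trait.
#' @param trait Trait to analyse.
#' @return Named numeric vector of WAASB values with attribute `weights`.
#' @export
waasb <- function(x, vc, trait) {
  means <- cell_means(x, trait)
  G <- nrow(means); E <- ncol(means)
  if (G < 2L || E < 2L) stop("design error: need G >= 2 and E >= 2", call. = FALSE)
  R <- vc$design$R
  cen <- sweep(unclass(means), 1L, rowMeans(means))
  cen <- sweep(cen, 2L, colMeans(means))
  cen <- cen + mean(means)
  denom <- vc$sigma2_ge + vc$sigma2_e / R
  shrink_ge <- if (denom == 0) 0 else vc$sigma2_ge / denom
  B <- shrink_ge * cen
  K <- min(G - 1L, E - 1L)
  sv <- svd(B, nu = K, nv = K)
  dvals <- sv$d[seq_len(K)]
  keep <- dvals > max(dvals[1L], 1) * 1e-12
  if (!any(keep)) {
    w <- rep(0, K)
    out <- stats::setNames(rep(0, G), rownames(means))
    attr(out, "weights") <- w
    return(out)
  }
  lambda <- dvals[keep]^2
  w <- 100 * lambda / sum(lambda)
  sc <- sweep(sv$u[, keep, drop = FALSE], 2L, sqrt(dvals[keep]), "*")
  out <- drop(abs(sc) %*% w) / sum(w)
  names(out) <- rownames(means)
  attr(out, "weights") <- w
  out
}

#' Classify genotypes into the four quadrants of the Y x WAASB plane
#'
#' Quadrants relative to the trait grand mean (vertical threshold) and the
#' mean WAASB (horizontal threshold): I = below-mean trait, above-mean WAASB
#' (unstable, low performance); II = above-mean trait, above-mean WAASB
#' (productive but unstable); III = below-mean trait, below-mean WAASB
#' (stable but low performance); IV = above-mean trait, below-mean WAASB
#' (productive and broadly adapted). Boundary ties resolve toward the
#' favorable side (IV).
#'
#' @param mean Per-genotype trait means.
#' @param waasb Per-genotype WAASB values.
#' @param grand_mean Vertical threshold (defaults to `mean(mean)`).
#' @param mean_waasb Horizontal threshold (defaults to `mean(waasb)`).
#' @return Character vector of quadrant labels `"I"`/`"II"`/`"III"`/`"IV"`.
#' @export
quadrant_classify <- function(mean, waasb, grand_mean = base::mean(mean),
                              mean_waasb = base::mean(waasb)) {
  stopifnot(length(mean) == length(waasb),
            is.finite(grand_mean), is.finite(mean_waasb))
  high <- mean >= grand_mean     # ties favour the productive side
  stable <- waasb <= mean_waasb  # ties favour the stable side
  out <- ifelse(high & stable, "IV",
                ifelse(high & !stable, "II",
                       ifelse(!high & stable, "III", "I")))
  stats::setNames(out, names(mean))
}

#' Full BLUP/WAASB summary for one trait
#'
#' Convenience wrapper running [pooled_anova()], [variance_components()],
#' [blup_predicted_means()], [genetic_stats()], [waasb()] and
#' [quadrant_classify()] in sequence.
#'
#' @param x A balanced [met_table()].
#' @param trait Trait to analyse.
#' @return List of class `blup_fit` with elements `anova`, `vc`, `blup`,
#'   `stats`, `waasb`, `quadrant`.
#' @export
blup_waasb <- function(x, trait) {
  anova <- pooled_anova(x, trait)
  vc <- variance_components(anova)
  means <- cell_means(x, trait)
  bl <- blup_predicted_means(vc, means)
  w <- waasb(x, vc, trait)
  structure(list(anova = anova, vc = vc, blup = bl,
                 stats = genetic_stats(vc), waasb = w,
                 quadrant = quadrant_classify(bl$observed_mean, w)),
            class = "blup_fit")
}
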