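#' AMMI stability index (ASI)
#'
#' Per-genotype distance combining the squared IPCA scores of the significant
#' interaction axes, each weighted by the squared share of interaction SS the
#' axis explains:
#' \deqn{ASI_i = \sqrt{\sum_{k=1}^{K} \alpha_{ik}^2\, \theta_k^2}}
#' with theta as fraction-of-interaction (0-1) weights. Lower ASI means a
#' genotype contributes less to the interaction, i.e. is more stable.
#'
#' @param fit An [ammi_decompose()] result.
#' @param n_pcs Number of axes to use; defaults to the number of significant
#'   axes counted by the fit.
#' @return Named numeric vector of ASI values (one per genotype).
#' @export
asi <- function(fit, n_pcs = NULL) {
  if (is.null(n_pcs)) n_pcs <- fit$n_significant
  if (n_pcs < 1L) stop("parameter error: n_pcs must be >= 1", call. = FALSE)
  if (n_pcs > length(fit$eigenvalues)) {
    stop("parameter error: n_pcs exceeds available axes", call. = FALSE)
  }
  theta <- fit$theta_pct[seq_len(n_pcs)] / 100
  sc <- fit$scores_g[, seq_len(n_pcs), drop = FALSE]
  sqrt(drop(sc^2 %*% theta^2))
}

#' Rank genotypes with average-rank tie handling
#'
#' @param values Named numeric vector (one value per genotype).
#' @param direction `"asc"`: rank 1 for the smallest value (used for
#'   stability indices); `"desc"`: rank 1 for the largest (used for trait
#'   means when larger is better).
#' @return Named vector of fractional ranks; ties receive the average of the
#'   ranks they span, so each rank column sums to G(G+1)/2.
#' @export
rank_genotypes <- function(values, direction = c("asc", "desc")) {
  if (length(values) == 0L) stop("contract error: empty input", call. = FALSE)
  if (any(!is.finite(values))) stop("contract error: non-finite values",
                                    call. = FALSE)
  direction <- match.arg(direction)
  v <- if (direction == "asc") values else -values
  rank(v, ties.method = "average")
}

#' Simultaneous selection index
#'
#' SSI = rASI + rY: the sum of a genotype's stability rank and its
#' mean-performance rank. The smallest SSI marks the genotype that is both
#' stable and high performing.
#'
#' @param rASI Stability ranks (1 = most stable).
#' @param rY Mean-performance ranks (1 = best mean).
#' @return Numeric vector of SSI values.
#' @export
ssi <- function(rASI, rY) {
  stopifnot(length(rASI) == length(rY))
  if (any(rASI <= 0) || any(rY <= 0)) {
    stop("contract error: ranks must be positive", call. = FALSE)
  }
  rASI + rY
}

#' Per-genotype stability and superiority table
#'
#' Combines ASI, its rank, the across-environment mean, the mean rank, and
#' the simultaneous selection index into the selection table used to shortlist
#' genotypes.
#'
#' @param fit An [ammi_decompose()] result.
#' @param means The matching [cell_means()] matrix.
#' @param direction Ranking direction for the trait mean (`"desc"` when a
#'   larger value is better, the case for dormancy intensity and all yield
#'   traits here).
#' @param n_pcs Passed to [asi()].
#' @return data.frame of class `stability_table`: `genotype`, `ASI`, `rASI`,
#'   `mean`, `rY`, `SSI`.
#' @export
stability_table <- function(fit, means, direction = c("desc", "asc"),
                            n_pcs = NULL) {
  direction <- match.arg(direction)
  a <- asi(fit, n_pcs)
  m <- rowMeans(means)
  stopifnot(identical(names(a), rownames(means)))
  rA <- rank_genotypes(a, "asc")
  rY <- rank_genotypes(m, direction)
  structure(data.frame(genotype = rownames(means), ASI = a, rASI = rA,
                       mean = m, rY = rY, SSI = ssi(rA, rY),
                       row.names = NULL, stringsAsFactors = FALSE),
            trait = attr(means, "trait", exact = TRUE),
            class = c("stability_table", "data.frame"))
}

#' Value relative to the environment maximum (YREM)
#'
#' Y_ij = X_ij / MAX_j: each genotype's cell mean divided by the best cell
#' mean in that environment. In the absence of crossover interaction a
#' genotype's across-environment average is 1.0; the shortfall
#' (crossover loss = 1 - average) is the fraction of attainable performance
#' lost to rank-changing interaction.
#'
#' @param means A [cell_means()] matrix with non-negative entries and a
#'   strictly positive maximum in every environment (a zero numerator is a
#'   legitimate trait value — fully non-dormant lines score 0 — but a
#'   non-positive column maximum leaves the ratio undefined).
#' @return data.frame of class `yrem_table`: `genotype`, one column per
#'   environment, `avg`, `crossover_loss`.
#' @export
yrem <- function(means) {
  if (any(means < 0) || any(apply(means, 2L, max) <= 0)) {
    stop("domain error: YREM undefined for negative cell means or a ",
         "non-positive environment maximum", call. = FALSE)
  }
  y <- sweep(unclass(means), 2L, apply(means, 2L, max), "/")
  avg <- rowMeans(y)
  out <- data.frame(genotype = rownames(means), y, avg = avg,
                    crossover_loss = 1 - avg,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  structure(out, trait = attr(means, "trait", exact = TRUE),
            class = c("yrem_table", "data.frame"))
}
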