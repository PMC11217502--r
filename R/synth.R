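#' Configuration for the synthetic trial generator
#'
#' Defines a balanced multi-season trial with additive genotype and season
#' effects, a structured low-rank multiplicative interaction (the repeatable
#' "signal"), unstructured interaction noise, and replicate error:
#' y_ijr = mu + g_i + e_j + sum_k sqrt(lambda_k) alpha_ik gamma_jk
#'         + eta_ij + eps_ijr.
#' Defaults mirror the groundnut dormancy-trial regime: 32 genotypes over 3
#' seasons with 3 replicate blocks, a dominant rank-1 interaction carrying
#' about 90 percent of the interaction SS, large genotypic variance (entry-
#' mean heritability about 0.96), and a small set of planted donor genotypes
#' with high trait values and no structured interaction.
#'
#' @param G,E,R Design sizes (genotypes, environments/seasons, replicates).
#' @param mu Grand mean (trait units).
#' @param sigma_g Genotype-effect SD.
#' @param sigma_ge_noise SD of the unstructured interaction noise eta.
#' @param sigma_e Replicate-error SD.
#' @param interaction_rank Rank of the structured interaction.
#' @param lambda Singular values (length `interaction_rank`) of the
#'   structured interaction on the cell-mean SS scale; if NULL, scaled so the
#'   expected signal share of the interaction SS is `target_pct_signal`.
#' @param target_pct_signal Planted signal percentage used when `lambda` is
#'   NULL.
#' @param env_effects Season main effects (length E, centered); default an
#'   evenly spaced spread of +/- 4 trait units.
#' @param n_donors Number of planted donor genotypes (high additive effect
#'   `donor_effect`, zero structured interaction).
#' @param donor_effect Additive effect of each donor; default 2.5 * sigma_g,
#'   emulating the wide dormant/non-dormant separation seen in fresh-seed
#'   dormancy panels.
#' @param percent If TRUE, clip generated values to [0, 100] (with a warning
#'   reporting the clipping rate); default FALSE (unbounded trait scale).
#' @param trait Trait label written into the table.
#' @param germination List: `days` (assay days), `p_dormant`, `p_non_dormant`,
#'   `p_intermediate` (dormancy probability schedules over `days`),
#'   `n_seeds` per replicate, `n_non_dormant` and `n_intermediate` genotype
#'   counts among the non-donors.
#' @param marker_error Probability that a marker call contradicts the true
#'   dormancy status (assay failures / recombinants).
#' @param seed Integer seed governing every draw.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(G = 32L, E = 3L, R = 3L,
                         mu = 70, sigma_g = 25, sigma_ge_noise = 1,
                         sigma_e = 5,
                         interaction_rank = 1L, lambda = NULL,
                         target_pct_signal = 90,
                         env_effects = NULL,
                         n_donors = 5L, donor_effect = 2.5 * sigma_g,
                         percent = FALSE, trait = "Y",
                         germination = list(),
                         marker_error = 0.1,
                         seed = 1L) {
  stopifnot(G >= 2L, E >= 2L, R >= 1L,
            sigma_g >= 0, sigma_ge_noise >= 0, sigma_e >= 0,
            interaction_rank <= min(G - 1L, E - 1L),
            n_donors >= 0L, n_donors < G)
  if (G - n_donors <= interaction_rank) {
    stop("parameter error: need G - n_donors > interaction_rank so the ",
         "non-donor genotypes can carry the structured interaction",
         call. = FALSE)
  }
  df_gsi <- (G - 1) * (E - 1)
  if (is.null(lambda)) {
    p <- target_pct_signal / 100
    stopifnot(p > 0, p < 1)
    # E[signal SS] = R sum(lambda) + R sigma_eta^2 df; E[noise SS] = sigma_e^2 df
    total <- df_gsi * (p / (1 - p) * sigma_e^2 - R * sigma_ge_noise^2) / R
    if (total < 0) stop("parameter error: target_pct_signal unattainable with ",
                        "these noise SDs", call. = FALSE)
    lambda <- total * rev(seq_len(interaction_rank)) /
      sum(seq_len(interaction_rank))
  }
  stopifnot(length(lambda) == interaction_rank, all(lambda >= 0))
  if (is.null(env_effects)) {
    env_effects <- if (E == 1L) 0 else seq(-1, 1, length.out = E) * 4
  }
  stopifnot(length(env_effects) == E)
  env_effects <- env_effects - mean(env_effects)
  germ <- utils::modifyList(
    list(days = c(7L, 15L, 21L),
         p_dormant = c(0.99, 0.97, 0.95),
         p_non_dormant = c(0.60, 0.20, 0.05),
         p_intermediate = c(0.90, 0.65, 0.50),
         n_seeds = 50L, n_non_dormant = 8L, n_intermediate = 4L),
    germination)
  structure(list(G = as.integer(G), E = as.integer(E), R = as.integer(R),
                 mu = mu, sigma_g = sigma_g, sigma_ge_noise = sigma_ge_noise,
                 sigma_e = sigma_e, interaction_rank = as.integer(interaction_rank),
                 lambda = lambda, env_effects = env_effects,
                 n_donors = as.integer(n_donors), donor_effect = donor_effect,
                 percent = percent, trait = trait, germination = germ,
                 marker_error = marker_error, seed = as.integer(seed)),
            class = "synth_config")
}

# orthonormal columns, centered (orthogonal to the all-ones vector);
# rows listed in `zero_rows` are exactly zero
.random_centered_basis <- function(n, k, zero_rows = integer(0)) {
  free <- setdiff(seq_len(n), zero_rows)
  stopifnot(length(free) > k)
  X <- matrix(0, n, k)
  X[free, ] <- matrix(stats::rnorm(length(free) * k), length(free), k)
  X[free, ] <- sweep(X[free, , drop = FALSE], 2L,
                     colMeans(X[free, , drop = FALSE]))
  qr.Q(qr(X))[, seq_len(k), drop = FALSE]
}

#' Generate a synthetic MET table with known ground truth
#'
#' @param config A [synth_config()].
#' @return List with `met` (a [met_table()]) and `truth` (realised effects:
#'   `g`, `env_effects`, `alpha`, `gamma`, `lambda`, `eta`, `donors`,
#'   `pct_signal` (expected signal share of the interaction SS), `H2`
#'   (planted entry-mean heritability), `clip_rate`).
#' @export
generate_met <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  G <- config$G; E <- config$E; R <- config$R; k <- config$interaction_rank
  gts <- sprintf("G%02d", seq_len(G))
  envs <- sprintf("s%d", seq_len(E))
  donors <- seq_len(config$n_donors)

  g <- stats::rnorm(G, 0, config$sigma_g)
  g[donors] <- config$donor_effect
  alpha <- .random_centered_basis(G, k, zero_rows = donors)
  gamma <- .random_centered_basis(E, k)
  structured <- alpha %*% (sqrt(config$lambda) * t(gamma))
  eta <- matrix(stats::rnorm(G * E, 0, config$sigma_ge_noise), G, E)
  cellmu <- config$mu + outer(g, config$env_effects, "+") + structured + eta

  d <- expand.grid(genotype = gts, env = envs, rep = seq_len(R),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$trait <- config$trait
  d$value <- cellmu[cbind(match(d$genotype, gts), match(d$env, envs))] +
    stats::rnorm(nrow(d), 0, config$sigma_e)

  clip_rate <- 0
  if (config$percent) {
    clipped <- d$value < 0 | d$value > 100
    clip_rate <- mean(clipped)
    if (clip_rate > 0) {
      warning(sprintf("clipped %.1f%% of values to [0, 100]", 100 * clip_rate),
              call. = FALSE)
    }
    d$value <- pmin(pmax(d$value, 0), 100)
  }

  df_gsi <- (G - 1) * (E - 1)
  sig_ss <- R * sum(config$lambda) + R * config$sigma_ge_noise^2 * df_gsi
  noise_ss <- config$sigma_e^2 * df_gsi
  s2_ge_eff <- sum(config$lambda) / df_gsi + config$sigma_ge_noise^2
  h2 <- config$sigma_g^2 /
    (config$sigma_g^2 + s2_ge_eff / E + config$sigma_e^2 / (E * R))

  met <- met_table(d, percent_traits = if (config$percent) config$trait
                                       else character(0))
  list(met = met,
       truth = list(g = stats::setNames(g, gts),
                    env_effects = stats::setNames(config$env_effects, envs),
                    alpha = alpha, gamma = gamma, lambda = config$lambda,
                    eta = eta, donors = gts[donors],
                    pct_signal = 100 * sig_ss / (sig_ss + noise_ss),
                    H2 = h2, clip_rate = clip_rate))
}

#' Generate cumulative germination counts with planted dormancy classes
#'
#' Non-donor genotypes are assigned `n_non_dormant` non-dormant and
#' `n_intermediate` intermediate classes (the rest dormant, like the donors).
#' Each seed's germination day is drawn so the cumulative counts are
#' non-decreasing by construction; the expected 21-day IOD equals 100 times
#' the scheduled dormancy probability (above 90 for dormant, below 20 for
#' non-dormant classes at the defaults).
#'
#' @param config A [synth_config()].
#' @return List with `records` (data.frame: genotype, rep, assay, day,
#'   germinated, total) and `truth` (named vector of planted classes).
#' @export
generate_germination <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  gc_ <- config$germination
  probs <- list(dormant = gc_$p_dormant, non_dormant = gc_$p_non_dormant,
                intermediate = gc_$p_intermediate)
  for (nm in names(probs)) {
    if (any(probs[[nm]] < 0 | probs[[nm]] > 1) ||
        length(probs[[nm]]) != length(gc_$days)) {
      stop("parameter error: invalid dormancy probability schedule for ", nm,
           call. = FALSE)
    }
  }
  set.seed(config$seed + 1L)
  G <- config$G
  gts <- sprintf("G%02d", seq_len(G))
  cls <- rep("dormant", G)
  non_donor <- setdiff(seq_len(G), seq_len(config$n_donors))
  pool <- sample(non_donor)
  cls[pool[seq_len(min(gc_$n_non_dormant, length(pool)))]] <- "non_dormant"
  rest <- pool[-seq_len(min(gc_$n_non_dormant, length(pool)))]
  cls[rest[seq_len(min(gc_$n_intermediate, length(rest)))]] <- "intermediate"

  rows <- list()
  for (i in seq_len(G)) {
    p <- probs[[cls[i]]]
    q <- cummax(1 - p)   # cumulative germination probability, monotone
    for (as_ in c("field", "lab")) {
      for (r in seq_len(config$R)) {
        n <- gc_$n_seeds
        germ <- 0L
        prev_q <- 0
        counts <- integer(length(gc_$days))
        for (di in seq_along(gc_$days)) {
          p_inc <- if (prev_q >= 1) 0 else (q[di] - prev_q) / (1 - prev_q)
          germ <- germ + stats::rbinom(1L, n - germ, p_inc)
          counts[di] <- germ
          prev_q <- q[di]
        }
        rows[[length(rows) + 1L]] <-
          data.frame(genotype = gts[i], rep = r, assay = as_,
                     day = gc_$days, germinated = counts, total = n,
                     stringsAsFactors = FALSE)
      }
    }
  }
  list(records = do.call(rbind, rows),
       truth = stats::setNames(cls, gts))
}

#' Generate an allele-specific marker panel from planted dormancy classes
#'
#' The true allele tracks the planted class (positive for dormant and
#' intermediate, negative for non-dormant); each call is flipped with
#' probability `marker_error`, emulating assay failures and recombinants.
#'
#' @param config A [synth_config()].
#' @param classes Named vector of planted classes (from
#'   [generate_germination()]).
#' @return data.frame with `genotype`, `marker_call`, `true_allele`.
#' @export
generate_marker <- function(config, classes) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  true_pos <- classes != "non_dormant"
  flip <- stats::runif(length(classes)) < config$marker_error
  call_ <- ifelse(xor(true_pos, flip), "positive", "negative")
  data.frame(genotype = names(classes), marker_call = call_,
             true_allele = ifelse(true_pos, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic trial bundle
#'
#' @param config A [synth_config()].
#' @return List with `met`, `germination`, `marker` and `truth` (merged truth
#'   records of the three generators).
#' @export
generate_trial <- function(config) {
  m <- generate_met(config)
  ger <- generate_germination(config)
  mk <- generate_marker(config, ger$truth)
  list(met = m$met, germination = ger$records, marker = mk,
       truth = c(m$truth, list(dormancy_class = ger$truth)))
}
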