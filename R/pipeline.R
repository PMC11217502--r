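#' Run the full stability-analysis pipeline and write a report bundle
#'
#' Sequences, per trait: pooled ANOVA, AMMI decomposition, signal/noise
#' partition, AMMI1 biplot coordinates, the ASI/SSI stability table, YREM,
#' and the BLUP/WAASB/quadrant summary; then (when germination and marker
#' inputs are supplied) the dormancy screen and the combined donor report.
#' Every output is written as CSV or JSON under `outdir` together with a
#' machine-readable manifest carrying an MD5 checksum per file, so reruns
#' with identical inputs are byte-identical.
#'
#' @param met A [met_table()].
#' @param traits Traits to analyse (default: all traits in `met`).
#' @param outdir Output directory (created if absent).
#' @param germination Optional germination records (see [iod()]).
#' @param marker Optional marker panel (see [marker_concordance()]).
#' @param transform `"none"` or `"log"` (natural log with `offset`), applied
#'   at the record level before analysis.
#' @param offset Offset for the log transform.
#' @param alpha Significance level for counting interaction axes.
#' @param asi_pcs `"significant"`, `"all"`, or an integer number of axes for
#'   the ASI.
#' @param direction Ranking direction for trait means (see
#'   [stability_table()]).
#' @param donor_criteria Criteria list passed to [select_donors()].
#' @return (Invisibly) list with per-trait results, the donor report, and the
#'   manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(met, traits = unique(met$trait), outdir,
                         germination = NULL, marker = NULL,
                         transform = c("none", "log"), offset = 1,
                         alpha = 0.05, asi_pcs = "significant",
                         direction = "desc",
                         donor_criteria = list()) {
  stopifnot(inherits(met, "met_table"))
  transform <- match.arg(transform)
  missing_traits <- setdiff(traits, unique(met$trait))
  if (length(missing_traits) > 0L) {
    stop("config error: trait(s) not in input: ",
         paste(missing_traits, collapse = ", "), call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (transform == "log") met <- log_transform(met, offset)

  files <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  emit_json <- function(x, name) {
    path <- file.path(outdir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, name)
  }

  results <- list()
  stab_list <- list()
  yrem_list <- list()
  for (tr in traits) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop("stage '", what, "' failed for trait ", tr, ": ",
             conditionMessage(e), call. = FALSE)
      })
    }
    anova <- stage("anova", pooled_anova(met, tr))
    means <- stage("cell_means", cell_means(met, tr))
    fit <- stage("ammi", ammi_decompose(means, anova, alpha = alpha))
    part <- stage("signal_noise", partition_signal_noise(anova))
    coords <- stage("biplot", ammi1_coordinates(fit, means))
    n_pcs <- switch(as.character(asi_pcs),
                    significant = NULL,
                    all = length(fit$eigenvalues),
                    as.integer(asi_pcs))
    stab <- stage("stability", stability_table(fit, means, direction = direction,
                                               n_pcs = n_pcs))
    yt <- stage("yrem", yrem(means))
    vc <- stage("variance_components", variance_components(anova))
    bl <- stage("blup", blup_predicted_means(vc, means))
    gs <- stage("genetic_stats", genetic_stats(vc))
    w <- stage("waasb", waasb(met, vc, tr))
    quad <- quadrant_classify(bl$observed_mean, w)

    slug <- gsub("[^A-Za-z0-9]+", "_", tr)
    emit_csv(as.data.frame(anova), paste0(slug, "_anova.csv"))
    scores <- rbind(
      data.frame(entity = rownames(fit$scores_g), type = "genotype",
                 pc = rep(seq_along(fit$eigenvalues),
                          each = nrow(fit$scores_g)),
                 score = as.vector(fit$scores_g), stringsAsFactors = FALSE),
      data.frame(entity = rownames(fit$scores_e), type = "environment",
                 pc = rep(seq_along(fit$eigenvalues),
                          each = nrow(fit$scores_e)),
                 score = as.vector(fit$scores_e), stringsAsFactors = FALSE))
    emit_csv(scores, paste0(slug, "_ammi_scores.csv"))
    emit_csv(data.frame(GSI_SS = part$GSI_SS, signal_SS = part$GSI_signal_SS,
                        noise_SS = part$GSI_noise_SS,
                        pct_signal = part$pct_signal,
                        pct_noise = part$pct_noise),
             paste0(slug, "_signal_noise.csv"))
    emit_csv(coords, paste0(slug, "_biplot.csv"))
    emit_csv(as.data.frame(stab), paste0(slug, "_stability.csv"))
    emit_csv(as.data.frame(yt), paste0(slug, "_yrem.csv"))
    emit_json(list(variance_components = list(sigma2_g = vc$sigma2_g,
                                              sigma2_ge = vc$sigma2_ge,
                                              sigma2_e = vc$sigma2_e),
                   H2 = gs$H2, As = gs$As, CV = gs$CV),
              paste0(slug, "_genetic_stats.json"))
    emit_csv(data.frame(bl, WAASB = unname(w[bl$genotype]),
                        quadrant = unname(quad[bl$genotype])),
             paste0(slug, "_blup_waasb.csv"))

    results[[tr]] <- list(anova = anova, ammi = fit, signal_noise = part,
                          stability = stab, yrem = yt, vc = vc, blup = bl,
                          genetic_stats = gs, waasb = w, quadrant = quad)
    stab_list[[tr]] <- stab
    yrem_list[[tr]] <- yt
  }

  donor_report <- NULL
  if (!is.null(germination)) {
    phen <- dormancy_phenotypes(germination)
    emit_csv(as.data.frame(phen), "dormancy_phenotypes.csv")
    if (!is.null(marker)) {
      conc <- marker_concordance(marker, phen)
      emit_json(list(counts = conc$counts, concordance = conc$concordance,
                     discordant_marker_negative = conc$discordant_marker_negative,
                     discordant_marker_positive = conc$discordant_marker_positive),
                "marker_concordance.json")
    }
    donor_report <- select_donors(phen, stability = stab_list,
                                  yrem_tables = yrem_list,
                                  criteria = donor_criteria)
    emit_csv(as.data.frame(donor_report), "donor_report.csv")
    emit_json(list(criteria = attr(donor_report, "criteria"),
                   selected = donor_report$genotype[donor_report$selected]),
              "donor_selected.json")
  }

  manifest <- list(
    traits = as.list(traits),
    transform = transform,
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(outdir, f))))
    }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, donor_report = donor_report,
                 manifest = manifest))
}
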