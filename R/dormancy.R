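#' Intensity of dormancy from cumulative germination counts
#'
#' IOD at a day d is the percentage of freshly harvested seeds that have NOT
#' germinated by d: 100 * (1 - sum(germinated) / sum(total)), with counts
#' pooled over replicates (and environments) at the latest recorded day at or
#' before d. Pooling counts rather than averaging per-replicate percentages
#' keeps the estimate robust to unequal seed totals.
#'
#' @param records data.frame of cumulative germination counts with columns
#'   `genotype`, `rep`, `assay` (`"field"` or `"lab"`), `day`, `germinated`,
#'   `total` (an `env` column, if present, is pooled over).
#' @param day Requested day after sowing (15 or 21 in practice).
#' @param assay Which assay to summarise.
#' @return Named numeric vector: IOD percent per genotype.
#' @export
iod <- function(records, day = 21L, assay = c("field", "lab")) {
  assay <- match.arg(assay)
  req <- c("genotype", "rep", "day", "germinated", "total")
  stopifnot(all(req %in% names(records)))
  sub <- if ("assay" %in% names(records)) {
    records[records$assay == assay, , drop = FALSE]
  } else records
  sub <- sub[sub$day <= day, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("contract error: no records at or before day ", day, call. = FALSE)
  }
  if (any(sub$germinated < 0 | sub$germinated > sub$total)) {
    stop("integrity error: germinated outside [0, total]", call. = FALSE)
  }
  grp_cols <- intersect(c("env", "rep"), names(sub))
  split_key <- interaction(sub[c("genotype", grp_cols)], drop = TRUE)
  latest <- do.call(rbind, lapply(split(sub, split_key), function(s) {
    s[which.max(s$day), , drop = FALSE]
  }))
  germ <- tapply(latest$germinated, latest$genotype, sum)
  tot <- tapply(latest$total, latest$genotype, sum)
  if (any(tot == 0)) stop("domain error: total seed count 0", call. = FALSE)
  out <- stats::setNames(as.numeric(100 * (1 - germ / tot)), names(germ))
  out[order(names(out))]
}

#' Classify dormancy from IOD at 21 days after sowing
#'
#' Dormant when IOD21 exceeds the upper threshold (default 80, the level at
#' which the dormancy marker co-segregates with phenotype), non-dormant below
#' the lower threshold (default 20, the operational cut-off for non-dormant
#' lines), intermediate otherwise.
#'
#' @param iod21 IOD percent at 21 days after sowing.
#' @param lower,upper Classification thresholds (lower < upper).
#' @return Character vector: `"dormant"`, `"non_dormant"` or `"intermediate"`.
#' @export
classify_dormancy <- function(iod21, lower = 20, upper = 80) {
  stopifnot(lower < upper)
  ifelse(iod21 > upper, "dormant",
         ifelse(iod21 < lower, "non_dormant", "intermediate"))
}

#' Per-genotype dormancy phenotype summary
#'
#' Computes the four standard IOD variables (15/21 days after sowing, field
#' and laboratory assays) and a dormancy class from the mean of the two
#' 21-day assays (the cumulative field + laboratory evidence). Assays absent
#' from the records yield NA columns and the class falls back to whichever
#' 21-day assay is available.
#'
#' @param records Germination records as in [iod()].
#' @param lower,upper Thresholds passed to [classify_dormancy()].
#' @return data.frame of class `dormancy_phenotype`: `genotype`, `IOD15F`,
#'   `IOD21F`, `IOD15L`, `IOD21L`, `iod21_mean`, `dormancy_class`.
#' @export
dormancy_phenotypes <- function(records, lower = 20, upper = 80) {
  assays <- unique(records$assay)
  get <- function(day, as_) {
    if (!as_ %in% assays) return(NULL)
    iod(records, day, as_)
  }
  pieces <- list(IOD15F = get(15L, "field"), IOD21F = get(21L, "field"),
                 IOD15L = get(15L, "lab"), IOD21L = get(21L, "lab"))
  gts <- sort(unique(records$genotype))
  out <- data.frame(genotype = gts, stringsAsFactors = FALSE)
  for (nm in names(pieces)) {
    out[[nm]] <- if (is.null(pieces[[nm]])) NA_real_ else pieces[[nm]][gts]
  }
  out$iod21_mean <- rowMeans(out[c("IOD21F", "IOD21L")], na.rm = TRUE)
  out$dormancy_class <- classify_dormancy(out$iod21_mean, lower, upper)
  class(out) <- c("dormancy_phenotype", "data.frame")
  out
}

#' Marker-phenotype concordance for the dormancy marker panel
#'
#' Crosses allele-specific marker calls (band presence) with phenotypic
#' dormancy classes. A genotype is concordant when marker-positive and
#' dormant, or marker-negative and non-dormant; discordances are reported by
#' direction; intermediates are untestable.
#'
#' @param panel data.frame with columns `genotype` and `marker_call`
#'   (`"positive"`/`"negative"`, or 1/0).
#' @param phenotypes A [dormancy_phenotypes()] table (or any data.frame with
#'   `genotype` and `dormancy_class`).
#' @return List of class `marker_concordance`: per-genotype `status` table,
#'   `counts`, `concordance` (fraction over testable genotypes), and named
#'   lists of discordant genotypes.
#' @export
marker_concordance <- function(panel, phenotypes) {
  stopifnot(all(c("genotype", "marker_call") %in% names(panel)),
            all(c("genotype", "dormancy_class") %in% names(phenotypes)))
  call_ <- panel$marker_call
  if (is.numeric(call_)) call_ <- ifelse(call_ > 0, "positive", "negative")
  panel$marker_call <- call_
  m <- merge(panel[c("genotype", "marker_call")],
             phenotypes[c("genotype", "dormancy_class")], by = "genotype")
  if (nrow(m) == 0L) {
    stop("contract error: no genotype has both a marker call and a dormancy class",
         call. = FALSE)
  }
  m$status <- ifelse(m$dormancy_class == "intermediate", "untestable",
              ifelse(m$marker_call == "positive" & m$dormancy_class == "dormant",
                     "concordant",
              ifelse(m$marker_call == "negative" & m$dormancy_class == "non_dormant",
                     "concordant",
              ifelse(m$marker_call == "negative", "discordant_marker_negative",
                     "discordant_marker_positive"))))
  counts <- table(factor(m$status, c("concordant", "discordant_marker_negative",
                                     "discordant_marker_positive", "untestable")))
  testable <- sum(counts) - counts[["untestable"]]
  structure(list(status = m,
                 counts = as.list(counts),
                 concordance = if (testable > 0) counts[["concordant"]] / testable
                               else NA_real_,
                 discordant_marker_negative =
                   m$genotype[m$status == "discordant_marker_negative"],
                 discordant_marker_positive =
                   m$genotype[m$status == "discordant_marker_positive"]),
            class = "marker_concordance")
}

#' @export
print.marker_concordance <- function(x, ...) {
  cat(sprintf("Marker-phenotype concordance: %.1f%% of %d testable genotypes\n",
              100 * x$concordance,
              sum(unlist(x$counts)) - x$counts$untestable))
  cat("  concordant:", x$counts$concordant,
      "| dormant-but-marker-negative:", x$counts$discordant_marker_negative,
      "| non-dormant-but-marker-positive:", x$counts$discordant_marker_positive,
      "| untestable:", x$counts$untestable, "\n")
  invisible(x)
}

#' Select stable fresh-seed-dormancy donor lines
#'
#' Applies the donor criteria jointly: (i) dormant class with mean 21-day IOD
#' at or above `min_iod21` across the available assays; (ii) average YREM at
#' or above the per-trait thresholds in `min_yrem`; (iii) SSI rank at or
#' below `max_ssi_rank` for at least one of the supplied economic traits.
#' Criteria whose inputs are absent are skipped. Evidence for every criterion
#' is attached per genotype.
#'
#' @param phenotypes A [dormancy_phenotypes()] table, or NULL to skip the
#'   dormancy criterion.
#' @param stability Named list of [stability_table()]s (one per economic
#'   trait), or NULL.
#' @param yrem_tables Named list of [yrem()] tables keyed by trait, or NULL.
#' @param criteria List with elements `min_iod21` (default 90), `min_yrem`
#'   (named numeric vector over traits, default none), `max_ssi_rank`
#'   (default 10).
#' @return data.frame of class `donor_report`: one row per genotype in the
#'   common set with per-criterion evidence and pass flags; attribute
#'   `criteria` records the thresholds. Selected donors have `selected = TRUE`.
#' @export
select_donors <- function(phenotypes = NULL, stability = NULL,
                          yrem_tables = NULL,
                          criteria = list()) {
  crit <- utils::modifyList(list(min_iod21 = 90, min_yrem = NULL,
                                 max_ssi_rank = 10), criteria)
  sets <- list()
  if (!is.null(phenotypes)) sets <- c(sets, list(phenotypes$genotype))
  if (!is.null(stability)) {
    sets <- c(sets, lapply(stability, function(s) s$genotype))
  }
  if (!is.null(yrem_tables)) {
    sets <- c(sets, lapply(yrem_tables, function(y) y$genotype))
  }
  if (length(sets) == 0L) stop("contract error: no inputs supplied", call. = FALSE)
  common <- Reduce(intersect, sets)
  if (length(common) == 0L) {
    stop("contract error: empty common genotype set", call. = FALSE)
  }
  out <- data.frame(genotype = sort(common), stringsAsFactors = FALSE)
  pass <- rep(TRUE, nrow(out))

  if (!is.null(phenotypes)) {
    i <- match(out$genotype, phenotypes$genotype)
    out$iod21_mean <- phenotypes$iod21_mean[i]
    out$dormancy_class <- phenotypes$dormancy_class[i]
    out$pass_dormancy <- out$dormancy_class == "dormant" &
      out$iod21_mean >= crit$min_iod21
    pass <- pass & out$pass_dormancy
  }
  if (!is.null(yrem_tables) && !is.null(crit$min_yrem)) {
    ok <- rep(TRUE, nrow(out))
    for (tr in names(crit$min_yrem)) {
      yt <- yrem_tables[[tr]]
      if (is.null(yt)) stop("contract error: no YREM table for trait ", tr,
                            call. = FALSE)
      avg <- yt$avg[match(out$genotype, yt$genotype)]
      out[[paste0("yrem_", tr)]] <- avg
      ok <- ok & avg >= crit$min_yrem[[tr]]
    }
    out$pass_yrem <- ok
    pass <- pass & ok
  }
  if (!is.null(stability)) {
    any_ok <- rep(FALSE, nrow(out))
    for (tr in names(stability)) {
      st <- stability[[tr]]
      r <- rank_genotypes(stats::setNames(st$SSI, st$genotype), "asc")
      rk <- r[out$genotype]
      out[[paste0("ssi_rank_", tr)]] <- rk
      any_ok <- any_ok | rk <= crit$max_ssi_rank
    }
    out$pass_ssi <- any_ok
    pass <- pass & any_ok
  }
  out$selected <- pass
  structure(out, criteria = crit, class = c("donor_report", "data.frame"))
}
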