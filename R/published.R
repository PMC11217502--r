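#' Published groundnut trial summary tables
#'
#' Small bundled CSVs transcribed from the printed summary tables of the
#' groundnut fresh-seed-dormancy multi-season trial that this package's
#' methods reproduce: the AMMI ANOVA layout (degrees of freedom and mean
#' squares per trait), the signal/noise partition, the ASI/SSI rank table,
#' and the YREM tables for the dormancy and yield traits. Raw plot-level
#' data were not published, so these printed summaries are the inputs for
#' re-deriving every piece of inter-table arithmetic.
#'
#' @param name One of `"ammi_anova"`, `"signal_noise"`, `"stability_ranks"`,
#'   `"yrem_dormancy"`, `"yrem_yield"`.
#' @return A data.frame.
#' @export
published_table <- function(name = c("ammi_anova", "signal_noise",
                                     "stability_ranks", "yrem_dormancy",
                                     "yrem_yield")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("published_", name, ".csv"),
                      package = "metstab", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published ANOVA for one trait as a `met_anova`
#'
#' @param trait One of the eight trial traits (IOD15F, IOD21F, IOD15L,
#'   IOD21L, PYLP, HPW, HKW, SP).
#' @return A `met_anova` built with [as_met_anova()] from the printed df and
#'   mean squares (main-effect and residual rows; the per-axis PC rows are
#'   dropped since they are outputs, not inputs, of the decomposition).
#' @export
published_anova <- function(trait) {
  tab <- published_table("ammi_anova")
  tab <- tab[tab$trait == trait, ]
  if (nrow(tab) == 0L) stop("unknown trait: ", trait, call. = FALSE)
  tab <- tab[tab$source %in% c("ENV", "REP(ENV)", "GEN", "ENV:GEN", "Residuals"), ]
  attr(tab, "trait") <- trait
  as_met_anova(tab, design = c(G = 32, E = 3, R = 3))
}

#' Published YREM season values as a means matrix
#'
#' The printed YREM values are themselves on the relative (0, 1] scale with
#' a maximum of 1 in every season, so feeding them back through [yrem()]
#' reproduces the printed table and its averages.
#'
#' @param trait A dormancy trait (IOD15F/IOD21F/IOD15L/IOD21L) or a yield
#'   trait (PYLP/HPW/HKW/SP).
#' @return A `means_matrix` of the printed season values (columns s1..s3).
#' @export
published_yrem_means <- function(trait) {
  which_ <- if (trait %in% c("PYLP", "HPW", "HKW", "SP")) "yrem_yield"
            else "yrem_dormancy"
  tab <- published_table(which_)
  tab <- tab[tab$trait == trait, ]
  if (nrow(tab) == 0L) stop("unknown trait: ", trait, call. = FALSE)
  m <- as.matrix(tab[c("s1", "s2", "s3")])
  rownames(m) <- tab$genotype
  structure(m, trait = trait, R = 1L,
            class = c("means_matrix", "matrix", "array"))
}
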