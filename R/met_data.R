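#' Construct a validated multi-environment-trial table
#'
#' A `met_table` holds long-format replicated phenotype records from a
#' multi-season/multi-location trial laid out as a randomized complete block
#' design: one row per (genotype, environment, replicate, trait) observation.
#' It is the unit every downstream analysis (pooled ANOVA, AMMI, stability
#' indices, BLUP) consumes.
#'
#' @param data A data.frame with columns `genotype`, `env`, `rep`, `trait`,
#'   `value` (see `schema` of [read_met_table()] to remap other names first).
#' @param percent_traits Character vector of trait names measured on a 0-100
#'   percentage scale; their values are range-checked.
#' @return A data.frame of class `met_table` with attributes `design`
#'   (named list with `G`, `E`, `R`, `balanced`) and `transform`.
#' @examples
#' d <- expand.grid(genotype = c("g1", "g2"), env = c("e1", "e2"), rep = 1:3)
#' d$trait <- "Y"; d$value <- rnorm(nrow(d), 50, 5)
#' met <- met_table(d)
#' met_design(met)
#' @export
met_table <- function(data, percent_traits = c("IOD15F", "IOD21F", "IOD15L",
                                               "IOD21L", "SP")) {
  required <- c("genotype", "env", "rep", "trait", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)[required]
  data$genotype <- as.character(data$genotype)
  data$env <- as.character(data$env)
  data$trait <- as.character(data$trait)
  if (!is.numeric(data$value)) {
    stop("parse error: 'value' is not numeric", call. = FALSE)
  }
  bad <- which(!is.finite(data$value))
  if (length(bad) > 0L) {
    stop("parse error: non-finite value at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(data$rep) || any(data$rep < 1) || any(data$rep != round(data$rep))) {
    stop("parse error: 'rep' must contain integers >= 1", call. = FALSE)
  }
  data$rep <- as.integer(data$rep)

  key <- paste(data$genotype, data$env, data$rep, data$trait, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    d1 <- data[which(dup)[1L], ]
    stop("integrity error: duplicated record for (genotype=", d1$genotype,
         ", env=", d1$env, ", rep=", d1$rep, ", trait=", d1$trait, ")",
         call. = FALSE)
  }

  pct <- data$trait %in% percent_traits
  if (any(pct)) {
    out_of_range <- pct & (data$value < 0 | data$value > 100)
    if (any(out_of_range)) {
      stop("integrity error: percentage trait value outside [0, 100] at row(s) ",
           paste(utils::head(which(out_of_range), 5L), collapse = ", "),
           call. = FALSE)
    }
  }

  structure(data,
            design = .met_design(data, warn = TRUE),
            transform = list(type = "none"),
            class = c("met_table", "data.frame"))
}

.met_design <- function(data, warn = FALSE) {
  G <- length(unique(data$genotype))
  E <- length(unique(data$env))
  R <- max(data$rep)
  balanced <- TRUE
  for (tr in unique(data$trait)) {
    sub <- data[data$trait == tr, ]
    counts <- table(sub$genotype, sub$env)
    if (any(counts != R)) {
      balanced <- FALSE
      if (warn) {
        off <- which(counts != R, arr.ind = TRUE)
        cells <- apply(off, 1L, function(i) {
          paste0("(", rownames(counts)[i[1L]], ", ", colnames(counts)[i[2L]], ")")
        })
        warning("unbalanced cells for trait ", tr, ": ",
                paste(utils::head(cells, 5L), collapse = ", "),
                if (length(cells) > 5L) ", ..." else "",
                call. = FALSE)
      }
    }
  }
  list(G = G, E = E, R = R, balanced = balanced)
}

#' Design summary of a MET table
#'
#' @param x A [met_table()].
#' @param trait Optional trait; if given, the balanced flag is recomputed for
#'   that trait only.
#' @return Named list with `G`, `E`, `R` and logical `balanced`.
#' @export
met_design <- function(x, trait = NULL) {
  stopifnot(inherits(x, "met_table"))
  if (is.null(trait)) return(attr(x, "design"))
  .met_design(x[x$trait == trait, , drop = FALSE])
}

#' @export
print.met_table <- function(x, ...) {
  d <- attr(x, "design")
  cat("MET table: ", d$G, " genotypes x ", d$E, " environments x ",
      d$R, " replicates; traits: ",
      paste(unique(x$trait), collapse = ", "), "\n", sep = "")
  cat(if (isTRUE(d$balanced)) "balanced design" else "UNBALANCED design",
      "; transform: ", attr(x, "transform")$type, "\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read a MET table from CSV
#'
#' Reads a long-format, UTF-8, headered CSV and validates it into a
#' [met_table()]. Column names can be remapped through `schema`, e.g. when the
#' file calls the environment column `season`.
#'
#' @param path Path to the CSV file.
#' @param schema Named character vector mapping the canonical names
#'   (`genotype`, `env`, `rep`, `trait`, `value`) to the column names used in
#'   the file.
#' @param ... Passed to [met_table()].
#' @return A validated [met_table()].
#' @export
read_met_table <- function(path,
                           schema = c(genotype = "genotype", env = "env",
                                      rep = "rep", trait = "trait",
                                      value = "value"),
                           ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("genotype", "env", "rep", "trait", "value")
  schema <- schema[canonical]
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: column(s) not in file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw[unname(schema)]
  names(out) <- canonical
  if (!is.numeric(out$value)) {
    suppressWarnings(num <- as.numeric(out$value))
    if (anyNA(num)) {
      stop("parse error: non-numeric value at row(s) ",
           paste(utils::head(which(is.na(num)), 5L), collapse = ", "),
           call. = FALSE)
    }
    out$value <- num
  }
  met_table(out, ...)
}

#' Log-transform trait values
#'
#' Replaces each value by `log(value + offset)`, the normalising transform
#' applied to replicated trial data before pooled analysis. The transform is
#' recorded in the table's provenance metadata so downstream reports can state
#' the scale of analysis.
#'
#' @param x A [met_table()].
#' @param offset Non-negative shift added before taking logs; the default 1
#'   accommodates percentage traits with observed zeros.
#' @return The transformed `met_table`.
#' @export
log_transform <- function(x, offset = 1) {
  stopifnot(inherits(x, "met_table"), offset >= 0)
  shifted <- x$value + offset
  bad <- which(shifted <= 0)
  if (length(bad) > 0L) {
    d1 <- x[bad[1L], ]
    stop("domain error: value + offset <= 0 for (genotype=", d1$genotype,
         ", env=", d1$env, ", rep=", d1$rep, ", trait=", d1$trait, ")",
         call. = FALSE)
  }
  x$value <- log(shifted)
  attr(x, "transform") <- list(type = "log", offset = offset)
  x
}

#' Genotype-by-environment cell means
#'
#' Averages replicates to the G x E grid of cell means X_ij used by the AMMI
#' decomposition and by the relative-to-environment-maximum statistics.
#'
#' @param x A [met_table()].
#' @param trait Trait to average.
#' @return A numeric G x E matrix of class `means_matrix` (genotypes in rows,
#'   environments in columns) with attributes `trait` and `R` (replicates per
#'   cell).
#' @export
cell_means <- function(x, trait) {
  stopifnot(inherits(x, "met_table"))
  sub <- x[x$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for trait ", trait, call. = FALSE)
  g <- sort(unique(sub$genotype))
  e <- sort(unique(sub$env))
  counts <- table(factor(sub$genotype, g), factor(sub$env, e))
  if (any(counts == 0L)) {
    off <- which(counts == 0L, arr.ind = TRUE)
    cells <- apply(off, 1L, function(i) paste0("(", g[i[1L]], ", ", e[i[2L]], ")"))
    stop("completeness error: empty cell(s): ",
         paste(utils::head(cells, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(unique(as.vector(counts))) != 1L) {
    stop("design error: unequal replicate counts across cells", call. = FALSE)
  }
  m <- tapply(sub$value, list(factor(sub$genotype, g), factor(sub$env, e)), mean)
  m <- matrix(as.numeric(m), nrow = length(g), ncol = length(e),
              dimnames = list(g, e))
  structure(m, trait = trait, R = as.integer(counts[1L]),
            class = c("means_matrix", "matrix", "array"))
}

#' Levene homogeneity test on within-environment error variances
#'
#' Tests whether the RCBD error variance is homogeneous across environments,
#' the check that justifies pooling seasons into one combined analysis. The
#' test operates on within-environment residuals
#' (value - genotype mean - replicate mean + environment mean), not raw
#' values, because the hypothesis concerns error mean squares. W is the
#' one-way ANOVA F statistic on absolute deviations of those residuals from
#' their per-environment center, referred to F(E - 1, N - E).
#'
#' Because the residuals of each environment's RCBD fit span only
#' (G - 1)(R - 1) free dimensions, the default weights each environment by
#' that effective residual df in the between-group sum of squares and refers
#' W to F(E - 1, E(G - 1)(R - 1) - E); this keeps the test's size close to
#' nominal. `weights = "count"` gives the textbook one-way-ANOVA-on-absolute-
#' deviations form with raw group sizes and F(E - 1, N - E), which is
#' anti-conservative on residuals.
#'
#' @param x A [met_table()].
#' @param trait Trait to test.
#' @param center `"mean"` for the classic test, `"median"` for the
#'   Brown-Forsythe variant.
#' @param weights `"effective_df"` (default, df-corrected) or `"count"`
#'   (textbook form).
#' @return List with `W`, `p.value`, `df` (length 2), `center`, `weights`.
#' @export
levene_homogeneity <- function(x, trait, center = c("mean", "median"),
                               weights = c("effective_df", "count")) {
  stopifnot(inherits(x, "met_table"))
  center <- match.arg(center)
  weights <- match.arg(weights)
  sub <- x[x$trait == trait, , drop = FALSE]
  envs <- unique(sub$env)
  if (length(envs) < 2L) stop("insufficient-data error: need >= 2 environments",
                              call. = FALSE)
  res <- numeric(0)
  grp <- character(0)
  eff_df <- stats::setNames(numeric(length(envs)), envs)
  for (ev in envs) {
    s <- sub[sub$env == ev, ]
    nG <- length(unique(s$genotype)); nR <- length(unique(s$rep))
    if (nrow(s) < 4L || nG < 2L || nR < 2L) {
      stop("insufficient-data error: environment ", ev,
           " lacks residual degrees of freedom", call. = FALSE)
    }
    gm <- tapply(s$value, s$genotype, mean)
    rm_ <- tapply(s$value, s$rep, mean)
    r <- s$value - gm[s$genotype] - rm_[as.character(s$rep)] + mean(s$value)
    res <- c(res, r)
    grp <- c(grp, rep(ev, length(r)))
    eff_df[ev] <- (nG - 1) * (nR - 1)
  }
  grp <- factor(grp, levels = envs)
  ctr <- tapply(res, grp, if (center == "mean") mean else stats::median)
  z <- abs(res - ctr[grp])
  n <- length(z); k <- nlevels(grp)
  zbar <- mean(z)
  zg <- tapply(z, grp, mean)
  w <- if (weights == "count") tabulate(grp) else eff_df
  df2 <- if (weights == "count") n - k else sum(eff_df) - k
  ss_between <- sum(w * (zg - zbar)^2)
  ss_within <- sum((z - zg[grp])^2)
  if (ss_between == 0) {
    W <- 0
    p <- 1
  } else if (ss_within == 0) {
    W <- Inf
    p <- 0
  } else {
    W <- (ss_between / (k - 1)) / (ss_within / (n - k))
    p <- stats::pf(W, k - 1, df2, lower.tail = FALSE)
  }
  list(W = W, p.value = p, df = c(k - 1, df2), center = center,
       weights = weights)
}

#' Echo a validation report for a MET table
#'
#' @param x A [met_table()].
#' @return A list (suitable for JSON serialisation) with record counts, the
#'   design, the balanced flag and the recorded transform.
#' @export
validation_report <- function(x) {
  stopifnot(inherits(x, "met_table"))
  d <- attr(x, "design")
  list(n_records = nrow(x),
       traits = unique(x$trait),
       G = d$G, E = d$E, R = d$R,
       balanced = d$balanced,
       transform = attr(x, "transform"))
}
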