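#' Two-way sequential-SS ANOVA for one metabolite
#'
#' Fits a linear model to one metabolite's concentrations with genotype,
#' time of day (categorical, one level per sampling index) and animal as
#' covariates, plus the genotype-by-time interaction, and tests the three
#' design terms by two-way ANOVA with sequential (type-I) sums of squares
#' in the order genotype, time, animal, genotype:time. Animal is a fixed
#' factor nested in genotype, so its indicator columns are collinear with
#' the genotype contrast; entering genotype first keeps it estimable and
#' aliased animal columns are dropped. F tests use the residual mean
#' square. Rows with missing concentrations are dropped.
#'
#' @param values numeric vector of concentrations, one per study sample.
#' @param design data.frame aligned with `values`, columns `genotype`
#'   (`"control"`/`"HD"`), `sampling_index` (time-point label) and
#'   `sheep_id`.
#' @return named numeric vector `c(p_genotype, p_time, p_interaction)`.
#' @export
fit_metabolite_anova <- function(values, design) {
  keep <- !is.na(values)
  y <- values[keep]
  genotype <- factor(design$genotype[keep], levels = c("control", "HD"))
  time <- factor(design$sampling_index[keep])
  animal <- factor(design$sheep_id[keep])
  per_geno <- tapply(animal, genotype, function(a) length(unique(a)))
  if (any(is.na(per_geno)) || any(per_geno < 2)) {
    stop("need >= 2 sheep per genotype")
  }
  fit <- stats::lm(y ~ genotype + time + animal + genotype:time)
  if (stats::df.residual(fit) == 0L) {
    stop("zero residual degrees of freedom")
  }
  av <- stats::anova(fit)
  p <- av[["Pr(>F)"]]
  names(p) <- rownames(av)
  c(p_genotype = unname(p["genotype"]),
    p_time = unname(p["time"]),
    p_interaction = unname(p["genotype:time"]))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted values (q-values) in the input order; every output
#'   weakly exceeds its input and the significance ordering is preserved.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Group means and standard errors for one metabolite
#'
#' Mean and SEM over all non-missing samples of each genotype, pooling
#' sheep and time points (the 24 h mean +/- SEM convention).
#'
#' @param values numeric concentrations per study sample.
#' @param design data.frame with a `genotype` column aligned with
#'   `values`; `sheep_id` is needed when `by = "sheep"`.
#' @param by `"pooled"` (default) pools all samples; `"sheep"` first
#'   averages within sheep and computes the SEM over sheep-level 24 h
#'   means.
#' @return named numeric vector `c(control_mean, control_sem, hd_mean,
#'   hd_sem)`.
#' @export
group_means_sem <- function(values, design, by = c("pooled", "sheep")) {
  by <- match.arg(by)
  out <- c(control_mean = NA_real_, control_sem = NA_real_,
           hd_mean = NA_real_, hd_sem = NA_real_)
  for (g in c("control", "HD")) {
    sel <- design$genotype == g & !is.na(values)
    v <- values[sel]
    if (by == "sheep") {
      v <- as.numeric(tapply(v, design$sheep_id[sel], mean))
    }
    if (length(v) < 2L) stop("genotype ", g, " has < 2 non-missing values")
    key <- if (g == "control") "control" else "hd"
    out[paste0(key, "_mean")] <- mean(v)
    out[paste0(key, "_sem")] <- stats::sd(v) / sqrt(length(v))
  }
  out
}

#' Screen every metabolite with the two-way ANOVA
#'
#' Runs [fit_metabolite_anova()] for each metabolite of a concentration
#' table, adjusts each design term across metabolites with
#' Benjamini-Hochberg FDR, and appends pooled group means and SEMs.
#'
#' @param table a `conc_table` (study samples are used; QC wells are
#'   ignored).
#' @param sem `"pooled"` or `"sheep"`, see [group_means_sem()].
#' @return a data.frame of class `anova_results`, one row per metabolite:
#'   `abbreviation`, `class`, `p_*`, `fdr_*` for genotype/time/
#'   interaction, and `control_mean`, `control_sem`, `hd_mean`, `hd_sem`.
#' @export
screen_metabolites <- function(table, sem = "pooled") {
  stopifnot(inherits(table, "conc_table"))
  is_study <- table$samples$sample_type == "study"
  design <- table$samples[is_study, ]
  v <- table$values[is_study, , drop = FALSE]
  abbrs <- table$annotation$abbreviation
  pmat <- matrix(NA_real_, length(abbrs), 3,
                 dimnames = list(abbrs, c("p_genotype", "p_time",
                                          "p_interaction")))
  gm <- matrix(NA_real_, length(abbrs), 4,
               dimnames = list(abbrs, c("control_mean", "control_sem",
                                        "hd_mean", "hd_sem")))
  for (j in seq_along(abbrs)) {
    pmat[j, ] <- fit_metabolite_anova(v[, j], design)
    gm[j, ] <- group_means_sem(v[, j], design, by = sem)
  }
  res <- data.frame(abbreviation = abbrs,
                    class = table$annotation$class,
                    pmat,
                    fdr_genotype = bh_fdr(pmat[, "p_genotype"]),
                    fdr_time = bh_fdr(pmat[, "p_time"]),
                    fdr_interaction = bh_fdr(pmat[, "p_interaction"]),
                    gm, row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("anova_results", "data.frame")
  res
}

#' Tabulate significance by metabolite class and direction
#'
#' A metabolite is significant when its genotype FDR is strictly below
#' `alpha`. Direction is read off the stored group means: increased when
#' the HD mean exceeds the control mean, decreased when below, and a tie
#' when the stored values are exactly equal (ties are counted separately,
#' never silently assigned a direction).
#'
#' @param results a data.frame with columns `fdr_genotype`,
#'   `control_mean`, `hd_mean` and (unless `annotation` is given)
#'   `class` -- e.g. the output of [screen_metabolites()] or the packaged
#'   reference table from [load_reference_screen()].
#' @param annotation optional annotation table supplying `abbreviation`
#'   and `class` when `results` lacks a class column.
#' @param alpha FDR cutoff, default 0.05 (strict `<`).
#' @return a data.frame of class `significance_summary`, one row per
#'   class plus a `total` row: `n_total`, `n_significant`, `n_increased`,
#'   `n_decreased`, `n_tied_direction`.
#' @export
summarize_significance <- function(results, annotation = NULL,
                                   alpha = 0.05) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L) {
    out <- data.frame(class = "total", n_total = 0L, n_significant = 0L,
                      n_increased = 0L, n_decreased = 0L,
                      n_tied_direction = 0L, stringsAsFactors = FALSE)
    class(out) <- c("significance_summary", "data.frame")
    return(out)
  }
  if (!"class" %in% names(results)) {
    if (is.null(annotation)) {
      stop("results carry no class column and no annotation was given")
    }
    results$class <- annotation$class[match(results$abbreviation,
                                            annotation$abbreviation)]
  }
  if (anyNA(results$class)) stop("every result row needs a class")
  sig <- results$fdr_genotype < alpha
  dir <- ifelse(results$hd_mean > results$control_mean, "increased",
                ifelse(results$hd_mean < results$control_mean,
                       "decreased", "tied"))
  classes <- unique(results$class)
  rows <- lapply(c(classes, "total"), function(cl) {
    sel <- if (cl == "total") rep(TRUE, nrow(results)) else
      results$class == cl
    data.frame(class = cl, n_total = sum(sel),
               n_significant = sum(sel & sig),
               n_increased = sum(sel & sig & dir == "increased"),
               n_decreased = sum(sel & sig & dir == "decreased"),
               n_tied_direction = sum(sel & sig & dir == "tied"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("significance_summary", "data.frame")
  out
}

#' Define a metabolite concentration ratio
#'
#' @param name label for the ratio (e.g. `"Cit/Arg"`).
#' @param numerator,denominator metabolite abbreviations (distinct).
#' @param interpretation free-text note on the enzyme activity the ratio
#'   proxies.
#' @return a list with class `ratio_definition`.
#' @export
ratio_definition <- function(name, numerator, denominator,
                             interpretation = "") {
  if (numerator == denominator) {
    stop("numerator and denominator must differ")
  }
  structure(list(name = name, numerator = numerator,
                 denominator = denominator,
                 interpretation = interpretation),
            class = "ratio_definition")
}

#' The urea-/nitric-oxide-cycle ratio set
#'
#' Cit/Arg, Cit/Orn and Orn/Arg, used as proxies for nitric oxide
#' synthase, ornithine carbamoylphosphate transferase and arginase
#' activity respectively.
#'
#' @return a named list of [ratio_definition()] objects.
#' @export
urea_cycle_ratios <- function() {
  list(
    `Cit/Arg` = ratio_definition("Cit/Arg", "Cit", "Arg",
                                 "nitric oxide synthase activity"),
    `Cit/Orn` = ratio_definition("Cit/Orn", "Cit", "Orn",
                                 "ornithine carbamoylphosphate transferase activity"),
    `Orn/Arg` = ratio_definition("Orn/Arg", "Orn", "Arg",
                                 "arginase activity"))
}

#' Per-sample concentration ratio series
#'
#' The ratio is missing whenever either component is missing; a zero
#' denominator yields a missing value with a warning. The resulting
#' series can be fed to [fit_metabolite_anova()] unchanged.
#'
#' @param table a `conc_table` whose panel contains both components.
#' @param ratio a [ratio_definition()].
#' @return numeric vector, one ratio per sample (in table row order).
#' @export
compute_ratio_series <- function(table, ratio) {
  stopifnot(inherits(table, "conc_table"),
            inherits(ratio, "ratio_definition"))
  abbrs <- table$annotation$abbreviation
  for (part in c("numerator", "denominator")) {
    if (!ratio[[part]] %in% abbrs) {
      stop(part, " '", ratio[[part]], "' not in panel")
    }
  }
  num <- table$values[, ratio$numerator]
  den <- table$values[, ratio$denominator]
  zero <- !is.na(den) & den == 0
  if (any(zero)) {
    warning("zero denominator in ", sum(zero), " sample(s) for ",
            ratio$name, "; reported as missing")
    den[zero] <- NA_real_
  }
  num / den
}
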