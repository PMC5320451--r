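#' QC thresholds for metabolite exclusion
#'
#' @param max_out_of_range_fraction maximum tolerated fraction of study
#'   samples flagged below LOD, below LLOQ or above ULOQ (pooled); a
#'   metabolite with a strictly larger fraction is excluded. Default 0.25.
#' @param max_qc2_cv maximum tolerated coefficient of variation of the QC2
#'   repeats; strictly larger CVs exclude the metabolite. Default 0.30.
#' @return a list with class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_out_of_range_fraction = 0.25,
                          max_qc2_cv = 0.30) {
  if (max_out_of_range_fraction < 0 || max_out_of_range_fraction > 1 ||
      max_qc2_cv < 0 || max_qc2_cv > 1) {
    stop("thresholds must lie in [0, 1]")
  }
  structure(list(max_out_of_range_fraction = max_out_of_range_fraction,
                 max_qc2_cv = max_qc2_cv),
            class = "qc_thresholds")
}

#' Flag concentrations against assay quantification limits
#'
#' Classifies each value relative to its metabolite's LOD / LLOQ / ULOQ.
#' Boundary convention mirrors the assay's strict inequalities: a value
#' strictly below LOD is `below_lod`; a value at or above LOD but strictly
#' below LLOQ is `below_lloq` (quantifiable-but-below-LLOQ, so a value
#' exactly at LOD lands here); a value strictly above ULOQ is
#' `above_uloq`; missing values are flagged `missing`.
#'
#' @param values numeric vector of concentrations in uM (`NA` = missing).
#' @param annotation a single-row slice of a [metabolite_annotation()]
#'   table (or any list with `lod`, `lloq`, `uloq`).
#' @return character vector of flags, one per value: `"below_lod"`,
#'   `"below_lloq"`, `"above_uloq"`, `"in_range"` or `"missing"`.
#' @export
flag_out_of_range <- function(values, annotation) {
  lod <- annotation$lod[1]; lloq <- annotation$lloq[1]
  uloq <- annotation$uloq[1]
  if (is.na(lod) || is.na(lloq) || is.na(uloq) ||
      lod > lloq || lloq >= uloq) {
    stop("invalid quantification limits (need lod <= lloq < uloq)")
  }
  flags <- rep("in_range", length(values))
  flags[values < lod] <- "below_lod"
  flags[values >= lod & values < lloq] <- "below_lloq"
  flags[values > uloq] <- "above_uloq"
  flags[is.na(values)] <- "missing"
  flags
}

#' Per-metabolite coefficient of variation of the QC2 repeats
#'
#' @param table a `conc_table` containing QC2 wells.
#' @return named numeric vector, CV (sd/mean) of all QC2 measurements per
#'   metabolite.
#' @export
qc2_cv <- function(table) {
  stopifnot(inherits(table, "conc_table"))
  qc2 <- table$values[table$samples$sample_type == "QC2", , drop = FALSE]
  if (nrow(qc2) < 2L) stop("need at least 2 QC2 wells to compute a CV")
  m <- colMeans(qc2, na.rm = TRUE)
  s <- apply(qc2, 2, stats::sd, na.rm = TRUE)
  cv <- s / m
  cv[!is.finite(cv)] <- NA_real_
  cv
}

#' Apply the metabolite exclusion rules
#'
#' A metabolite is excluded when, over study samples only, the pooled
#' fraction of measurements below LOD, below LLOQ or above ULOQ exceeds
#' `max_out_of_range_fraction`; or when its QC2 coefficient of variation
#' exceeds `max_qc2_cv`; or when its mean blank-well value exceeds the
#' LOD ("blank out of range"). Rules are evaluated in that order and the
#' first violated rule is recorded as the reason. Missing cells count
#' toward neither the numerator nor the denominator of the fraction.
#'
#' @param table a `conc_table` (QC and blank wells included).
#' @param thresholds a [qc_thresholds()] object.
#' @param qc2_stats optional named vector of per-metabolite QC2 CVs; when
#'   `NULL` they are computed from the table's QC2 wells via [qc2_cv()].
#' @return a list with class `exclusion_report`: `retained` (character
#'   vector of abbreviations), `excluded` (named character vector mapping
#'   abbreviation to reason: `"out_of_range_fraction"`, `"qc2_cv"` or
#'   `"blank_out_of_range"`), and `details` (per-metabolite data.frame).
#' @export
exclude_metabolites <- function(table, thresholds = qc_thresholds(),
                                qc2_stats = NULL) {
  stopifnot(inherits(table, "conc_table"))
  is_study <- table$samples$sample_type == "study"
  if (!any(is_study)) stop("no study samples in table")
  if (is.null(qc2_stats)) qc2_stats <- qc2_cv(table)
  absent <- setdiff(table$annotation$abbreviation, names(qc2_stats))
  if (length(absent) > 0L) {
    stop("qc2_stats missing metabolites: ", paste(absent, collapse = ", "))
  }
  is_blank <- table$samples$sample_type == "blank"
  abbrs <- table$annotation$abbreviation
  oor_frac <- numeric(length(abbrs))
  blank_mean <- rep(NA_real_, length(abbrs))
  for (j in seq_along(abbrs)) {
    ann_j <- table$annotation[j, ]
    flags <- flag_out_of_range(table$values[is_study, j], ann_j)
    observed <- flags != "missing"
    oor_frac[j] <- if (any(observed)) {
      mean(flags[observed] %in% c("below_lod", "below_lloq", "above_uloq"))
    } else 0
    if (any(is_blank)) {
      blank_mean[j] <- mean(table$values[is_blank, j], na.rm = TRUE)
    }
  }
  cv <- unname(qc2_stats[abbrs])
  oor_fail <- oor_frac > thresholds$max_out_of_range_fraction
  cv_fail <- !is.na(cv) & cv > thresholds$max_qc2_cv
  blank_fail <- !is.na(blank_mean) & blank_mean > table$annotation$lod
  reason <- rep(NA_character_, length(abbrs))
  reason[blank_fail] <- "blank_out_of_range"
  reason[cv_fail] <- "qc2_cv"
  reason[oor_fail] <- "out_of_range_fraction"  # first rule wins
  excluded <- stats::setNames(reason[!is.na(reason)], abbrs[!is.na(reason)])
  details <- data.frame(abbreviation = abbrs,
                        out_of_range_fraction = oor_frac,
                        qc2_cv = cv, blank_mean = blank_mean,
                        excluded = !is.na(reason),
                        reason = reason,
                        stringsAsFactors = FALSE)
  structure(list(retained = abbrs[is.na(reason)], excluded = excluded,
                 details = details, thresholds = thresholds),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("exclusion_report: ", length(x$retained), " retained, ",
      length(x$excluded), " excluded\n", sep = "")
  if (length(x$excluded) > 0L) print(table(unname(x$excluded)))
  invisible(x)
}

#' Normalize between plates using QC2 repeats
#'
#' For each metabolite, the per-plate QC2 mean is computed and a global
#' target set to the median of the plate means (robust to a single bad
#' plate). Every measurement on a plate is multiplied by
#' `target / plate QC2 mean`, so that after normalization the per-plate
#' QC2 means agree across plates. Missing cells stay missing. The
#' operation is idempotent: re-running it on its own output yields unit
#' factors.
#'
#' @param table a `conc_table`; every plate must carry at least 2 QC2
#'   wells.
#' @return a list: `table` (the normalized `conc_table`) and `factors`
#'   (plate x metabolite matrix of correction factors).
#' @export
qc2_normalize <- function(table) {
  stopifnot(inherits(table, "conc_table"))
  plates <- unique(table$samples$plate_id)
  is_qc2 <- table$samples$sample_type == "QC2"
  for (pl in plates) {
    n_qc2 <- sum(is_qc2 & table$samples$plate_id == pl)
    if (n_qc2 < 2L) stop("plate without (>=2) QC2 wells: ", pl)
  }
  abbrs <- table$annotation$abbreviation
  plate_means <- matrix(NA_real_, length(plates), length(abbrs),
                        dimnames = list(plates, abbrs))
  for (pl in plates) {
    rows <- is_qc2 & table$samples$plate_id == pl
    plate_means[pl, ] <- colMeans(table$values[rows, , drop = FALSE],
                                  na.rm = TRUE)
  }
  if (any(plate_means == 0, na.rm = TRUE)) {
    stop("QC2 mean of zero: correction factor undefined")
  }
  target <- apply(plate_means, 2, stats::median, na.rm = TRUE)
  factors <- sweep(1 / plate_means, 2, target, `*`)
  values <- table$values
  for (pl in plates) {
    rows <- table$samples$plate_id == pl
    values[rows, ] <- sweep(values[rows, , drop = FALSE], 2,
                            factors[pl, ], `*`)
  }
  list(table = conc_table(table$samples, table$annotation, values),
       factors = factors)
}
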