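#' @keywords internal
"_PACKAGE"

# Metadata columns that a concentration CSV must carry, in canonical order.
CONC_META_COLS <- c("sample_id", "sheep_id", "genotype", "clock_time",
                    "sampling_index", "plate_id", "sample_type")

METABOLITE_CLASSES <- c("amino_acid", "biogenic_amine", "acylcarnitine",
                        "lysoPC", "PC_aa", "PC_ae", "sphingolipid")

SAMPLE_TYPES <- c("study", "QC1", "QC2", "QC3", "blank")

#' Construct a metabolite annotation table
#'
#' An annotation table carries, for each metabolite on the panel, its full
#' name, unique abbreviation, compound class and assay quantification limits
#' (LOD, LLOQ, ULOQ, all in uM). The limits drive the out-of-range flagging
#' used by the QC exclusion rules; the class labels drive the per-class
#' significance tabulation.
#'
#' @param name character vector of full metabolite names.
#' @param abbreviation character vector of unique abbreviations used as
#'   column names in concentration tables.
#' @param metabolite_class character vector; one of `"amino_acid"`,
#'   `"biogenic_amine"`, `"acylcarnitine"`, `"lysoPC"`, `"PC_aa"`,
#'   `"PC_ae"`, `"sphingolipid"`.
#' @param lod,lloq,uloq numeric quantification limits in uM with
#'   `lod <= lloq < uloq`.
#' @return a `data.frame` with class `metabolite_annotation`.
#' @export
metabolite_annotation <- function(name, abbreviation, metabolite_class,
                                  lod, lloq, uloq) {
  ann <- data.frame(name = as.character(name),
                    abbreviation = as.character(abbreviation),
                    class = as.character(metabolite_class),
                    lod = as.numeric(lod), lloq = as.numeric(lloq),
                    uloq = as.numeric(uloq),
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
  class(ann) <- c("metabolite_annotation", "data.frame")
  ann
}

validate_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  required <- c("name", "abbreviation", "class", "lod", "lloq", "uloq")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(ann$abbreviation)) {
    dup <- unique(ann$abbreviation[duplicated(ann$abbreviation)])
    stop("duplicate metabolite abbreviations: ", paste(dup, collapse = ", "))
  }
  bad_class <- setdiff(unique(ann$class), METABOLITE_CLASSES)
  if (length(bad_class) > 0L) {
    stop("unknown metabolite class: ", paste(bad_class, collapse = ", "))
  }
  if (any(ann$lod < 0) || any(ann$lloq < 0) || any(ann$uloq <= 0)) {
    stop("quantification limits must be non-negative (ULOQ positive)")
  }
  if (any(ann$lod > ann$lloq) || any(ann$lloq >= ann$uloq)) {
    stop("limits must satisfy lod <= lloq < uloq for every metabolite")
  }
  invisible(ann)
}

#' Construct a concentration table
#'
#' The central container of the pipeline: a sample-by-metabolite matrix of
#' concentrations in uM together with per-sample metadata and the panel
#' annotation. Missing measurements are `NA`. Study samples carry a sheep
#' id; QC and blank wells do not.
#'
#' @param samples data.frame with columns `sample_id`, `sheep_id`,
#'   `genotype` (`"control"`/`"HD"`, `NA` for QC wells), `clock_time`
#'   (decimal hours in \[0, 24)), `sampling_index` (integer, preserves order
#'   across the 25 h window where 15:00 occurs twice), `plate_id`,
#'   `sample_type` (`"study"`, `"QC1"`, `"QC2"`, `"QC3"`, `"blank"`).
#' @param annotation a [metabolite_annotation()] table.
#' @param values numeric matrix, `nrow(samples)` by `nrow(annotation)`,
#'   columns named by abbreviation; `NA` = missing; negative values rejected.
#' @return an object of class `conc_table`.
#' @export
conc_table <- function(samples, annotation, values) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_annotation(annotation)
  missing_meta <- setdiff(CONC_META_COLS, names(samples))
  if (length(missing_meta) > 0L) {
    stop("sample metadata missing columns: ",
         paste(missing_meta, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  }
  if (nrow(values) != nrow(samples) || ncol(values) != nrow(annotation)) {
    stop("value matrix is ", nrow(values), "x", ncol(values),
         " but metadata imply ", nrow(samples), "x", nrow(annotation))
  }
  if (is.null(colnames(values))) colnames(values) <- annotation$abbreviation
  if (!identical(colnames(values), annotation$abbreviation)) {
    stop("value matrix columns must match annotation abbreviations in order")
  }
  bad_type <- setdiff(unique(samples$sample_type), SAMPLE_TYPES)
  if (length(bad_type) > 0L) {
    stop("unknown sample_type: ", paste(bad_type, collapse = ", "))
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("negative concentrations are not allowed")
  }
  is_study <- samples$sample_type == "study"
  if (any(is_study & (is.na(samples$sheep_id) | samples$sheep_id == ""))) {
    stop("every study sample must carry a sheep_id")
  }
  rownames(values) <- samples$sample_id
  structure(list(samples = samples, annotation = annotation,
                 values = values),
            class = "conc_table")
}

#' @export
print.conc_table <- function(x, ...) {
  n_study <- sum(x$samples$sample_type == "study")
  cat("conc_table: ", nrow(x$values), " samples (", n_study, " study) x ",
      ncol(x$values), " metabolites\n", sep = "")
  cat("  sheep: ", length(unique(stats::na.omit(
    x$samples$sheep_id[x$samples$sample_type == "study"]))),
    "  plates: ", length(unique(x$samples$plate_id)),
    "  missing fraction (study): ",
    signif(missing_fraction(x), 3), "\n", sep = "")
  invisible(x)
}

#' @export
dim.conc_table <- function(x) dim(x$values)

#' Fraction of missing study measurements
#'
#' @param table a `conc_table`.
#' @return fraction of `NA` cells among study-sample cells.
#' @export
missing_fraction <- function(table) {
  stopifnot(inherits(table, "conc_table"))
  v <- table$values[table$samples$sample_type == "study", , drop = FALSE]
  if (length(v) == 0L) return(0)
  mean(is.na(v))
}

#' Subset a concentration table
#'
#' @param table a `conc_table`.
#' @param samples logical/integer index over rows, or NULL to keep all.
#' @param metabolites character abbreviations (or index) to keep, or NULL.
#' @return the subsetted `conc_table`.
#' @export
subset_conc_table <- function(table, samples = NULL, metabolites = NULL) {
  stopifnot(inherits(table, "conc_table"))
  si <- if (is.null(samples)) seq_len(nrow(table$values)) else samples
  mi <- if (is.null(metabolites)) seq_len(ncol(table$values)) else {
    if (is.character(metabolites)) {
      idx <- match(metabolites, table$annotation$abbreviation)
      if (anyNA(idx)) {
        stop("unknown metabolite(s): ",
             paste(metabolites[is.na(idx)], collapse = ", "))
      }
      idx
    } else metabolites
  }
  conc_table(table$samples[si, , drop = FALSE],
             `class<-`(table$annotation[mi, , drop = FALSE],
                       c("metabolite_annotation", "data.frame")),
             table$values[si, mi, drop = FALSE])
}

#' Read a concentration table and its panel annotation from CSV
#'
#' The concentration file must have one header row, the metadata columns
#' `sample_id, sheep_id, genotype, clock_time, sampling_index, plate_id,
#' sample_type`, and one column per metabolite named by its abbreviation.
#' Empty cells become missing values. The annotation file needs the columns
#' of [metabolite_annotation()].
#'
#' @param path path to the concentration CSV.
#' @param annotation_path path to the panel annotation CSV.
#' @return a validated `conc_table`.
#' @export
read_concentration_table <- function(path, annotation_path) {
  if (!file.exists(path)) stop("concentration file not found: ", path)
  if (!file.exists(annotation_path)) {
    stop("annotation file not found: ", annotation_path)
  }
  ann_raw <- utils::read.csv(annotation_path, check.names = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
  ann <- metabolite_annotation(ann_raw$name, ann_raw$abbreviation,
                               ann_raw$class, ann_raw$lod, ann_raw$lloq,
                               ann_raw$uloq)
  extra <- setdiff(names(ann_raw),
                   c("name", "abbreviation", "class", "lod", "lloq", "uloq"))
  for (col in extra) ann[[col]] <- ann_raw[[col]]

  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#",
                         na.strings = c("", "NA"))
  missing_meta <- setdiff(CONC_META_COLS, names(raw))
  if (length(missing_meta) > 0L) {
    stop("concentration file missing metadata columns: ",
         paste(missing_meta, collapse = ", "))
  }
  met_cols <- setdiff(names(raw), CONC_META_COLS)
  unknown <- setdiff(met_cols, ann$abbreviation)
  if (length(unknown) > 0L) {
    stop("metabolite column(s) absent from annotation: ",
         paste(unknown, collapse = ", "))
  }
  absent <- setdiff(ann$abbreviation, met_cols)
  if (length(absent) > 0L) {
    stop("annotation metabolite(s) missing from concentration file: ",
         paste(absent, collapse = ", "))
  }
  values <- as.matrix(raw[, ann$abbreviation, drop = FALSE])
  storage.mode(values) <- "double"
  samples <- raw[, CONC_META_COLS]
  samples$sheep_id <- as.character(samples$sheep_id)
  samples$sample_id <- as.character(samples$sample_id)
  samples$plate_id <- as.character(samples$plate_id)
  conc_table(samples, ann, values)
}

#' Write a concentration table (and optionally its annotation) to CSV
#'
#' @param table a `conc_table`.
#' @param path output CSV path for the concentration matrix + metadata.
#' @param annotation_path optional output path for the annotation.
#' @return invisibly, `path`.
#' @export
write_concentration_table <- function(table, path, annotation_path = NULL) {
  stopifnot(inherits(table, "conc_table"))
  df <- cbind(table$samples,
              as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(annotation_path)) {
    utils::write.csv(as.data.frame(table$annotation), annotation_path,
                     row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Write a tabular result to delimiter-separated text
#'
#' Writes a comma-separated file with one header row, preceded by a comment
#' line stating the floating-point precision used. Refuses to write an
#' empty table.
#'
#' @param rows a non-empty data.frame.
#' @param path output path.
#' @param digits significant digits for floating-point columns (default 10,
#'   recorded in the file's header comment).
#' @return invisibly, `path`.
#' @export
write_results_table <- function(rows, path, digits = 10) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stop("refusing to write an empty results table")
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- signif(out[[j]], digits)
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# floating-point values at %d significant digits",
                     digits), con)
  utils::write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path input path.
#' @return a data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#", na.strings = c("", "NA"))
}

#' Load the packaged per-metabolite screening summary table
#'
#' Returns the packaged machine-readable copy of the published
#' per-metabolite ANOVA summary for the 130-metabolite ovine plasma panel:
#' genotype / time-of-day / interaction FDR values and 24 h group means
#' (+/- SEM, uM) for 10 control and 14 HD transgenic sheep. Taurine is
#' carried with its amine class label plus the flag
#' `counted_as_amino_acid_in_methods`.
#'
#' @return a data.frame with one row per metabolite, columns `name`,
#'   `abbreviation`, `class`, `fdr_genotype`, `fdr_time`,
#'   `fdr_interaction`, `control_mean`, `control_sem`, `hd_mean`,
#'   `hd_sem`, `counted_as_amino_acid_in_methods`.
#' @export
load_reference_screen <- function() {
  path <- system.file("extdata", "table1_anova.csv", package = "metabpanel",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
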