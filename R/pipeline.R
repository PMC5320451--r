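#' Pipeline configuration
#'
#' Collects every input path, threshold and seed of an end-to-end run.
#' Can be built directly or read from a YAML file with the same field
#' names.
#'
#' @param concentrations path to the concentration CSV.
#' @param annotation path to the panel annotation CSV.
#' @param melatonin path to the melatonin CSV (long format: `sheep_id`,
#'   `clock_time`, `concentration`).
#' @param out_dir output directory (created if absent).
#' @param thresholds a [qc_thresholds()].
#' @param dlmo_threshold melatonin onset threshold fraction, default
#'   0.25.
#' @param alpha screening FDR cutoff, default 0.05.
#' @param criteria a [marker_filter_criteria()].
#' @param max_panel_size largest panel size, default 12.
#' @param target_specificity operating specificity for the reported
#'   sensitivity, default 0.90.
#' @return a list with class `pipeline_config`.
#' @export
pipeline_config <- function(concentrations, annotation, melatonin,
                            out_dir, thresholds = qc_thresholds(),
                            dlmo_threshold = 0.25, alpha = 0.05,
                            criteria = marker_filter_criteria(),
                            max_panel_size = 12,
                            target_specificity = 0.90) {
  for (p in c(concentrations, annotation, melatonin)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(concentrations = concentrations, annotation = annotation,
                 melatonin = melatonin, out_dir = out_dir,
                 thresholds = thresholds, dlmo_threshold = dlmo_threshold,
                 alpha = alpha, criteria = criteria,
                 max_panel_size = max_panel_size,
                 target_specificity = target_specificity),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()]; nested keys `thresholds` and `criteria` are
#'   passed to [qc_thresholds()] and [marker_filter_criteria()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- if (is.null(y$thresholds)) qc_thresholds() else {
    do.call(qc_thresholds, y$thresholds)
  }
  crit <- if (is.null(y$criteria)) marker_filter_criteria() else {
    do.call(marker_filter_criteria, y$criteria)
  }
  pipeline_config(
    concentrations = y$concentrations, annotation = y$annotation,
    melatonin = y$melatonin, out_dir = y$out_dir, thresholds = thr,
    dlmo_threshold = y$dlmo_threshold %||% 0.25,
    alpha = y$alpha %||% 0.05, criteria = crit,
    max_panel_size = y$max_panel_size %||% 12,
    target_specificity = y$target_specificity %||% 0.90)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_melatonin_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  lapply(split(df, df$sheep_id), function(d) {
    d <- d[order(seq_len(nrow(d))), ]
    melatonin_profile(d$sheep_id[1], d$clock_time, d$concentration)
  })
}

write_melatonin_csv <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sheep_id = p$sheep_id, clock_time = p$times,
               concentration = p$concentrations,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stage order: QC exclusion, QC2 between-plate normalization, DLMO
#' phase alignment, per-metabolite ANOVA screening with FDR, class
#' tabulation, urea-cycle ratios, marker pre-selection, forward-stepwise
#' panel building under leave-one-sheep-out cross-validation, ROC and
#' per-phase-bin AUC reporting, and the clustering leaf order for the
#' heat map. Every artifact is written to `config$out_dir` together with
#' a manifest recording seeds, thresholds and input checksums; re-running
#' with the same config reproduces the bundle bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  table <- stage("read", read_concentration_table(config$concentrations,
                                                  config$annotation))
  report <- stage("qc_exclude",
                  exclude_metabolites(table, config$thresholds))
  write_results_table(report$details, out("exclusions.csv"))
  table <- subset_conc_table(table, metabolites = report$retained)

  norm <- stage("qc2_normalize", qc2_normalize(table))
  table <- norm$table
  write_concentration_table(table, out("normalized.csv"))

  profiles <- stage("melatonin", read_melatonin_csv(config$melatonin))
  alignments <- stage("dlmo",
                      compute_alignments(profiles, config$dlmo_threshold))
  write_results_table(alignments, out("dlmo.csv"))
  table <- stage("align", align_to_dlmo(table, alignments))

  results <- stage("screen", screen_metabolites(table))
  write_results_table(results, out("anova.csv"))
  summary <- summarize_significance(results, alpha = config$alpha)
  write_results_table(summary, out("summary.csv"))

  ratios <- stage("ratios", {
    defs <- urea_cycle_ratios()
    avail <- vapply(defs, function(d) {
      all(c(d$numerator, d$denominator) %in%
            table$annotation$abbreviation)
    }, logical(1))
    lapply(defs[avail], function(d) {
      series <- compute_ratio_series(table, d)
      is_study <- table$samples$sample_type == "study"
      p <- fit_metabolite_anova(series[is_study],
                                table$samples[is_study, ])
      gm <- group_means_sem(series[is_study],
                            table$samples[is_study, ])
      c(list(name = d$name), as.list(p), as.list(gm))
    })
  })
  if (length(ratios) > 0L) {
    write_results_table(do.call(rbind, lapply(ratios, as.data.frame)),
                        out("ratios.csv"))
  }

  presel <- stage("preselect",
                  preselect_markers(results, table, config$criteria))
  write_results_table(presel, out("preselection.csv"))
  candidates <- presel$abbreviation[presel$selected]

  panel_stage <- if (length(candidates) > 0L) {
    stage("panel", {
      fdr <- stats::setNames(results$fdr_genotype, results$abbreviation)
      panels <- stepwise_build_panels(table, candidates,
                                      max_size = config$max_panel_size,
                                      fdr = fdr)
      final <- panels[[length(panels)]]
      preds <- losocv_predictions(table, final$markers)
      roc <- roc_curve(preds)
      opp <- sensitivity_at_specificity(preds, config$target_specificity)
      bins <- auc_by_timepoint(preds)
      sheep <- sheep_level_classification(preds, opp$threshold)
      list(panels = panels, predictions = preds, roc = roc,
           operating_point = opp, bin_auc = bins, sheep = sheep)
    })
  } else NULL
  if (!is.null(panel_stage)) {
    jsonlite::write_json(
      lapply(panel_stage$panels, function(p) {
        list(markers = p$markers,
             coefficients = as.list(p$coefficients),
             step_auc = p$step_auc, final_auc = p$final_auc)
      }),
      out("panel.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_results_table(
      data.frame(threshold = panel_stage$roc$thresholds,
                 sensitivity = panel_stage$roc$sensitivity,
                 specificity = panel_stage$roc$specificity),
      out("roc.csv"))
    write_results_table(panel_stage$bin_auc, out("bin_auc.csv"))
    write_results_table(panel_stage$sheep, out("sheep_predictions.csv"))
  }

  clust <- stage("cluster", {
    prof <- binned_genotype_profiles(table)
    hierarchical_cluster_order(prof)
  })
  write_results_table(
    data.frame(leaf = clust$order,
               abbreviation = rownames(clust$matrix)[clust$order]),
    out("cluster_order.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("metabpanel")),
    inputs = list(
      concentrations = unname(tools::md5sum(config$concentrations)),
      annotation = unname(tools::md5sum(config$annotation)),
      melatonin = unname(tools::md5sum(config$melatonin))),
    thresholds = unclass(config$thresholds),
    criteria = unclass(config$criteria),
    dlmo_threshold = config$dlmo_threshold, alpha = config$alpha,
    max_panel_size = config$max_panel_size,
    target_specificity = config$target_specificity)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(exclusions = report, table = table, results = results,
                 summary = summary, ratios = ratios,
                 preselection = presel, panel = panel_stage,
                 cluster = clust))
}

#' Metabolite-by-phase-bin standardized group-mean profiles
#'
#' Builds the matrix clustered for the heat map: per-genotype,
#' per-phase-bin mean concentrations, standardized per metabolite
#' (z-score across bins) so that profile shape rather than absolute
#' scale drives the clustering.
#'
#' @param table an aligned `conc_table` (with `phase_offset`).
#' @param standardize z-score each row (default TRUE).
#' @return numeric matrix, metabolites by (genotype x bin) columns.
#' @export
binned_genotype_profiles <- function(table, standardize = TRUE) {
  stopifnot(inherits(table, "conc_table"))
  s <- table$samples
  is_study <- s$sample_type == "study"
  if (!"phase_offset" %in% names(s)) {
    stop("table must be phase-aligned first (see align_to_dlmo)")
  }
  bins <- phase_bin(s$phase_offset[is_study])
  geno <- s$genotype[is_study]
  v <- table$values[is_study, , drop = FALSE]
  key <- interaction(geno, bins, drop = TRUE)
  prof <- t(apply(v, 2, function(col) {
    tapply(col, key, mean, na.rm = TRUE)
  }))
  if (standardize) {
    prof <- t(scale(t(prof)))
    prof[is.nan(prof)] <- 0
  }
  prof
}

#' Agglomerative clustering order for the heat map
#'
#' Euclidean distance with Ward linkage; deterministic given the input
#' (ties resolved by lower row index, the default of the underlying
#' agglomeration). Rows with missing cells are rejected: group-mean
#' profiles must be complete before clustering.
#'
#' @param matrix numeric matrix with at least 2 rows and no missing
#'   cells.
#' @return a list: `order` (leaf order), `merge` and `height` (the merge
#'   tree), `hclust` (the full `stats::hclust` object), `matrix` (the
#'   input).
#' @export
hierarchical_cluster_order <- function(matrix) {
  if (nrow(matrix) < 2L) stop("need >= 2 rows to cluster")
  if (anyNA(matrix)) {
    stop("missing cells in profile matrix; impute upstream before ",
         "clustering")
  }
  hc <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                      method = "ward.D2")
  list(order = hc$order, merge = hc$merge, height = hc$height,
       hclust = hc, matrix = matrix)
}
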