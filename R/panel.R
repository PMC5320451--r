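#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' AUC equals the probability that a randomly chosen case scores above a
#' randomly chosen control, with ties counted half:
#' `(#{case-control pairs with case > control} + 0.5 * ties) / (n1 * n0)`.
#' Computed via midranks.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels 0/1 vector; 1 is the positive (HD) class.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Marker pre-selection criteria
#'
#' @param alpha_fdr genotype FDR cutoff (strict `<`), default 0.05.
#' @param perm_alpha permutation p-value cutoff (strict `<`), default
#'   0.05.
#' @param n_permutations number of sheep-level label permutations for the
#'   AUC null, default 10000 (minimum 100).
#' @param min_relative_difference minimum `|hd - control| / control`
#'   group-mean difference (strict `>`), default 0.05.
#' @param permutation_seed integer seed making the permutation null
#'   reproducible.
#' @return a list with class `marker_filter_criteria`.
#' @export
marker_filter_criteria <- function(alpha_fdr = 0.05, perm_alpha = 0.05,
                                   n_permutations = 10000,
                                   min_relative_difference = 0.05,
                                   permutation_seed = 1L) {
  if (alpha_fdr <= 0 || perm_alpha <= 0 || min_relative_difference <= 0) {
    stop("criteria must be positive")
  }
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  structure(list(alpha_fdr = alpha_fdr, perm_alpha = perm_alpha,
                 n_permutations = as.integer(n_permutations),
                 min_relative_difference = min_relative_difference,
                 permutation_seed = as.integer(permutation_seed)),
            class = "marker_filter_criteria")
}

# Sheep-level genotype layout of the study samples of a conc_table:
# per-sheep row indices and labels, used by the permutation null and the
# cross-validation folds.
sheep_layout <- function(table) {
  s <- table$samples
  is_study <- s$sample_type == "study"
  sheep <- unique(s$sheep_id[is_study])
  rows <- lapply(sheep, function(sh) which(is_study & s$sheep_id == sh))
  geno <- vapply(rows, function(r) s$genotype[r[1]], character(1))
  list(sheep = sheep, rows = rows,
       is_hd = geno == "HD", study_rows = which(is_study))
}

#' Sheep-level permutation test of a single-marker AUC
#'
#' The observed statistic is the non-cross-validated single-marker AUC
#' with orientation `max(AUC, 1 - AUC)` (a marker may discriminate in
#' either direction). The null is built by permuting genotype labels at
#' the sheep level -- all samples of one animal move together, because
#' repeated samples within an animal are exchangeable only as a block --
#' recomputing the oriented AUC for each relabelling. The p-value uses
#' the add-one estimator `(1 + #{perm >= observed}) / (1 + B)`, so it is
#' never below `1/(B+1)`.
#'
#' Internally the permuted AUCs are computed from per-sheep rank sums
#' (scores are fixed under relabelling), which is algebraically identical
#' to the midrank AUC of [auc()].
#'
#' @param values one metabolite's concentrations per sample of `table`
#'   (study rows are used).
#' @param table a `conc_table` supplying sheep ids and genotypes.
#' @param criteria a [marker_filter_criteria()]; uses `n_permutations`
#'   and `permutation_seed`.
#' @return list: `observed_auc` (oriented), `p_value`, `n_permutations`.
#' @export
permutation_auc_test <- function(values, table, criteria =
                                   marker_filter_criteria()) {
  lay <- sheep_layout(table)
  n_sheep <- length(lay$sheep)
  n_hd <- sum(lay$is_hd)
  if (n_hd == 0L || n_hd == n_sheep) stop("both genotypes must be present")
  if (choose(n_sheep, n_hd) < 20) {
    stop("fewer than 20 distinct sheep-label assignments; ",
         "use exact enumeration instead of sampling")
  }
  v <- values[lay$study_rows]
  keep <- !is.na(v)
  v <- v[keep]
  # map study rows back to per-sheep ids on the non-missing subset
  row_sheep <- integer(length(lay$study_rows))
  for (i in seq_along(lay$rows)) {
    row_sheep[match(lay$rows[[i]], lay$study_rows)] <- i
  }
  row_sheep <- row_sheep[keep]
  r <- rank(v, ties.method = "average")
  sheep_ranksum <- vapply(seq_len(n_sheep),
                          function(i) sum(r[row_sheep == i]), numeric(1))
  sheep_n <- vapply(seq_len(n_sheep),
                    function(i) sum(row_sheep == i), numeric(1))
  auc_from_assignment <- function(hd_idx) {
    n1 <- sum(sheep_n[hd_idx]); n0 <- length(v) - n1
    if (n1 == 0 || n0 == 0) return(NA_real_)
    a <- (sum(sheep_ranksum[hd_idx]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    max(a, 1 - a)
  }
  observed <- auc_from_assignment(which(lay$is_hd))
  B <- criteria$n_permutations
  perm_auc <- local({
    rng <- get_rng_state()
    on.exit(restore_rng_state(rng))
    set.seed(criteria$permutation_seed)
    vapply(seq_len(B), function(b) {
      auc_from_assignment(sample.int(n_sheep, n_hd))
    }, numeric(1))
  })
  p <- (1 + sum(perm_auc >= observed, na.rm = TRUE)) / (1 + B)
  list(observed_auc = observed, p_value = p, n_permutations = B)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Pre-select candidate markers for panel building
#'
#' A marker passes when all three criteria hold: (1) genotype FDR below
#' `alpha_fdr` in the screening results; (2) sheep-level permutation AUC
#' p-value below `perm_alpha`; (3) relative group-mean difference
#' `|hd_mean - control_mean| / control_mean` above
#' `min_relative_difference`. All three verdicts are reported for every
#' metabolite.
#'
#' @param results an `anova_results` table from [screen_metabolites()].
#' @param table the `conc_table` the results were computed from.
#' @param criteria a [marker_filter_criteria()].
#' @return data.frame, one row per metabolite: `abbreviation`,
#'   `pass_fdr`, `pass_permutation`, `pass_difference`, `selected`, plus
#'   `observed_auc`, `perm_p`, `relative_difference`.
#' @export
preselect_markers <- function(results, table,
                              criteria = marker_filter_criteria()) {
  stopifnot(inherits(table, "conc_table"))
  idx <- match(results$abbreviation, table$annotation$abbreviation)
  if (anyNA(idx)) stop("results and table disagree on the panel")
  n <- nrow(results)
  perm_p <- obs_auc <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    pt <- permutation_auc_test(table$values[, idx[j]], table, criteria)
    perm_p[j] <- pt$p_value
    obs_auc[j] <- pt$observed_auc
  }
  if (any(results$control_mean == 0)) {
    stop("relative difference undefined (control mean 0) for: ",
         paste(results$abbreviation[results$control_mean == 0],
               collapse = ", "))
  }
  rel_diff <- abs(results$hd_mean - results$control_mean) /
    results$control_mean
  out <- data.frame(
    abbreviation = results$abbreviation,
    fdr_genotype = results$fdr_genotype,
    observed_auc = obs_auc, perm_p = perm_p,
    relative_difference = rel_diff,
    pass_fdr = results$fdr_genotype < criteria$alpha_fdr,
    pass_permutation = perm_p < criteria$perm_alpha,
    pass_difference = rel_diff > criteria$min_relative_difference,
    stringsAsFactors = FALSE)
  out$selected <- out$pass_fdr & out$pass_permutation & out$pass_difference
  out
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximizes the binomial log-likelihood; convergence when the largest
#' coefficient change drops below `tol` (default 1e-8) or after
#' `max_iter` iterations. When (quasi-)complete separation is detected --
#' fitted probabilities numerically at 0/1 with diverging coefficients --
#' the model is refitted with a fixed ridge penalty of 1e-6 on the
#' non-intercept coefficients and the fit is flagged.
#'
#' @param features numeric matrix, samples by markers (log-concentration
#'   scale); no missing values.
#' @param labels 0/1 response.
#' @param tol,max_iter convergence controls.
#' @return list with class `logistic_fit`: `coefficients` (intercept
#'   first), `converged`, `separation` (logical flag), `fitted`.
#' @export
fit_logistic <- function(features, labels, tol = 1e-8, max_iter = 100) {
  X <- cbind(`(Intercept)` = 1, as.matrix(features))
  y <- as.numeric(labels)
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (length(unique(y)) < 2L) stop("need both classes to fit")
  irls <- function(lambda) {
    beta <- numeric(ncol(X))
    pen <- diag(c(0, rep(lambda, ncol(X) - 1L)), ncol(X))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- pmin(pmax(drop(X %*% beta), -30), 30)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / w
      A <- crossprod(X, X * w) + pen
      beta_new <- tryCatch(solve(A, crossprod(X, w * z)),
                           error = function(e) NULL)
      if (is.null(beta_new)) return(NULL)
      delta <- max(abs(beta_new - beta))
      beta <- drop(beta_new)
      if (delta < tol) { converged <- TRUE; break }
    }
    mu <- stats::plogis(pmin(pmax(drop(X %*% beta), -30), 30))
    list(coefficients = stats::setNames(beta, colnames(X)),
         converged = converged, fitted = mu)
  }
  fit <- irls(0)
  separated <- is.null(fit) || !fit$converged ||
    any(fit$fitted > 1 - 1e-8 | fit$fitted < 1e-8)
  if (separated) {
    fit <- irls(1e-6)
    if (is.null(fit)) stop("logistic fit failed even with ridge penalty")
  }
  structure(list(coefficients = fit$coefficients,
                 converged = fit$converged, separation = separated,
                 fitted = fit$fitted),
            class = "logistic_fit")
}

#' Predicted probabilities from a logistic fit
#'
#' @param fit a `logistic_fit`.
#' @param features matrix with the same marker columns used in fitting.
#' @return numeric vector of probabilities.
#' @export
predict_logistic <- function(fit, features) {
  X <- cbind(1, as.matrix(features))
  stats::plogis(pmin(pmax(drop(X %*% fit$coefficients), -30), 30))
}

# Per-fold feature preparation: impute missing raw values with the
# training-fold mean, floor non-positive values at half the training
# fold's smallest positive value, then take natural logs. Imputation and
# flooring statistics come from the training fold only, so no
# information leaks from the held-out sheep.
prepare_fold_features <- function(raw_train, raw_test) {
  k <- ncol(raw_train)
  for (j in seq_len(k)) {
    col <- raw_train[, j]
    m <- mean(col, na.rm = TRUE)
    if (is.nan(m)) stop("marker column entirely missing in training fold")
    raw_train[is.na(raw_train[, j]), j] <- m
    raw_test[is.na(raw_test[, j]), j] <- m
    pos <- raw_train[, j][raw_train[, j] > 0]
    floor_val <- if (length(pos) > 0) min(pos) / 2 else 1e-12
    raw_train[raw_train[, j] <= 0, j] <- floor_val
    raw_test[raw_test[, j] <= 0, j] <- floor_val
  }
  list(train = log(raw_train), test = log(raw_test))
}

#' Leave-one-sheep-out cross-validated predictions
#'
#' One fold per animal: a logistic model on the log-transformed marker
#' concentrations is trained on all samples of all other sheep and used
#' to predict every sample of the held-out sheep. Missing marker values
#' are imputed as the per-marker mean across training-fold samples (raw
#' scale, before the log transform). Time never enters the feature set.
#' Predictions are pooled over folds, so every study sample receives
#' exactly one held-out prediction.
#'
#' @param table a `conc_table`; needs at least 3 sheep per genotype.
#' @param markers character vector of marker abbreviations (non-empty).
#' @return data.frame of class `cv_predictions`: `sample_id`,
#'   `sheep_id`, `genotype`, `phase_bin`, `predicted_probability`.
#' @export
losocv_predictions <- function(table, markers) {
  stopifnot(inherits(table, "conc_table"))
  if (length(markers) == 0L) stop("markers must be non-empty")
  folds <- losocv_folds(table, markers)
  predict_folds(folds, seq_along(markers))
}

# Precompute everything fold-dependent once for a candidate marker set,
# so stepwise search can evaluate marker subsets by column-indexing.
losocv_folds <- function(table, markers) {
  lay <- sheep_layout(table)
  if (sum(lay$is_hd) < 3L || sum(!lay$is_hd) < 3L) {
    stop("need >= 3 sheep per genotype for leave-one-sheep-out CV")
  }
  midx <- match(markers, table$annotation$abbreviation)
  if (anyNA(midx)) {
    stop("unknown marker(s): ", paste(markers[is.na(midx)], collapse = ", "))
  }
  s <- table$samples
  raw <- table$values[, midx, drop = FALSE]
  bins <- if ("phase_offset" %in% names(s)) {
    phase_bin(s$phase_offset)
  } else {
    s$clock_time
  }
  folds <- lapply(seq_along(lay$sheep), function(i) {
    test_rows <- lay$rows[[i]]
    train_rows <- setdiff(lay$study_rows, test_rows)
    y_train <- as.numeric(s$genotype[train_rows] == "HD")
    if (length(unique(y_train)) < 2L) {
      stop("fold for sheep ", lay$sheep[i], " loses one class entirely")
    }
    feats <- prepare_fold_features(raw[train_rows, , drop = FALSE],
                                   raw[test_rows, , drop = FALSE])
    list(train = feats$train, test = feats$test, y_train = y_train,
         test_rows = test_rows)
  })
  list(folds = folds, samples = s, markers = markers, bins = bins)
}

predict_folds <- function(fold_data, marker_idx) {
  s <- fold_data$samples
  out <- lapply(fold_data$folds, function(f) {
    fit <- fit_logistic(f$train[, marker_idx, drop = FALSE], f$y_train)
    p <- predict_logistic(fit, f$test[, marker_idx, drop = FALSE])
    data.frame(sample_id = s$sample_id[f$test_rows],
               sheep_id = s$sheep_id[f$test_rows],
               genotype = s$genotype[f$test_rows],
               phase_bin = fold_data$bins[f$test_rows],
               predicted_probability = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("cv_predictions", "data.frame")
  res
}

cv_auc <- function(predictions) {
  auc(predictions$predicted_probability,
      as.integer(predictions$genotype == "HD"))
}

#' Forward-stepwise construction of logistic marker panels
#'
#' Step 1 selects the single candidate with the highest pooled
#' leave-one-sheep-out cross-validated AUC; each later step adds the
#' candidate with the largest strictly positive AUC gain. The search
#' stops when no candidate improves the AUC or `max_size` is reached.
#' All intermediate panels are returned. Ties in gain are broken by
#' smaller genotype FDR (when supplied), then alphabetically.
#'
#' @param table a `conc_table`.
#' @param candidates character vector of candidate marker abbreviations.
#' @param max_size largest panel size to consider, default 12.
#' @param fdr optional named numeric vector of genotype FDRs used for
#'   tie-breaking.
#' @return list of class `panel_models`; each element has `markers`,
#'   `coefficients` (from a fit on all samples, log scale),
#'   `step_auc` (cross-validated AUC after each step so far) and
#'   `final_auc`. The step AUC sequence is strictly increasing by
#'   construction.
#' @export
stepwise_build_panels <- function(table, candidates, max_size = 12,
                                  fdr = NULL) {
  if (length(candidates) == 0L) stop("candidates must be non-empty")
  fold_data <- losocv_folds(table, candidates)
  cand_fdr <- if (is.null(fdr)) {
    stats::setNames(rep(NA_real_, length(candidates)), candidates)
  } else fdr[candidates]
  chosen <- integer(0)
  step_auc <- numeric(0)
  panels <- list()
  best_auc <- -Inf
  repeat {
    remaining <- setdiff(seq_along(candidates), chosen)
    if (length(remaining) == 0L || length(chosen) >= max_size) break
    cand_auc <- vapply(remaining, function(j) {
      cv_auc(predict_folds(fold_data, c(chosen, j)))
    }, numeric(1))
    ord <- order(-cand_auc, cand_fdr[remaining],
                 candidates[remaining], method = "radix")
    best_j <- remaining[ord[1]]
    best_val <- cand_auc[ord[1]]
    if (length(chosen) > 0L && best_val <= best_auc) break
    if (length(chosen) == 0L || best_val > best_auc) {
      chosen <- c(chosen, best_j)
      best_auc <- best_val
      step_auc <- c(step_auc, best_val)
      panels[[length(panels) + 1L]] <- build_panel_model(
        table, candidates[chosen], step_auc)
    }
  }
  structure(panels, class = "panel_models")
}

build_panel_model <- function(table, markers, step_auc) {
  is_study <- table$samples$sample_type == "study"
  midx <- match(markers, table$annotation$abbreviation)
  raw <- table$values[is_study, midx, drop = FALSE]
  feats <- prepare_fold_features(raw, raw)$train
  y <- as.numeric(table$samples$genotype[is_study] == "HD")
  fit <- fit_logistic(feats, y)
  structure(list(markers = markers, coefficients = fit$coefficients,
                 separation = fit$separation, step_auc = step_auc,
                 final_auc = step_auc[length(step_auc)]),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat("panel_model with", length(x$markers), "marker(s):",
      paste(x$markers, collapse = ", "), "\n")
  cat("  cross-validated AUC:", round(x$final_auc, 3), "\n")
  invisible(x)
}

#' ROC curve from pooled cross-validated predictions
#'
#' @param predictions a `cv_predictions` data.frame.
#' @return list with class `roc_curve`: descending `thresholds`,
#'   `sensitivity`, `specificity` and the trapezoidal `auc`.
#' @export
roc_curve <- function(predictions) {
  scores <- predictions$predicted_probability
  labels <- as.integer(predictions$genotype == "HD")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- spec <- numeric(length(thr))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  for (i in seq_along(thr)) {
    pos <- scores >= thr[i]
    sens[i] <- sum(pos & labels == 1L) / n1
    spec[i] <- sum(!pos & labels == 0L) / n0
  }
  fpr <- 1 - spec
  area <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(thresholds = thr, sensitivity = sens,
                 specificity = spec, auc = area),
            class = "roc_curve")
}

#' Sensitivity at a fixed specificity
#'
#' Sweeps all decision thresholds (predicted positive when probability >=
#' threshold) and returns the maximum sensitivity among thresholds whose
#' specificity is at least the target, together with that threshold. No
#' interpolation between operating points.
#'
#' @param predictions a `cv_predictions` data.frame.
#' @param target_specificity required specificity in (0, 1), default
#'   0.90.
#' @return list: `sensitivity`, `threshold`, `specificity` (achieved).
#' @export
sensitivity_at_specificity <- function(predictions,
                                       target_specificity = 0.90) {
  if (target_specificity <= 0 || target_specificity >= 1) {
    stop("target specificity must lie in (0, 1)")
  }
  scores <- predictions$predicted_probability
  labels <- as.integer(predictions$genotype == "HD")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  thr <- c(sort(unique(scores), decreasing = TRUE), Inf)
  best <- list(sensitivity = 0, threshold = Inf, specificity = 1)
  for (t in thr) {
    pos <- scores >= t
    spec <- sum(!pos & labels == 0L) / n0
    if (spec >= target_specificity) {
      sens <- sum(pos & labels == 1L) / n1
      if (sens > best$sensitivity) {
        best <- list(sensitivity = sens, threshold = t,
                     specificity = spec)
      }
    }
  }
  best
}

#' Cross-validated AUC per circadian phase bin
#'
#' Partitions the pooled cross-validated predictions by phase bin and
#' computes the AUC within each bin. Bins missing one class are reported
#' with an `NA` AUC rather than dropped.
#'
#' @param predictions a `cv_predictions` data.frame.
#' @return data.frame: `phase_bin`, `n`, `auc` (NA when a class is
#'   absent in the bin).
#' @export
auc_by_timepoint <- function(predictions) {
  bins <- sort(unique(predictions$phase_bin))
  rows <- lapply(bins, function(b) {
    p <- predictions[predictions$phase_bin == b, ]
    a <- if (length(unique(p$genotype)) < 2L) NA_real_ else cv_auc(p)
    data.frame(phase_bin = b, n = nrow(p), auc = a)
  })
  do.call(rbind, rows)
}

#' Per-sheep classification from pooled CV predictions
#'
#' Summarizes each animal by the median of its held-out per-sample
#' probabilities and classifies it against a decision threshold
#' (typically the one returned by [sensitivity_at_specificity()]).
#'
#' @param predictions a `cv_predictions` data.frame.
#' @param threshold decision threshold on the median probability.
#' @return data.frame: `sheep_id`, `genotype`, `median_probability`,
#'   `predicted_hd`.
#' @export
sheep_level_classification <- function(predictions, threshold) {
  sheep <- unique(predictions$sheep_id)
  rows <- lapply(sheep, function(sh) {
    p <- predictions[predictions$sheep_id == sh, ]
    med <- stats::median(p$predicted_probability)
    data.frame(sheep_id = sh, genotype = p$genotype[1],
               median_probability = med,
               predicted_hd = med >= threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
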