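test_that("AUC matches pair enumeration, ties and edge cases", {
  expect_equal(auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(3, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # cases (0.9, 0.4), controls (0.5, 0.1): 3 of 4 pairs favourable
  expect_equal(auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(6:25, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(auc(scores, labels), auc_pair_oracle(scores, labels))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4)
  expect_equal(auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
})

test_that("sheep-level permutation p-values match exhaustive enumeration", {
  # 3+3 sheep: exactly choose(6,3) = 20 label assignments
  tab <- tiny_cohort(n_control = 3, n_hd = 3, timepoints = 4, n_metab = 1,
                     seed = 8, hd_shift = 0.6)
  crit <- marker_filter_criteria(n_permutations = 4000,
                                 permutation_seed = 5)
  got <- permutation_auc_test(tab$values[, 1], tab, crit)
  # enumeration oracle over all 20 assignments
  lay <- metabpanel:::sheep_layout(tab)
  v <- tab$values[lay$study_rows, 1]
  labels_for <- function(hd_set) {
    lab <- integer(length(v))
    for (i in hd_set) lab[match(lay$rows[[i]], lay$study_rows)] <- 1L
    lab
  }
  all_sets <- utils::combn(6, 3, simplify = FALSE)
  null_auc <- vapply(all_sets, function(s) {
    a <- auc_pair_oracle(v, labels_for(s))
    max(a, 1 - a)
  }, numeric(1))
  obs <- max(auc_pair_oracle(v, labels_for(which(lay$is_hd))),
             1 - auc_pair_oracle(v, labels_for(which(lay$is_hd))))
  expect_equal(got$observed_auc, obs)
  exact_p <- mean(null_auc >= obs)
  # Monte-Carlo estimate converges to the exhaustive value
  expect_lt(abs(got$p_value - exact_p), 0.03)
  expect_gte(got$p_value, 1 / (crit$n_permutations + 1))
})

test_that("permutation test is reproducible, null-calibrated and guarded", {
  tab <- tiny_cohort(n_control = 5, n_hd = 5, timepoints = 3, n_metab = 1,
                     seed = 3, hd_shift = 0)
  crit <- marker_filter_criteria(n_permutations = 400,
                                 permutation_seed = 11)
  a <- permutation_auc_test(tab$values[, 1], tab, crit)
  b <- permutation_auc_test(tab$values[, 1], tab, crit)
  expect_identical(a, b)
  expect_gt(a$p_value, 0.05)  # no effect injected
  # identical values in both groups -> p ~ 1
  v <- rep(c(2, 3, 4), 10)
  flat <- permutation_auc_test(
    c(v, rep(NA, nrow(tab$values) - 30))[seq_len(nrow(tab$values))],
    tab, crit)
  expect_gt(flat$p_value, 0.5)
  # too few distinct sheep relabellings
  tab_small <- tiny_cohort(n_control = 2, n_hd = 2, timepoints = 3)
  expect_error(permutation_auc_test(tab_small$values[, 1], tab_small,
                                    crit), "exact enumeration")
})

test_that("logistic IRLS reproduces closed forms and glm", {
  # intercept-only on 14 cases / 10 controls
  X <- matrix(numeric(0), nrow = 24, ncol = 0)
  y <- rep(c(1, 0), c(14, 10))
  fit <- fit_logistic(X, y)
  expect_equal(unname(fit$coefficients[1]), log(14 / 10),
               tolerance = 1e-7)
  # single binary feature: coefficient = 2x2 log odds ratio
  xb <- rep(c(1, 1, 0, 0), c(8, 6, 4, 12))
  yb <- rep(c(1, 0, 1, 0), c(8, 6, 4, 12))
  fit2 <- fit_logistic(matrix(xb, ncol = 1), yb)
  expect_equal(unname(fit2$coefficients[2]),
               log((8 * 12) / (6 * 4)), tolerance = 1e-6)
  # duplicating every sample leaves coefficients unchanged
  fit2b <- fit_logistic(matrix(c(xb, xb), ncol = 1), c(yb, yb))
  expect_equal(fit2$coefficients, fit2b$coefficients, tolerance = 1e-7)
  # agreement with glm on a random two-feature problem
  set.seed(21)
  Xr <- matrix(rnorm(200), 100, 2)
  yr <- rbinom(100, 1, plogis(0.3 + Xr %*% c(1, -0.5)))
  fit3 <- fit_logistic(Xr, yr)
  ref <- glm.fit(cbind(1, Xr), yr, family = binomial())
  expect_equal(unname(fit3$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
  expect_false(fit3$separation)
  expect_error(fit_logistic(matrix(c(1, NA), 2, 1), c(0, 1)),
               "non-finite")
})

test_that("separated data are ridge-stabilized and flagged", {
  X <- matrix(c(-2, -1, -0.5, 0.5, 1, 2), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(X, y)
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients)))
  p <- predict_logistic(fit, X)
  expect_true(all(p[y == 1] > 0.5) && all(p[y == 0] < 0.5))
})

test_that("LOSOCV produces one held-out prediction per study sample", {
  tab <- tiny_cohort(n_control = 4, n_hd = 4, timepoints = 5, n_metab = 3,
                     seed = 14, hd_shift = 0)
  preds <- losocv_predictions(tab, c("M1", "M2"))
  is_study <- tab$samples$sample_type == "study"
  expect_equal(nrow(preds), sum(is_study))
  expect_setequal(preds$sample_id, tab$samples$sample_id[is_study])
  expect_equal(anyDuplicated(preds$sample_id), 0L)
  expect_true(all(preds$predicted_probability >= 0 &
                    preds$predicted_probability <= 1))
  expect_error(losocv_predictions(tab, character(0)), "non-empty")
  expect_error(losocv_predictions(tab, "nope"), "nope")
})

test_that("a strongly shifted marker yields near-perfect cross-validated AUC", {
  # 3-SD genotype shift on the log scale, full-size cohort
  tab <- tiny_cohort(n_control = 10, n_hd = 14, timepoints = 13,
                     n_metab = 2, seed = 4, hd_shift = 0.6)
  preds <- losocv_predictions(tab, "M1")
  a <- auc(preds$predicted_probability,
           as.integer(preds$genotype == "HD"))
  expect_gt(a, 0.95)
})

test_that("cross-validation never flatters null markers", {
  # pooled leave-one-sheep-out predictions are conservative under the
  # null: each fold's training prevalence shifts its intercept against
  # the held-out animal's class, so the pooled AUC sits below 0.5
  # (never above chance), and approaches 0.5 only with signal
  aucs <- vapply(1:10, function(seed) {
    tab <- tiny_cohort(n_control = 7, n_hd = 7, timepoints = 5,
                       n_metab = 2, seed = seed, hd_shift = 0)
    preds <- losocv_predictions(tab, c("M1", "M2"))
    auc(preds$predicted_probability, as.integer(preds$genotype == "HD"))
  }, numeric(1))
  expect_lt(mean(aucs), 0.55)
  expect_gt(mean(aucs), 0.05)
})

test_that("training-fold imputation fills missing markers without leakage", {
  tab <- tiny_cohort(n_control = 3, n_hd = 3, timepoints = 4, n_metab = 2,
                     seed = 6)
  v <- tab$values
  miss_row <- which(tab$samples$sheep_id == "C1")[1]
  v[miss_row, 1] <- NA
  tab <- conc_table(tab$samples, tab$annotation, v)
  preds <- losocv_predictions(tab, c("M1", "M2"))
  expect_equal(nrow(preds),
               sum(tab$samples$sample_type == "study"))
  expect_false(anyNA(preds$predicted_probability))
})

test_that("stepwise search finds the informative marker first and only improves", {
  first_hits <- vapply(1:5, function(seed) {
    tab <- tiny_cohort(n_control = 5, n_hd = 5, timepoints = 6,
                       n_metab = 6, seed = seed, hd_shift = 0)
    v <- tab$values
    hd <- tab$samples$sample_type == "study" &
      tab$samples$genotype == "HD"
    v[hd, 1] <- v[hd, 1] * exp(0.8)  # M1 informative, M2..M6 null
    tab <- conc_table(tab$samples, tab$annotation, v)
    panels <- stepwise_build_panels(tab, paste0("M", 1:6))
    panels[[1]]$markers[1]
  }, character(1))
  expect_true(mean(first_hits == "M1") >= 0.8)
})

test_that("stepwise AUC sequences increase strictly and all-null panels stay small", {
  tab <- tiny_cohort(n_control = 5, n_hd = 5, timepoints = 5, n_metab = 5,
                     seed = 31, hd_shift = 0)
  panels <- stepwise_build_panels(tab, paste0("M", 1:5), max_size = 4)
  final <- panels[[length(panels)]]
  expect_true(all(diff(final$step_auc) > 0) || length(final$step_auc) == 1)
  expect_equal(final$final_auc, final$step_auc[length(final$step_auc)])
  expect_equal(length(panels), length(final$markers))
  expect_lte(length(final$markers), 4L)
  expect_error(stepwise_build_panels(tab, character(0)), "non-empty")
})

test_that("sensitivity at fixed specificity follows the threshold sweep", {
  preds <- data.frame(
    predicted_probability = c(seq(0.05, 0.50, by = 0.05),
                              c(0.45, 0.55, 0.65, 0.75, 0.85)),
    genotype = rep(c("control", "HD"), c(10, 5)))
  got <- sensitivity_at_specificity(preds, 0.90)
  # threshold 0.50 gives 1 false positive (specificity 0.9) and 4 true
  # positives; 0.55 reaches the same sensitivity at specificity 1
  expect_equal(got$sensitivity, 0.8)
  expect_true(got$threshold %in% c(0.50, 0.55))
  expect_gte(got$specificity, 0.9)
  # perfect classifier
  perfect <- data.frame(predicted_probability = c(0.1, 0.2, 0.8, 0.9),
                        genotype = c("control", "control", "HD", "HD"))
  expect_equal(sensitivity_at_specificity(perfect)$sensitivity, 1.0)
  # constant scores: no threshold reaches 90% specificity with positives
  const <- data.frame(predicted_probability = rep(0.5, 10),
                      genotype = rep(c("control", "HD"), 5))
  expect_equal(sensitivity_at_specificity(const)$sensitivity, 0)
  expect_error(sensitivity_at_specificity(perfect, 1.2), "\\(0, 1\\)")
})

test_that("ROC curve area equals the Mann-Whitney AUC", {
  set.seed(13)
  preds <- data.frame(
    predicted_probability = round(runif(60), 2),
    genotype = sample(rep(c("control", "HD"), 30)))
  roc <- roc_curve(preds)
  expect_equal(roc$auc,
               auc(preds$predicted_probability,
                   as.integer(preds$genotype == "HD")),
               tolerance = 1e-12)
  expect_true(all(diff(roc$sensitivity) >= 0))
})

test_that("per-bin AUC matches a pair-count oracle and flags missing classes", {
  set.seed(17)
  preds <- data.frame(
    predicted_probability = runif(40),
    genotype = sample(rep(c("control", "HD"), 20)),
    phase_bin = rep(c(-2, 0, 2, 4), each = 10))
  got <- auc_by_timepoint(preds)
  for (b in c(-2, 0, 2, 4)) {
    p <- preds[preds$phase_bin == b, ]
    expect_equal(got$auc[got$phase_bin == b],
                 auc_pair_oracle(p$predicted_probability,
                                 as.integer(p$genotype == "HD")))
  }
  # a bin with one class reports NA, not silence
  preds$genotype[preds$phase_bin == 4] <- "control"
  got2 <- auc_by_timepoint(preds)
  expect_true(is.na(got2$auc[got2$phase_bin == 4]))
  expect_equal(nrow(got2), 4L)
})

test_that("sheep-level classification thresholds the median CV probability", {
  preds <- data.frame(
    sheep_id = rep(c("A", "B"), each = 3),
    genotype = rep(c("control", "HD"), each = 3),
    predicted_probability = c(0.1, 0.2, 0.9, 0.6, 0.7, 0.2))
  cls <- sheep_level_classification(preds, threshold = 0.5)
  expect_equal(cls$median_probability, c(0.2, 0.6))
  expect_equal(cls$predicted_hd, c(FALSE, TRUE))
})
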