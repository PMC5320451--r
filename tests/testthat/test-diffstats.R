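test_that("sequential-SS ANOVA matches the explicit projection oracle", {
  # constructed 2-genotype x 2-time x 4-sheep design
  design <- data.frame(
    genotype = rep(c("control", "HD"), each = 4),
    sampling_index = rep(0:1, 4),
    sheep_id = rep(c("A", "B", "C", "D"), each = 2))
  set.seed(11)
  values <- exp(rnorm(8, log(10), 0.3))
  got <- fit_metabolite_anova(values, design)
  want <- anova_projection_oracle(values, design)
  expect_equal(got, want, tolerance = 1e-10)

  # randomized small designs, with and without missing values
  for (seed in 1:10) {
    set.seed(seed)
    n_c <- sample(2:3, 1); n_h <- sample(2:3, 1); tps <- sample(3:4, 1)
    d <- data.frame(
      genotype = rep(rep(c("control", "HD"), c(n_c, n_h)), each = tps),
      sampling_index = rep(seq_len(tps) - 1, n_c + n_h),
      sheep_id = rep(paste0("S", seq_len(n_c + n_h)), each = tps))
    v <- exp(rnorm(nrow(d), log(5), 0.4))
    if (seed %% 2 == 0) v[sample(length(v), 2)] <- NA
    expect_equal(fit_metabolite_anova(v, d),
                 anova_projection_oracle(v, d), tolerance = 1e-10)
  }
})

test_that("ANOVA p-values are location invariant and errors are raised", {
  design <- data.frame(
    genotype = rep(c("control", "HD"), each = 6),
    sampling_index = rep(0:2, 4),
    sheep_id = rep(c("A", "B", "C", "D"), each = 3))
  set.seed(2)
  values <- rnorm(12, 10)
  expect_equal(fit_metabolite_anova(values, design),
               fit_metabolite_anova(values + 123.4, design),
               tolerance = 1e-8)
  one_sheep <- design
  one_sheep$sheep_id[one_sheep$genotype == "HD"] <- "Z"
  expect_error(fit_metabolite_anova(values, one_sheep), ">= 2 sheep")
})

test_that("null p-values are approximately uniform", {
  design <- data.frame(
    genotype = rep(c("control", "HD"), c(4, 4) * 4)[1:32],
    sampling_index = rep(0:3, 8),
    sheep_id = rep(paste0("S", 1:8), each = 4))
  design$genotype <- rep(c("control", "HD"), each = 16)
  set.seed(5)
  p <- replicate(150, {
    fit_metabolite_anova(rnorm(32, 10), design)[["p_genotype"]]
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(p) - 0.5), 0.1)
})

test_that("BH adjustment equals the hand step-up computation and the oracle", {
  expect_equal(bh_fdr(c(0.005, 0.04, 0.9)), c(0.015, 0.06, 0.9))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  for (seed in 1:25) {
    set.seed(seed)
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_equal(order(q[order(p)]), seq_along(p))  # order preserved
  }
})

test_that("group means and SEMs match hand formulas and a recount", {
  design <- data.frame(genotype = c("control", "control", "control",
                                    "HD", "HD"),
                       sheep_id = c("A", "A", "B", "C", "D"))
  got <- group_means_sem(c(1, 2, 3, 7, 7), design)
  expect_equal(unname(got["control_mean"]), 2)
  expect_equal(unname(got["control_sem"]), sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(unname(got["control_sem"]), 0.5774, tolerance = 1e-4)
  expect_equal(unname(got["hd_sem"]), 0)
  expect_error(group_means_sem(c(1, 2, 3, 7, NA), design), "HD")
  # pooled recount on random fixtures with missing cells
  for (seed in 1:5) {
    set.seed(seed)
    d <- data.frame(genotype = sample(rep(c("control", "HD"), 10)),
                    sheep_id = paste0("S", rep(1:5, 4)))
    v <- rnorm(20, 50, 5)
    v[sample(20, 3)] <- NA
    got <- group_means_sem(v, d)
    hd <- v[d$genotype == "HD" & !is.na(v)]
    expect_equal(unname(got["hd_mean"]), mean(hd))
    expect_equal(unname(got["hd_sem"]), sd(hd) / sqrt(length(hd)))
  }
})

test_that("significance tabulation counts classes, directions and ties", {
  rows <- data.frame(
    abbreviation = c("a", "b", "c", "d"),
    class = c("amino_acid", "amino_acid", "PC_aa", "PC_aa"),
    fdr_genotype = c(0.01, 0.2, 0.04, 0.05),  # 0.05 is NOT < 0.05
    control_mean = c(1, 1, 2, 2), hd_mean = c(2, 5, 2, 9))
  s <- summarize_significance(rows)
  total <- s[s$class == "total", ]
  expect_equal(total$n_significant, 2L)
  expect_equal(total$n_increased, 1L)
  expect_equal(total$n_tied_direction, 1L)  # c: equal stored means
  expect_equal(s$n_significant[s$class == "amino_acid"], 1L)
  expect_equal(sum(s$n_increased + s$n_decreased + s$n_tied_direction ==
                     s$n_significant), nrow(s))
  empty <- summarize_significance(rows[0, ])
  expect_equal(empty$n_significant, 0L)
})

test_that("urea-cycle ratios computed from the reference means go the published way", {
  ref <- load_reference_screen()
  m <- function(a, col) ref[[col]][ref$abbreviation == a]
  cit_arg_hd <- m("Cit", "hd_mean") / m("Arg", "hd_mean")
  cit_arg_c <- m("Cit", "control_mean") / m("Arg", "control_mean")
  expect_equal(cit_arg_hd, 1.082, tolerance = 1e-3)
  expect_equal(cit_arg_c, 0.972, tolerance = 1e-3)
  expect_gt(cit_arg_hd, cit_arg_c)   # higher Cit/Arg in HD
  expect_gt(m("Cit", "hd_mean") / m("Orn", "hd_mean"),
            m("Cit", "control_mean") / m("Orn", "control_mean"))
  expect_lt(m("Orn", "hd_mean") / m("Arg", "hd_mean"),
            m("Orn", "control_mean") / m("Arg", "control_mean"))
})

test_that("ratio series handle zeros, missing and reciprocals", {
  tab <- tiny_cohort(n_metab = 3)
  ann <- as.data.frame(tab$annotation)
  ann$abbreviation <- c("Cit", "Arg", "Orn")
  colnames(tab$values) <- ann$abbreviation
  tab <- conc_table(tab$samples,
                    `class<-`(ann, c("metabolite_annotation", "data.frame")),
                    tab$values)
  r <- compute_ratio_series(tab, ratio_definition("Cit/Arg", "Cit", "Arg"))
  expect_equal(r, tab$values[, "Cit"] / tab$values[, "Arg"],
               ignore_attr = TRUE)
  inv <- compute_ratio_series(tab, ratio_definition("Arg/Cit", "Arg", "Cit"))
  expect_equal(r * inv, rep(1, length(r)), ignore_attr = TRUE)
  # zero denominator -> missing with a warning
  v <- tab$values
  v[1, "Arg"] <- 0
  tab2 <- conc_table(tab$samples, tab$annotation, v)
  expect_warning(r2 <- compute_ratio_series(
    tab2, ratio_definition("Cit/Arg", "Cit", "Arg")), "zero denominator")
  expect_true(is.na(r2[1]))
  expect_error(ratio_definition("x", "Cit", "Cit"), "differ")
})

test_that("screening a cohort returns FDR-adjusted rows for every metabolite", {
  tab <- tiny_cohort(n_control = 3, n_hd = 3, timepoints = 5, n_metab = 4,
                     hd_shift = 0)
  res <- screen_metabolites(tab)
  expect_s3_class(res, "anova_results")
  expect_equal(nrow(res), 4L)
  expect_true(all(res$fdr_genotype >= res$p_genotype))
  expect_true(all(res$fdr_time >= res$p_time))
  expect_true(all(res$control_mean > 0))
})
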