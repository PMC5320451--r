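# Small deterministic fixtures shared across test files.

# A tiny panel annotation with easy round-number limits.
tiny_annotation <- function(n = 3) {
  metabolite_annotation(
    name = paste0("Metabolite ", seq_len(n)),
    abbreviation = paste0("M", seq_len(n)),
    metabolite_class = rep_len(c("amino_acid", "PC_aa", "sphingolipid"), n),
    lod = rep(0.01, n), lloq = rep(0.02, n), uloq = rep(1e4, n))
}

# A deterministic cohort table: n_sheep sheep split between genotypes,
# `timepoints` two-hourly samples each, plus 2 QC2 wells and 1 blank per
# plate spread over 2 plates. Values are filled from a seeded RNG.
tiny_cohort <- function(n_control = 2, n_hd = 2, timepoints = 3,
                        n_metab = 3, seed = 42, hd_shift = 0) {
  set.seed(seed)
  ann <- tiny_annotation(n_metab)
  sheep <- c(paste0("C", seq_len(n_control)), paste0("H", seq_len(n_hd)))
  geno <- rep(c("control", "HD"), c(n_control, n_hd))
  tp <- seq_len(timepoints) - 1L
  study <- data.frame(
    sample_id = paste0(rep(sheep, each = timepoints), "_",
                       rep(tp, length(sheep))),
    sheep_id = rep(sheep, each = timepoints),
    genotype = rep(geno, each = timepoints),
    clock_time = rep((15 + 2 * tp) %% 24, length(sheep)),
    sampling_index = rep(tp, length(sheep)),
    plate_id = rep_len(c("P1", "P2"), length(sheep) * timepoints),
    sample_type = "study", stringsAsFactors = FALSE)
  qc <- do.call(rbind, lapply(c("P1", "P2"), function(pl) {
    data.frame(
      sample_id = paste0(pl, c("_QC2_1", "_QC2_2", "_BL")),
      sheep_id = NA_character_, genotype = NA_character_,
      clock_time = 0, sampling_index = 0L, plate_id = pl,
      sample_type = c("QC2", "QC2", "blank"), stringsAsFactors = FALSE)
  }))
  samples <- rbind(study, qc)
  values <- matrix(exp(rnorm(nrow(samples) * n_metab, log(10), 0.2)),
                   nrow(samples), n_metab,
                   dimnames = list(samples$sample_id, ann$abbreviation))
  hd_rows <- samples$sample_type == "study" & samples$genotype == "HD"
  values[hd_rows, ] <- values[hd_rows, ] * exp(hd_shift)
  values[samples$sample_type == "blank", ] <- 0.001
  conc_table(samples, ann, values)
}

# The study-sample design of a table, as fit_metabolite_anova expects.
study_design <- function(table) {
  table$samples[table$samples$sample_type == "study", ]
}

study_values <- function(table, metabolite) {
  table$values[table$samples$sample_type == "study", metabolite]
}

# --- independent oracles ------------------------------------------------

# AUC by explicit enumeration of case-control pairs (ties count half).
auc_pair_oracle <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (x in cases) {
    for (y in controls) {
      total <- total + (x > y) + 0.5 * (x == y)
    }
  }
  total / (length(cases) * length(controls))
}

# Benjamini-Hochberg by the literal step-up definition: sort ascending,
# q_(k) = min_{j >= k} p_(j) * m / j capped at 1, back in input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (k in seq_len(m)) {
    vals <- vapply(k:m, function(j) p[ord[j]] * m / j, numeric(1))
    q_sorted[k] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Sequential (type-I) two-way ANOVA by explicit projections onto growing
# indicator-matrix column spaces; ranks and projections via SVD, so this
# path shares nothing with lm()/anova().
proj_rss <- function(X, y) {
  sv <- svd(X)
  keep <- sv$d > max(dim(X)) * max(sv$d) * .Machine$double.eps
  U <- sv$u[, keep, drop = FALSE]
  fitted <- U %*% crossprod(U, y)
  list(rss = sum((y - fitted)^2), rank = sum(keep))
}

anova_projection_oracle <- function(values, design) {
  keep <- !is.na(values)
  y <- values[keep]
  g <- factor(design$genotype[keep], levels = c("control", "HD"))
  tm <- factor(design$sampling_index[keep])
  an <- factor(design$sheep_id[keep])
  ind <- function(f) {
    out <- matrix(0, length(f), nlevels(f))
    out[cbind(seq_along(f), as.integer(f))] <- 1
    out
  }
  blocks <- list(matrix(1, length(y), 1), ind(g), ind(tm), ind(an))
  inter <- ind(g)[, rep(seq_len(nlevels(g)), nlevels(tm))] *
    ind(tm)[, rep(seq_len(nlevels(tm)), each = nlevels(g))]
  blocks[[5]] <- inter
  rss <- rank <- numeric(5)
  X <- NULL
  for (k in 1:5) {
    X <- cbind(X, blocks[[k]])
    pr <- proj_rss(X, y)
    rss[k] <- pr$rss
    rank[k] <- pr$rank
  }
  df_res <- length(y) - rank[5]
  ms_res <- rss[5] / df_res
  pval <- function(k) {
    df <- rank[k] - rank[k - 1]
    ss <- rss[k - 1] - rss[k]
    stats::pf((ss / df) / ms_res, df, df_res, lower.tail = FALSE)
  }
  c(p_genotype = pval(2), p_time = pval(3), p_interaction = pval(5))
}
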