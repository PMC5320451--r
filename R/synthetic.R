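#' Configuration of a synthetic around-the-clock cohort
#'
#' Parameterizes a simulated two-genotype sheep cohort with the
#' statistical structure the analysis assumes: per-metabolite group
#' means with two-level lognormal noise (between-sheep and within-sheep
#' multiplicative CVs), cosinor circadian structure phased to each
#' animal's dim-light melatonin onset, plate bias with QC2 repeats,
#' LOD censoring and sparse missingness.
#'
#' @param effect_table data.frame with one row per metabolite:
#'   `abbreviation`, `control_mean`, `hd_mean` (uM),
#'   `cv_between_sheep`, `cv_within_sheep`.
#' @param rhythm data.frame: `abbreviation`, `amplitude` (relative, in
#'   \[0, 1)), `peak_offset` (hours after DLMO at which the cosinor
#'   peaks).
#' @param annotation optional [metabolite_annotation()]; when `NULL`,
#'   limits are derived from the means (LOD at mean/100, LLOQ at
#'   mean/50, ULOQ at 100x mean) so that censoring is rare.
#' @param n_control,n_hd number of animals per genotype (defaults 10
#'   and 14).
#' @param timepoints two-hourly samples per sheep over the 25 h window
#'   starting 15:00 (default 13, so 15:00 recurs at the end).
#' @param dlmo_mean,dlmo_sd distribution of true melatonin onsets
#'   (hours; defaults 21.0 and 0.9).
#' @param missing_rate fraction of study cells dropped at random,
#'   default 0.012.
#' @param n_plates,qc2_per_plate plate structure (defaults 5 and 4);
#'   2 blank wells are added per plate.
#' @param plate_bias_sd lognormal sigma of the multiplicative plate
#'   bias, default 0.05.
#' @param qc2_noise_cv within-plate CV of the QC2 repeats, default
#'   0.05.
#' @param melatonin_noise_frac proportional assay noise of the
#'   melatonin profiles, default 0.10.
#' @param seed integer seed; mandatory, makes cohorts bit-reproducible.
#' @return a list with class `synthetic_config`.
#' @export
synthetic_config <- function(effect_table, rhythm = NULL,
                             annotation = NULL,
                             n_control = 10, n_hd = 14, timepoints = 13,
                             dlmo_mean = 21.0, dlmo_sd = 0.9,
                             missing_rate = 0.012, n_plates = 5,
                             qc2_per_plate = 4, plate_bias_sd = 0.05,
                             qc2_noise_cv = 0.05,
                             melatonin_noise_frac = 0.10, seed) {
  if (missing(seed)) stop("seed is mandatory")
  problems <- character(0)
  req <- c("abbreviation", "control_mean", "hd_mean",
           "cv_between_sheep", "cv_within_sheep")
  if (!all(req %in% names(effect_table))) {
    problems <- c(problems, "effect_table lacks required columns")
  } else {
    if (any(effect_table$control_mean <= 0) ||
        any(effect_table$hd_mean <= 0)) {
      problems <- c(problems, "means must be positive")
    }
    if (any(effect_table$cv_between_sheep < 0) ||
        any(effect_table$cv_within_sheep < 0)) {
      problems <- c(problems, "CVs must be non-negative")
    }
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    problems <- c(problems, "missing_rate must lie in [0, 1)")
  }
  if (n_control < 1 || n_hd < 1 || timepoints < 1) {
    problems <- c(problems, "cohort sizes must be positive")
  }
  if (is.null(rhythm)) {
    rhythm <- data.frame(abbreviation = effect_table$abbreviation,
                         amplitude = 0, peak_offset = 0,
                         stringsAsFactors = FALSE)
  }
  if (any(rhythm$amplitude < 0 | rhythm$amplitude >= 1)) {
    problems <- c(problems, "rhythm amplitudes must lie in [0, 1)")
  }
  if (length(problems) > 0L) {
    stop("invalid synthetic_config: ", paste(problems, collapse = "; "))
  }
  if (is.null(annotation)) {
    m <- pmin(effect_table$control_mean, effect_table$hd_mean)
    annotation <- metabolite_annotation(
      name = effect_table$abbreviation,
      abbreviation = effect_table$abbreviation,
      metabolite_class = if ("class" %in% names(effect_table)) {
        effect_table$class
      } else rep("PC_aa", nrow(effect_table)),
      lod = m / 100, lloq = m / 50,
      uloq = pmax(effect_table$control_mean, effect_table$hd_mean) * 100)
  }
  structure(list(effect_table = effect_table, rhythm = rhythm,
                 annotation = annotation, n_control = n_control,
                 n_hd = n_hd, timepoints = timepoints,
                 dlmo_mean = dlmo_mean, dlmo_sd = dlmo_sd,
                 missing_rate = missing_rate, n_plates = n_plates,
                 qc2_per_plate = qc2_per_plate,
                 plate_bias_sd = plate_bias_sd,
                 qc2_noise_cv = qc2_noise_cv,
                 melatonin_noise_frac = melatonin_noise_frac,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# The eight panel markers carried by the default preset.
PANEL8_MARKERS <- c("Cit", "Val", "PC aa C40:4", "PC aa C36:5",
                    "lysoPC a C17:0", "SM (OH) C24:1", "Thr", "C14:1")

#' Study-condition preset built from the packaged reference table
#'
#' Builds a [synthetic_config()] for the full 130-metabolite panel with
#' control means taken from the packaged reference screening table.
#' Total per-metabolite CVs are set so that pooled group SEMs at the
#' default cohort size approximate the published ones
#' (`cv = sem * sqrt(n_samples) / mean`, floored at 0.05; metabolites
#' whose SEM prints as 0.00 fall back to a typical CV of 0.25). One
#' eighth of the total variance is placed between sheep and the rest
#' within sheep (`cv_b = cv_total / sqrt(8)`): the emulated protocol
#' samples an age-, sex- and diet-matched flock under a constant dim
#' light routine, so circadian and assay variation dominate the
#' between-animal heterogeneity. With `effects = "panel8"`
#' (default) the eight published panel markers carry their reference HD
#' means and every other metabolite is null (HD mean = control mean);
#' with `effects = "none"` all metabolites are null. Metabolites whose
#' reference time-of-day FDR is below 0.05 get a relative cosinor
#' amplitude of 0.15 (others 0.02) with deterministically staggered peak
#' offsets.
#'
#' @param seed integer seed (mandatory).
#' @param effects `"panel8"` or `"none"`.
#' @param ... overrides passed on to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
paperlike_config <- function(seed, effects = c("panel8", "none"), ...) {
  effects <- match.arg(effects)
  ref <- load_reference_screen()
  n_samples <- 10 * 13
  cv_total <- ref$control_sem * sqrt(n_samples) / ref$control_mean
  cv_total[ref$control_sem == 0] <- 0.25  # SEM prints as 0.00
  cv_total <- pmax(cv_total, 0.05)
  hd_mean <- ref$control_mean
  if (effects == "panel8") {
    idx <- match(PANEL8_MARKERS, ref$abbreviation)
    hd_mean[idx] <- ref$hd_mean[idx]
  }
  effect_table <- data.frame(
    abbreviation = ref$abbreviation, class = ref$class,
    control_mean = ref$control_mean, hd_mean = hd_mean,
    cv_between_sheep = cv_total / sqrt(8),
    cv_within_sheep = cv_total * sqrt(7 / 8),
    stringsAsFactors = FALSE)
  rhythm <- data.frame(
    abbreviation = ref$abbreviation,
    amplitude = ifelse(ref$fdr_time < 0.05, 0.15, 0.02),
    peak_offset = (seq_len(nrow(ref)) * 7.3) %% 24,
    stringsAsFactors = FALSE)
  synthetic_config(effect_table = effect_table, rhythm = rhythm,
                   seed = seed, ...)
}

lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Generate a synthetic cohort
#'
#' Simulates the full data bundle for one cohort: the concentration
#' table (study samples plus QC2 and blank wells on each plate), hourly
#' melatonin profiles per sheep, and the ground truth needed to score
#' recovery (true DLMO per sheep, plate bias factors, per-metabolite
#' effect flags).
#'
#' Each study value is
#' `group_mean * sheep_factor * (1 + A * cos(2*pi*(t - DLMO - peak)/24))
#'  * residual * plate_bias`,
#' with lognormal sheep and residual factors of unit mean. Values below
#' the LOD are reported at LOD/2; study cells are then dropped at the
#' configured missing rate.
#'
#' @param config a [synthetic_config()].
#' @return a list with class `generated_cohort`: `concentrations` (a
#'   `conc_table`), `melatonin` (list of [melatonin_profile()]),
#'   `truth` (list: `dlmo` data.frame, `plate_factors`, `effects`
#'   data.frame with `is_shifted` flags).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  rng <- get_rng_state(); on.exit(restore_rng_state(rng))
  set.seed(config$seed)

  et <- config$effect_table
  m <- nrow(et)
  sheep <- c(sprintf("C%02d", seq_len(config$n_control)),
             sprintf("H%02d", seq_len(config$n_hd)))
  genotype <- rep(c("control", "HD"), c(config$n_control, config$n_hd))
  n_sheep <- length(sheep)
  dlmo <- stats::rnorm(n_sheep, config$dlmo_mean, config$dlmo_sd)

  tp <- seq_len(config$timepoints) - 1L
  t_unwrapped <- 15 + 2 * tp
  clock_time <- t_unwrapped %% 24

  study <- data.frame(
    sample_id = paste0(rep(sheep, each = config$timepoints), "_T",
                       sprintf("%02d", rep(tp, n_sheep))),
    sheep_id = rep(sheep, each = config$timepoints),
    genotype = rep(genotype, each = config$timepoints),
    clock_time = rep(clock_time, n_sheep),
    sampling_index = rep(tp, n_sheep),
    plate_id = NA_character_, sample_type = "study",
    stringsAsFactors = FALSE)
  n_study <- nrow(study)
  plates <- sprintf("P%d", seq_len(config$n_plates))
  study$plate_id <- sample(rep_len(plates, n_study))

  plate_factor <- stats::setNames(lognormal_factor(config$n_plates,
                                                   config$plate_bias_sd),
                                  plates)

  # between-sheep factors: one per sheep per metabolite
  sheep_factor <- matrix(NA_real_, n_sheep, m)
  for (j in seq_len(m)) {
    sheep_factor[, j] <- lognormal_factor(n_sheep, et$cv_between_sheep[j])
  }

  sheep_idx <- rep(seq_len(n_sheep), each = config$timepoints)
  t_all <- rep(t_unwrapped, n_sheep)
  geno_all <- study$genotype
  pf_all <- plate_factor[study$plate_id]
  values <- matrix(NA_real_, n_study, m,
                   dimnames = list(study$sample_id, et$abbreviation))
  for (j in seq_len(m)) {
    mu <- ifelse(geno_all == "HD", et$hd_mean[j], et$control_mean[j])
    amp <- config$rhythm$amplitude[j]
    peak <- config$rhythm$peak_offset[j]
    cosinor <- 1 + amp * cos(2 * pi * (t_all - dlmo[sheep_idx] - peak) / 24)
    resid <- lognormal_factor(n_study, et$cv_within_sheep[j])
    values[, j] <- mu * sheep_factor[cbind(sheep_idx, j)] * cosinor *
      resid * pf_all
  }
  # LOD censoring, then sparse missingness
  lod <- config$annotation$lod
  for (j in seq_len(m)) {
    below <- values[, j] < lod[j]
    values[below, j] <- lod[j] / 2
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(values)) < config$missing_rate
    values[drop] <- NA_real_
  }

  # QC2 and blank wells per plate
  qc_rows <- list(); qc_vals <- list()
  nominal <- et$control_mean
  for (pl in plates) {
    for (k in seq_len(config$qc2_per_plate)) {
      qc_rows[[length(qc_rows) + 1L]] <- data.frame(
        sample_id = paste0(pl, "_QC2_", k), sheep_id = NA_character_,
        genotype = NA_character_, clock_time = 0, sampling_index = 0L,
        plate_id = pl, sample_type = "QC2", stringsAsFactors = FALSE)
      qc_vals[[length(qc_vals) + 1L]] <-
        nominal * plate_factor[pl] * lognormal_factor(m, config$qc2_noise_cv)
    }
    for (k in 1:2) {
      qc_rows[[length(qc_rows) + 1L]] <- data.frame(
        sample_id = paste0(pl, "_BLANK_", k), sheep_id = NA_character_,
        genotype = NA_character_, clock_time = 0, sampling_index = 0L,
        plate_id = pl, sample_type = "blank", stringsAsFactors = FALSE)
      qc_vals[[length(qc_vals) + 1L]] <-
        lod / 10 * lognormal_factor(m, 0.2)
    }
  }
  qc_samples <- do.call(rbind, qc_rows)
  qc_matrix <- do.call(rbind, qc_vals)
  rownames(qc_matrix) <- qc_samples$sample_id
  colnames(qc_matrix) <- et$abbreviation

  samples <- rbind(study, qc_samples)
  all_values <- rbind(values, qc_matrix)
  table <- conc_table(samples, config$annotation, all_values)

  melatonin <- generate_melatonin(config, stats::setNames(dlmo, sheep))

  truth <- list(
    dlmo = data.frame(sheep_id = sheep, genotype = genotype,
                      dlmo = dlmo, stringsAsFactors = FALSE),
    plate_factors = plate_factor,
    effects = data.frame(abbreviation = et$abbreviation,
                         control_mean = et$control_mean,
                         hd_mean = et$hd_mean,
                         is_shifted = et$hd_mean != et$control_mean,
                         stringsAsFactors = FALSE))
  structure(list(concentrations = table, melatonin = melatonin,
                 truth = truth, config = config),
            class = "generated_cohort")
}

#' Generate hourly melatonin profiles with a known onset
#'
#' Each profile is a daytime baseline, a piecewise-linear nocturnal
#' onset ramp positioned so that the 25%-of-peak upward crossing falls
#' exactly at the animal's true DLMO, a nocturnal plateau, and a morning
#' offset ramp. Proportional assay noise is added and values below the
#' assay detection floor (3.9 pg/ml) are reported at the floor.
#'
#' @param config a [synthetic_config()]; `melatonin_noise_frac` sets the
#'   proportional noise SD (0 gives noiseless profiles).
#' @param true_dlmo named numeric vector of onsets (clock hours) per
#'   sheep, within the sampled window.
#' @return a list of [melatonin_profile()] objects.
#' @export
generate_melatonin <- function(config, true_dlmo) {
  hours <- 14:38  # hourly samples over 25 h, unwrapped
  floor_pgml <- 3.9
  ramp <- 3; plateau_hours <- 9.5; off_ramp <- 2
  if (any(true_dlmo < min(hours) + 1 | true_dlmo > max(hours) - 6)) {
    stop("true DLMO outside the sampled window")
  }
  lapply(names(true_dlmo), function(sh) {
    dlmo <- true_dlmo[[sh]]
    peak <- 100 * lognormal_factor(1, 0.2)
    base <- floor_pgml
    f <- (0.25 * peak - base) / (peak - base)
    t_on <- dlmo - f * ramp
    t_full <- t_on + ramp
    t_off <- t_full + plateau_hours
    v <- vapply(hours, function(t) {
      if (t < t_on) base
      else if (t < t_full) base + (peak - base) * (t - t_on) / ramp
      else if (t < t_off) peak
      else if (t < t_off + off_ramp) {
        peak - (peak - base) * (t - t_off) / off_ramp
      } else base
    }, numeric(1))
    if (config$melatonin_noise_frac > 0) {
      v <- v + stats::rnorm(length(v), 0, config$melatonin_noise_frac * v)
    }
    v <- pmax(v, floor_pgml)
    melatonin_profile(sh, hours %% 24, v)
  })
}

#' Synthetic kit fixture with 183 candidates and 53 constructed violators
#'
#' Builds a full-structure concentration table of 183 candidate
#' metabolites: the 130-metabolite reference panel plus 53 extra
#' candidates, each constructed to violate exactly one QC exclusion
#' rule -- 30 with more than 25% of study values below the LOD, 18 with
#' a QC2 coefficient of variation far above 30%, and 5 with blank wells
#' above the LOD. Applying [exclude_metabolites()] with default
#' thresholds therefore retains exactly the 130 panel metabolites, whose
#' class composition matches the kit (20 amino acids, 10 biogenic amines
#' including taurine, 11 acylcarnitines, 13 lysoPC, 62 PC, 14
#' sphingolipids).
#'
#' The out-of-range violators are enforced deterministically by setting
#' each violator's LOD just above its own 30th-percentile study value;
#' the QC2 violators get alternating +/-80% deviations around the
#' nominal QC2 value (CV 0.8, plate means untouched); the blank
#' violators get blank wells at three times their LOD.
#'
#' @param seed integer seed; the packaged fixture convention is seed
#'   101.
#' @return a list: `table` (the 183-candidate `conc_table`), `truth`
#'   (data.frame mapping each candidate to its constructed violation:
#'   `"none"`, `"out_of_range_fraction"`, `"qc2_cv"`,
#'   `"blank_out_of_range"`).
#' @export
generate_kit_fixture <- function(seed = 101L) {
  ref <- load_reference_screen()
  n_extra <- 53
  extra_class <- rep(c("acylcarnitine", "biogenic_amine", "PC_aa",
                       "amino_acid", "sphingolipid"),
                     c(26, 11, 14, 1, 1))
  extra <- data.frame(
    abbreviation = sprintf("XCAND%02d", seq_len(n_extra)),
    class = extra_class,
    control_mean = rep_len(c(0.5, 2, 10, 0.1, 5), n_extra),
    stringsAsFactors = FALSE)
  effect_table <- rbind(
    data.frame(abbreviation = ref$abbreviation, class = ref$class,
               control_mean = ref$control_mean,
               hd_mean = ref$control_mean,
               cv_between_sheep = 0.1, cv_within_sheep = 0.15,
               stringsAsFactors = FALSE),
    data.frame(abbreviation = extra$abbreviation, class = extra$class,
               control_mean = extra$control_mean,
               hd_mean = extra$control_mean,
               cv_between_sheep = 0.1, cv_within_sheep = 0.15,
               stringsAsFactors = FALSE))
  config <- synthetic_config(effect_table = effect_table,
                             missing_rate = 0, seed = seed)
  cohort <- generate_cohort(config)
  table <- cohort$concentrations

  violation <- rep("none", nrow(effect_table))
  names(violation) <- effect_table$abbreviation
  extra_idx <- 130L + seq_len(n_extra)
  violation[extra_idx[1:30]] <- "out_of_range_fraction"
  violation[extra_idx[31:48]] <- "qc2_cv"
  violation[extra_idx[49:53]] <- "blank_out_of_range"

  ann <- table$annotation
  is_study <- table$samples$sample_type == "study"
  is_qc2 <- table$samples$sample_type == "QC2"
  is_blank <- table$samples$sample_type == "blank"
  for (j in which(violation == "out_of_range_fraction")) {
    v <- sort(table$values[is_study, j])
    k <- ceiling(0.30 * length(v))
    ann$lod[j] <- (v[k] + v[k + 1]) / 2
    ann$lloq[j] <- ann$lod[j] * 1.1
    ann$uloq[j] <- max(v) * 100
  }
  for (j in which(violation == "qc2_cv")) {
    n_qc2 <- sum(is_qc2)
    nominal <- effect_table$control_mean[j]
    table$values[is_qc2, j] <- nominal *
      (1 + 0.8 * rep_len(c(-1, 1), n_qc2))
  }
  for (j in which(violation == "blank_out_of_range")) {
    table$values[is_blank, j] <- ann$lod[j] * 3
  }
  fixed <- conc_table(table$samples,
                      `class<-`(ann, c("metabolite_annotation",
                                       "data.frame")),
                      table$values)
  list(table = fixed,
       truth = data.frame(abbreviation = effect_table$abbreviation,
                          violation = unname(violation),
                          stringsAsFactors = FALSE))
}
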