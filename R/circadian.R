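#' Unwrap clock times into a monotone hour axis
#'
#' Clock times restart at midnight; over a 25 h sampling window the same
#' clock time can occur twice. Given times in sampling order, adds 24 h at
#' every wrap so the result is strictly increasing.
#'
#' @param clock_time numeric vector of clock times in \[0, 24), in
#'   sampling order.
#' @return numeric vector of unwrapped hours (first element unchanged).
#' @export
unwrap_clock_time <- function(clock_time) {
  if (length(clock_time) == 0L) return(clock_time)
  wraps <- cumsum(c(0, diff(clock_time) < 0))
  clock_time + 24 * wraps
}

#' Construct a melatonin profile
#'
#' @param sheep_id animal identifier.
#' @param times hourly clock times (h) covering the sampling window; must
#'   be strictly increasing after unwrapping across midnight.
#' @param concentrations plasma melatonin in pg/ml (`NA` = missing);
#'   at least 12 non-missing points are required.
#' @return a list with class `melatonin_profile`; `times_unwrapped` holds
#'   the monotone hour axis.
#' @export
melatonin_profile <- function(sheep_id, times, concentrations) {
  if (length(times) != length(concentrations)) {
    stop("times and concentrations differ in length")
  }
  tu <- unwrap_clock_time(times)
  if (any(diff(tu) <= 0)) {
    stop("times must be strictly increasing after unwrapping")
  }
  if (sum(!is.na(concentrations)) < 12L) {
    stop("melatonin profile needs >= 12 non-missing points")
  }
  structure(list(sheep_id = as.character(sheep_id), times = times,
                 times_unwrapped = tu,
                 concentrations = as.numeric(concentrations)),
            class = "melatonin_profile")
}

#' Dim-light melatonin onset by the 25%-threshold method
#'
#' The onset threshold is referenced to the animal's own profile:
#' `threshold_fraction` times the maximum observed concentration. DLMO is
#' the time of the first upward crossing of that threshold, located by
#' linear interpolation between the bracketing hourly samples. Missing
#' points are skipped; the crossing is searched on observed points only.
#'
#' @param profile a [melatonin_profile()].
#' @param threshold_fraction fraction of the observed peak, default 0.25.
#' @return DLMO as an unwrapped clock time in hours.
#' @export
compute_dlmo <- function(profile, threshold_fraction = 0.25) {
  stopifnot(inherits(profile, "melatonin_profile"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must lie in (0, 1)")
  }
  keep <- !is.na(profile$concentrations)
  tt <- profile$times_unwrapped[keep]
  cc <- profile$concentrations[keep]
  thr <- threshold_fraction * max(cc)
  above <- cc >= thr
  if (!any(above) || max(cc) <= 0) {
    stop("onset not identifiable: profile never exceeds threshold")
  }
  first_above <- which(above)[1]
  if (first_above == 1L) {
    stop("onset not identifiable: profile starts above threshold")
  }
  i <- first_above - 1L
  tt[i] + (thr - cc[i]) / (cc[first_above] - cc[i]) *
    (tt[first_above] - tt[i])
}

#' Compute per-sheep phase alignments from melatonin profiles
#'
#' @param profiles list of [melatonin_profile()] objects.
#' @param threshold_fraction passed to [compute_dlmo()].
#' @return data.frame with columns `sheep_id`, `dlmo` (unwrapped clock
#'   hours).
#' @export
compute_alignments <- function(profiles, threshold_fraction = 0.25) {
  data.frame(
    sheep_id = vapply(profiles, function(p) p$sheep_id, character(1)),
    dlmo = vapply(profiles, compute_dlmo, numeric(1),
                  threshold_fraction = threshold_fraction),
    stringsAsFactors = FALSE)
}

#' Align a concentration table to each animal's DLMO
#'
#' Adds a `phase_offset` column to the sample metadata: the sample's
#' unwrapped clock time minus the animal's DLMO, so that DLMO sits at
#' offset zero. Unwrapping is performed per sheep in `sampling_index`
#' order, so the second visit to the same clock time lands 24 h later.
#' Sample count and within-sheep ordering are unchanged; QC and blank
#' wells get `NA` offsets.
#'
#' @param table a `conc_table`.
#' @param alignments data.frame with `sheep_id` and `dlmo` columns (as
#'   produced by [compute_alignments()]).
#' @return the `conc_table` with `phase_offset` (hours relative to DLMO)
#'   and `time_unwrapped` added to its `samples`.
#' @export
align_to_dlmo <- function(table, alignments) {
  stopifnot(inherits(table, "conc_table"))
  s <- table$samples
  is_study <- s$sample_type == "study"
  sheep <- unique(s$sheep_id[is_study])
  missing_sheep <- setdiff(sheep, alignments$sheep_id)
  if (length(missing_sheep) > 0L) {
    stop("no DLMO alignment for sheep: ",
         paste(missing_sheep, collapse = ", "))
  }
  s$time_unwrapped <- NA_real_
  s$phase_offset <- NA_real_
  for (sh in sheep) {
    rows <- which(is_study & s$sheep_id == sh)
    ord <- order(s$sampling_index[rows])
    tu <- unwrap_clock_time(s$clock_time[rows][ord])
    s$time_unwrapped[rows[ord]] <- tu
    dlmo <- alignments$dlmo[match(sh, alignments$sheep_id)]
    s$phase_offset[rows[ord]] <- tu - dlmo
  }
  conc_table(s, table$annotation, table$values)
}

#' Snap phase offsets to 2-hour bins
#'
#' Cross-sheep summaries relative to DLMO use offsets snapped to the
#' nearest bin on a regular grid.
#'
#' @param offset numeric phase offsets in hours.
#' @param width bin width in hours, default 2.
#' @return numeric vector of bin centres.
#' @export
phase_bin <- function(offset, width = 2) {
  width * round(offset / width)
}
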