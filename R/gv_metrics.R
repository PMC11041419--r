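#' Per-patient time-in-patterns composition
#'
#' Tallies the pattern label of every kept window per patient and expresses
#' the tally as percentages of that patient's windows — the package's central
#' patient summary. Compositions sum to 100 by construction.
#'
#' @param labeled tibble with columns `patient_id` and `pattern` (labels in
#'   1..k), one row per window.
#' @param k number of patterns.
#' @return tibble with `patient_id`, `n_windows`, and columns
#'   `tip_1 .. tip_k` (percentages).
#' @export
time_in_patterns <- function(labeled, k) {
  stopifnot(all(labeled$pattern %in% seq_len(k)))
  split_pid <- split(labeled$pattern, labeled$patient_id)
  rows <- lapply(names(split_pid), function(pid) {
    lab <- split_pid[[pid]]
    comp <- 100 * tabulate(lab, nbins = k) / length(lab)
    out <- tibble::tibble(patient_id = pid, n_windows = length(lab))
    out[paste0("tip_", seq_len(k))] <- as.list(comp)
    out
  })
  dplyr::bind_rows(rows)
}

tip_matrix <- function(tip) {
  cols <- grep("^tip_", names(tip), value = TRUE)
  m <- as.matrix(tip[, cols])
  rownames(m) <- tip$patient_id
  m
}

#' Time in range over the consensus glucose bands
#'
#' Share of measurements falling in the five bands delimited by 3, 3.9, 10
#' and 13.9 mmol/L: `v <= 3`, `3 < v <= 3.9`, `3.9 < v <= 10`,
#' `10 < v < 13.9`, `v >= 13.9`. Measurement-weighted (each sample counts
#' once), which matches near-uniform 15-minute sampling.
#'
#' @param values numeric vector of glucose values (mmol/L), nonempty.
#' @param breakpoints the four band edges (default `c(3, 3.9, 10, 13.9)`).
#' @return named numeric vector of 5 percentages summing to 100.
#' @export
time_in_range <- function(values, breakpoints = c(3, 3.9, 10, 13.9)) {
  stopifnot(length(values) >= 1, length(breakpoints) == 4)
  b <- breakpoints
  counts <- c(
    sum(values <= b[1]),
    sum(values > b[1] & values <= b[2]),
    sum(values > b[2] & values <= b[3]),
    sum(values > b[3] & values < b[4]),
    sum(values >= b[4])
  )
  stats::setNames(100 * counts / length(values),
                  c("tir_low", "tir_below", "tir_target", "tir_high",
                    "tir_very_high"))
}

#' Per-patient glycemic summary
#'
#' Mean, sample SD (n - 1 denominator), coefficient of variation
#' (COV = SD / mean), and the five time-in-range percentages, per patient.
#' Patients with a single sample get `NA` SD/COV with a warning.
#'
#' @param data CGM tibble (`patient_id`, `time`, `glucose`).
#' @param breakpoints passed to [time_in_range()].
#' @return tibble with one row per patient: `patient_id`, `n_samples`,
#'   `mean_glucose`, `sd_glucose`, `cov`, `tir_low`, `tir_below`,
#'   `tir_target`, `tir_high`, `tir_very_high`.
#' @export
glycemic_summary <- function(data, breakpoints = c(3, 3.9, 10, 13.9)) {
  rows <- lapply(split(data$glucose, data$patient_id), function(v) {
    if (length(v) < 2) {
      warning("patient with a single sample: sd and cov are NA")
      s <- NA_real_
    } else s <- stats::sd(v)
    tir <- time_in_range(v, breakpoints)
    tibble::tibble(n_samples = length(v), mean_glucose = mean(v),
                   sd_glucose = s, cov = s / mean(v), !!!as.list(tir))
  })
  dplyr::bind_rows(rows, .id = "patient_id")
}

#' Fulfillment of the consensus glycemic targets
#'
#' Three recommended-target flags per patient: time in the 3.9-10 mmol/L
#' target band strictly above 70%, COV strictly below 0.36, and HbA1c
#' strictly below 58 mmol/mol (NA when HbA1c is unavailable).
#'
#' @param summary output of [glycemic_summary()].
#' @param hba1c optional numeric vector of HbA1c values (mmol/mol) aligned
#'   with `summary` rows, or a data frame with `patient_id` and `hba1c`.
#' @return `summary` with logical columns `tir_ok`, `cov_ok`, `hba1c_ok`.
#' @export
target_fulfillment <- function(summary, hba1c = NULL) {
  if (is.data.frame(hba1c)) {
    hba1c <- hba1c$hba1c[match(summary$patient_id, hba1c$patient_id)]
  }
  summary$tir_ok <- summary$tir_target > 70
  summary$cov_ok <- summary$cov < 0.36
  summary$hba1c_ok <- if (is.null(hba1c)) NA else hba1c < 58
  summary
}

#' Hourly distribution of pattern occurrence
#'
#' Diurnal view of the extracted patterns: for each clock hour (of the
#' window midpoint), the share of windows in that hour carrying each pattern
#' label. Columns (hours) with at least one window sum to 100 over patterns;
#' hours with no windows are absent. An optional grouping (e.g. patient
#' cluster) yields one table per group.
#'
#' @param labeled tibble with columns `pattern` and `start_hour` (and
#'   optionally the grouping column).
#' @param k number of patterns.
#' @param group optional name of a grouping column in `labeled`.
#' @return tibble with `group` (if requested), `pattern`, `hour`, `share`
#'   (percent of that hour's windows).
#' @export
pattern_occurrence_by_hour <- function(labeled, k, group = NULL) {
  one <- function(df, gname = NULL) {
    tab <- table(factor(df$pattern, levels = seq_len(k)), df$start_hour)
    share <- 100 * prop.table(tab, margin = 2)
    out <- tibble::tibble(
      pattern = as.integer(rep(rownames(share), ncol(share))),
      hour = as.integer(rep(colnames(share), each = nrow(share))),
      share = as.numeric(share)
    )
    if (!is.null(gname)) out <- tibble::add_column(out, group = gname,
                                                   .before = 1)
    out
  }
  if (is.null(group)) return(one(labeled))
  dplyr::bind_rows(lapply(split(labeled, labeled[[group]]),
                          function(df) one(df, df[[group]][1])))
}
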