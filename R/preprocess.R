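#' Windowing configuration
#'
#' Defines how a deduplicated CGM trace is sliced into overlapping
#' fixed-duration windows. The default search grid used elsewhere is
#' durations \{120, 150, 180\} minutes by overlaps \{0, 25, 50, 75\}%.
#' The stride is `duration * (1 - overlap_pct/100)` minutes; fractional
#' strides (e.g. 112.5 min for 150 min at 25%) are allowed — window bounds
#' are real-valued instants that minute-resolution samples are compared
#' against.
#'
#' @param duration window length in minutes (> 0).
#' @param overlap_pct percentage overlap between consecutive windows, in
#'   \[0, 100).
#' @param min_density minimum average measurement rate (measurements per
#'   hour) for a window to be kept by [density_filter()]; default 4.
#' @param anchor `"first_sample"` (default) anchors the window grid at each
#'   patient's first timestamp; `"midnight"` at the midnight preceding it.
#' @param emit_partial also emit trailing windows that extend past the last
#'   sample (default `FALSE`: only windows wholly inside the observation
#'   span are emitted, except that a span shorter than one duration still
#'   yields its single covering window).
#' @return an object of class `windowing_config`.
#' @export
windowing_config <- function(duration = 150, overlap_pct = 50,
                             min_density = 4, anchor = c("first_sample", "midnight"),
                             emit_partial = FALSE) {
  anchor <- match.arg(anchor)
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.numeric(overlap_pct) || overlap_pct < 0 || overlap_pct >= 100)
    stop("overlap_pct must lie in [0, 100)")
  if (min_density <= 0) stop("min_density must be > 0")
  stride <- duration * (1 - overlap_pct / 100)
  if (stride <= 0) stop("windowing stride must be a positive number of minutes")
  structure(
    list(duration = duration, overlap_pct = overlap_pct, stride = stride,
         min_density = min_density, anchor = anchor,
         emit_partial = emit_partial),
    class = "windowing_config"
  )
}

#' @export
print.windowing_config <- function(x, ...) {
  cat(sprintf("windowing: %g min, %g%% overlap (stride %g min), >= %g meas/h, anchor %s\n",
              x$duration, x$overlap_pct, x$stride, x$min_density, x$anchor))
  invisible(x)
}

#' Slice CGM traces into overlapping windows
#'
#' Windows start at the anchor instant and every `stride` minutes after it;
#' each covers the half-open interval `[start, start + duration)` so that a
#' sample falling exactly on a boundary belongs to the next grid position.
#' Samples are carried as (offset, value) pairs; windows are not resampled,
#' since DTW consumes the ordered value sequence directly and tolerates
#' uneven spacing (see [resample_windows()] for the optional regular-grid
#' variant). Empty grid positions are not emitted.
#'
#' @param data deduplicated CGM tibble (see [dedup_minute_median()]).
#' @param config a [windowing_config()].
#' @return tibble with one row per window: `patient_id`, `window_id`,
#'   `start` (POSIXct), `duration`, `start_hour` (0-23, clock hour of the
#'   window midpoint), `n_samples`, and list-columns `offsets` (minutes since
#'   start) and `values` (mmol/L).
#' @export
extract_windows <- function(data, config = windowing_config()) {
  stopifnot(inherits(config, "windowing_config"))
  res <- lapply(split(data, data$patient_id), extract_windows_one, config)
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(patient_id = character(), window_id = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          duration = numeric(), start_hour = integer(),
                          n_samples = integer(), offsets = list(),
                          values = list())
  }
  out
}

extract_windows_one <- function(series, config) {
  series <- dplyr::arrange(series, .data$time)
  t0 <- series$time[1]
  if (config$anchor == "midnight") t0 <- trunc(t0, units = "days")
  tm <- as.numeric(difftime(series$time, t0, units = "mins"))
  last <- tm[length(tm)]
  dur <- config$duration
  stride <- config$stride
  max_complete <- last - dur
  starts <- if (max_complete >= 0) seq(0, max_complete + 1e-9, by = stride) else numeric()
  if (config$emit_partial) {
    extra_from <- if (length(starts)) starts[length(starts)] + stride else 0
    if (extra_from <= last + 1e-9)
      starts <- c(starts, seq(extra_from, last + 1e-9, by = stride))
  } else if (!length(starts)) {
    starts <- 0  # span shorter than one duration: single covering window
  }
  eps <- 1e-9
  rows <- lapply(starts, function(s) {
    lo <- findInterval(s - eps, tm) + 1L
    hi <- findInterval(s + dur - eps, tm)
    if (hi < lo) return(NULL)
    idx <- lo:hi
    mid <- t0 + (s + dur / 2) * 60
    tibble::tibble(
      patient_id = series$patient_id[1],
      start = t0 + s * 60,
      duration = dur,
      start_hour = as.integer(format(mid, "%H", tz = "UTC")),
      n_samples = length(idx),
      offsets = list(tm[idx] - s),
      values = list(series$glucose[idx])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out))
    out <- tibble::add_column(
      out, window_id = paste0(out$patient_id, "#", seq_len(nrow(out))),
      .after = "patient_id")
  out
}

#' Discard windows with insufficient measurement density
#'
#' A window is kept iff its average measurement rate,
#' `60 * n_samples / duration` measurements per hour, is at least
#' `min_density`; strictly sparser windows are discarded. At the default
#' threshold of 4/h, a 150-minute window needs at least 10 samples.
#'
#' @param windows window tibble from [extract_windows()].
#' @param min_density measurements per hour (> 0).
#' @return list with `kept` (filtered window tibble) and `n_discarded`.
#' @export
density_filter <- function(windows, min_density = 4) {
  stopifnot(min_density > 0)
  rate <- 60 * windows$n_samples / windows$duration
  keep <- rate >= min_density
  list(kept = windows[keep, , drop = FALSE], n_discarded = sum(!keep))
}

#' Resample windows to a regular offset grid by linear interpolation
#'
#' Optional sensitivity-analysis helper: maps each window's (offset, value)
#' samples onto offsets `0, step, ..., duration - step` by linear
#' interpolation (constant extrapolation at the edges). Not applied by
#' default anywhere in the pipeline.
#'
#' @param windows window tibble.
#' @param step grid step in minutes (default 15).
#' @return the window tibble with `offsets`/`values` replaced by the regular
#'   grid and `n_samples` updated.
#' @export
resample_windows <- function(windows, step = 15) {
  grid_for <- function(dur) seq(0, dur - step, by = step)
  windows$values <- Map(function(off, val, dur) {
    g <- grid_for(dur)
    if (length(val) == 1) return(rep(val, length(g)))
    stats::approx(off, val, xout = g, rule = 2)$y
  }, windows$offsets, windows$values, windows$duration)
  windows$offsets <- lapply(windows$duration, grid_for)
  windows$n_samples <- lengths(windows$values)
  windows
}

#' Flatten windows to a long data frame (one row per sample)
#'
#' The persistable form: columns `patient_id, window_id, start, duration,
#' start_hour, offset, value`. [windows_from_df()] reverses it.
#'
#' @param windows window tibble.
#' @return long tibble.
#' @export
windows_to_df <- function(windows) {
  tidyr::unnest(
    dplyr::mutate(windows,
                  start = format(.data$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                  offset = .data$offsets, value = .data$values,
                  offsets = NULL, values = NULL, n_samples = NULL),
    c("offset", "value")
  )
}

#' Rebuild a window tibble from its long persisted form
#'
#' @param df long tibble as written by [windows_to_df()].
#' @return window tibble as produced by [extract_windows()].
#' @export
windows_from_df <- function(df) {
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$patient_id, .data$window_id, .data$start,
                    .data$duration, .data$start_hour),
    n_samples = dplyr::n(),
    offsets = list(.data$offset), values = list(.data$value),
    .groups = "drop"
  )
  out$start <- as.POSIXct(out$start, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out$start_hour <- as.integer(out$start_hour)
  dplyr::arrange(out, .data$patient_id, .data$start)
}
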