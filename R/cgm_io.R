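# mg/dL per mmol/L of glucose (molar mass 180.16 g/mol).
MGDL_PER_MMOLL <- 18.016

#' Convert glucose concentrations between mg/dL and mmol/L
#'
#' @param x numeric vector of glucose values.
#' @param from,to `"mmol_l"` or `"mg_dl"`. Conversion uses the factor
#'   18.016 mg/dL per mmol/L.
#' @return numeric vector in the `to` unit.
#' @export
convert_glucose <- function(x, from = c("mg_dl", "mmol_l"),
                            to = c("mmol_l", "mg_dl")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(x)
  if (from == "mg_dl") x / MGDL_PER_MMOLL else x * MGDL_PER_MMOLL
}

# Try a set of timestamp layouts; returns POSIXct (UTC) with NA where no
# layout parses. Timezone-naive stamps are taken as local clock time and
# stored in UTC so arithmetic is DST-free.
parse_timestamps <- function(x) {
  x <- trimws(as.character(x))
  fmts <- c(
    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M:%OS",
    "%Y-%m-%d %H:%M", "%d-%m-%Y %H:%M", "%d/%m/%Y %H:%M",
    "%m/%d/%Y %I:%M %p"
  )
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  todo <- !is.na(x) & nzchar(x)
  for (f in fmts) {
    if (!any(todo)) break
    p <- as.POSIXct(x[todo], format = f, tz = "UTC")
    hit <- !is.na(p)
    idx <- which(todo)[hit]
    out[idx] <- p[hit]
    todo[idx] <- FALSE
  }
  out
}

new_cgm_tbl <- function(patient_id, time, glucose) {
  tibble::tibble(
    patient_id = as.character(patient_id),
    time = time,
    glucose = as.numeric(glucose)
  )
}

#' Read CGM traces from CSV
#'
#' Reads continuous glucose monitoring data in either a canonical long layout
#' (`patient_id,timestamp,glucose[,unit]`) or a LibreView-style flash-monitor
#' export (columns `Device Timestamp`, `Record Type`, and
#' `Historic Glucose mmol/L` / `mg/dL`). All values are converted to mmol/L.
#' Rows with an unparseable timestamp or a non-positive / missing glucose are
#' dropped and tallied in a drop report attached to the result (see
#' [drop_report()]). The result is *not* deduplicated; see
#' [dedup_minute_median()].
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"libreview"`.
#' @param unit `"auto"`, `"mmol_l"`, or `"mg_dl"`. For the long dialect,
#'   `"auto"` uses a per-row `unit` column when present, otherwise guesses
#'   from the value scale (median > 30 is read as mg/dL). For LibreView the
#'   unit is taken from the glucose column header.
#' @param include_scans for the LibreView dialect, also keep scan-glucose
#'   rows (record type 1) alongside historic rows (record type 0). The
#'   source device's export mixes record types and the upstream handling is
#'   ambiguous, so this is an explicit flag (default `FALSE`).
#' @param patient_id fallback patient id for LibreView exports without a
#'   serial-number column (defaults to the file name).
#' @return a tibble with columns `patient_id`, `time` (POSIXct, minute or
#'   finer resolution), `glucose` (mmol/L), ordered by patient then time,
#'   with a `drop_report` attribute.
#' @export
read_cgm_csv <- function(path, dialect = c("long", "libreview"),
                         unit = c("auto", "mmol_l", "mg_dl"),
                         include_scans = FALSE, patient_id = NULL) {
  dialect <- match.arg(dialect)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("CGM file not found: ", path)
  if (dialect == "long") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    required <- c("patient_id", "timestamp", "glucose")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols))
      stop("CGM CSV is missing required column(s): ",
           paste(missing_cols, collapse = ", "))
    if (nrow(df) == 0) {
      warning("CGM file contains a header but no rows")
      out <- new_cgm_tbl(character(), as.POSIXct(character(), tz = "UTC"),
                         numeric())
      attr(out, "drop_report") <- list(n_rows = 0L, n_dropped = 0L,
                                       n_bad_timestamp = 0L,
                                       n_bad_glucose = 0L)
      return(out)
    }
    times <- parse_timestamps(df$timestamp)
    glucose <- suppressWarnings(as.numeric(df$glucose))
    row_unit <- if (unit == "auto" && "unit" %in% names(df)) {
      tolower(df$unit)
    } else if (unit == "auto") {
      med <- stats::median(glucose, na.rm = TRUE)
      rep(if (isTRUE(med > 30)) "mg_dl" else "mmol_l", nrow(df))
    } else {
      rep(unit, nrow(df))
    }
    glucose <- ifelse(row_unit %in% c("mg_dl", "mg/dl", "mgdl"),
                      glucose / MGDL_PER_MMOLL, glucose)
    pid <- df$patient_id
  } else {
    raw <- readLines(path, warn = FALSE)
    hdr <- grep("Device Timestamp", raw, fixed = TRUE)[1]
    if (is.na(hdr)) stop("LibreView CSV is missing required column: Device Timestamp")
    df <- utils::read.csv(path, skip = hdr - 1, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
    gcol_mmol <- grep("^Historic Glucose mmol/L$", names(df), value = TRUE)
    gcol_mgdl <- grep("^Historic Glucose mg/dL$", names(df), value = TRUE)
    if (!length(gcol_mmol) && !length(gcol_mgdl))
      stop("LibreView CSV is missing required column: Historic Glucose mmol/L (or mg/dL)")
    gcol <- if (length(gcol_mmol)) gcol_mmol[1] else gcol_mgdl[1]
    scol <- sub("Historic", "Scan", gcol)
    glucose <- suppressWarnings(as.numeric(df[[gcol]]))
    if (include_scans && scol %in% names(df)) {
      scan <- suppressWarnings(as.numeric(df[[scol]]))
      glucose[is.na(glucose)] <- scan[is.na(glucose)]
    }
    if ("Record Type" %in% names(df)) {
      keep_types <- if (include_scans) c("0", "1") else "0"
      drop_type <- !(trimws(df[["Record Type"]]) %in% keep_types)
      glucose[drop_type] <- NA_real_
    }
    if (length(gcol_mgdl) && gcol == gcol_mgdl[1])
      glucose <- glucose / MGDL_PER_MMOLL
    times <- parse_timestamps(df[["Device Timestamp"]])
    pid <- if ("Serial Number" %in% names(df) && any(nzchar(df[["Serial Number"]]))) {
      df[["Serial Number"]]
    } else {
      rep(patient_id %||% basename(path), nrow(df))
    }
  }
  bad_time <- is.na(times)
  bad_glucose <- !is.finite(glucose) | glucose <= 0
  keep <- !bad_time & !bad_glucose
  out <- new_cgm_tbl(pid[keep], times[keep], glucose[keep])
  out <- dplyr::arrange(out, .data$patient_id, .data$time)
  attr(out, "drop_report") <- list(
    n_rows = length(keep),
    n_dropped = sum(!keep),
    n_bad_timestamp = sum(bad_time),
    n_bad_glucose = sum(bad_glucose & !bad_time)
  )
  out
}

#' Drop report of a CGM read
#'
#' @param x result of [read_cgm_csv()].
#' @return list with `n_rows`, `n_dropped`, `n_bad_timestamp`,
#'   `n_bad_glucose`.
#' @export
drop_report <- function(x) attr(x, "drop_report")

#' Write CGM traces to the canonical long CSV
#'
#' Columns `patient_id,timestamp,glucose`, timestamps ISO-8601 to the second,
#' glucose in mmol/L. Round-trips through [read_cgm_csv()].
#'
#' @param data CGM tibble (`patient_id`, `time`, `glucose`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(data, path) {
  df <- data.frame(
    patient_id = data$patient_id,
    timestamp = format(data$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    glucose = formatC(data$glucose, digits = 12, format = "g")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse duplicate within-minute readings to their median
#'
#' Timestamps are truncated (not rounded) to the calendar minute; whenever a
#' patient has several readings in the same minute the median is kept. This
#' also resolves daylight-saving duplicates. Idempotent.
#'
#' @param data CGM tibble (`patient_id`, `time`, `glucose`).
#' @return CGM tibble with at most one value per patient per minute, ordered
#'   by patient then time.
#' @export
dedup_minute_median <- function(data) {
  if (nrow(data) == 0) return(new_cgm_tbl(character(),
                                          as.POSIXct(character(), tz = "UTC"),
                                          numeric()))
  minute <- as.POSIXct(floor(as.numeric(data$time) / 60) * 60,
                       origin = "1970-01-01", tz = "UTC")
  out <- tibble::tibble(patient_id = data$patient_id, time = minute,
                        glucose = data$glucose)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$patient_id, .data$time),
    glucose = stats::median(.data$glucose), .groups = "drop"
  )
  dplyr::arrange(out, .data$patient_id, .data$time)
}

#' Read a per-patient clinical covariate table
#'
#' Expects one row per patient with a `patient_id` column; all other columns
#' are carried through (numeric where parseable, otherwise categorical).
#' Missing values are allowed and handled per-variable downstream.
#'
#' @param path CSV file path.
#' @return tibble, one row per patient.
#' @export
read_clinical_csv <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df))
    stop("clinical CSV is missing required column: patient_id")
  if (anyDuplicated(df$patient_id))
    stop("clinical CSV has duplicated patient_id values")
  df$patient_id <- as.character(df$patient_id)
  num_ok <- vapply(df, function(x) {
    is.numeric(x) && all(is.finite(x) | is.na(x))
  }, logical(1))
  bad <- names(df)[vapply(df, is.numeric, logical(1)) & !num_ok]
  if (length(bad))
    stop("clinical CSV has non-finite numeric values in: ",
         paste(bad, collapse = ", "))
  tibble::as_tibble(df)
}
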