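#' DTW configuration
#'
#' Settings for the dynamic time warping distance used throughout pattern
#' extraction. The defaults — L1 local cost, symmetric unit-weight step, no
#' global constraint, and *unnormalized* inputs — are deliberate: the
#' extracted glucose patterns must distinguish absolute levels (a steady
#' normoglycemic window from a steady severely hyperglycemic one), which
#' z-normalization would erase.
#'
#' @param local_cost `"abs_diff"` (L1, default) or `"squared_diff"` (squared
#'   L2) per aligned pair.
#' @param band optional Sakoe-Chiba band half-width in cells; `NULL`
#'   (default) disables the global constraint. When active it must be at
#'   least `|length(a) - length(b)|` or the alignment is infeasible.
#' @param normalize_inputs z-normalize each sequence before alignment
#'   (default `FALSE`; see above).
#' @return an object of class `dtw_config`.
#' @export
dtw_config <- function(local_cost = c("abs_diff", "squared_diff"),
                       band = NULL, normalize_inputs = FALSE) {
  local_cost <- match.arg(local_cost)
  if (!is.null(band)) {
    band <- as.integer(band)
    if (band < 0) stop("band must be a nonnegative integer (or NULL)")
  }
  structure(list(local_cost = local_cost, band = band,
                 normalize_inputs = isTRUE(normalize_inputs)),
            class = "dtw_config")
}

check_seq <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1)
    stop(name, " must be a nonempty numeric sequence")
  if (!all(is.finite(x))) stop(name, " contains non-finite values")
  as.numeric(x)
}

check_band <- function(config, na, nb) {
  if (!is.null(config$band) && config$band < abs(na - nb))
    stop(sprintf("Sakoe-Chiba band %d is infeasible for lengths %d and %d",
                 config$band, na, nb))
}

cost_code <- function(config) if (config$local_cost == "abs_diff") 1L else 2L

#' Dynamic time warping distance between two sequences
#'
#' Minimal cumulative local cost over monotone, continuity-respecting warping
#' paths from the first to the last aligned pair. Symmetric in its arguments;
#' zero iff a perfect alignment exists (in particular for `a == b`). The raw
#' cumulative cost is returned — see [dtw_distance_normalized()] for the
#' path-independent normalized variant.
#'
#' @param a,b nonempty numeric sequences (glucose values, mmol/L).
#' @param config a [dtw_config()].
#' @return a single nonnegative number.
#' @export
dtw_distance <- function(a, b, config = dtw_config()) {
  a <- check_seq(a, "a"); b <- check_seq(b, "b")
  check_band(config, length(a), length(b))
  cpp_dtw_distance(a, b, cost_code(config),
                   if (is.null(config$band)) -1L else config$band,
                   config$normalize_inputs)
}

#' Length-normalized DTW distance
#'
#' The raw cumulative cost divided by `length(a) + length(b)`, making
#' distances comparable across window lengths. Provided for sensitivity
#' checks; the pattern model uses the raw cost.
#'
#' @inheritParams dtw_distance
#' @return a single nonnegative number.
#' @export
dtw_distance_normalized <- function(a, b, config = dtw_config()) {
  dtw_distance(a, b, config) / (length(a) + length(b))
}

#' Pairwise DTW distance matrix
#'
#' Computes each unordered pair once and mirrors it; the diagonal is zero.
#'
#' @param seqs list of nonempty numeric sequences.
#' @param config a [dtw_config()].
#' @return a symmetric `length(seqs)` x `length(seqs)` matrix.
#' @export
dtw_distance_matrix <- function(seqs, config = dtw_config()) {
  stopifnot(is.list(seqs), length(seqs) >= 1)
  for (i in seq_along(seqs)) {
    seqs[[i]] <- check_seq(seqs[[i]], paste0("seqs[[", i, "]]"))
  }
  lens <- lengths(seqs)
  if (!is.null(config$band) && diff(range(lens)) > config$band)
    stop(sprintf("Sakoe-Chiba band %d is infeasible for sequence lengths %d..%d",
                 config$band, min(lens), max(lens)))
  D <- cpp_dtw_matrix(seqs, cost_code(config),
                      if (is.null(config$band)) -1L else config$band,
                      config$normalize_inputs)
  dimnames(D) <- list(names(seqs), names(seqs))
  D
}

# Cross-distances between two sequence collections (assignment path).
dtw_cross_matrix <- function(seqs_a, seqs_b, config = dtw_config()) {
  seqs_a <- lapply(seqs_a, check_seq, "sequence")
  seqs_b <- lapply(seqs_b, check_seq, "sequence")
  cpp_dtw_cross(seqs_a, seqs_b, cost_code(config),
                if (is.null(config$band)) -1L else config$band,
                config$normalize_inputs)
}

#' Write / read a square distance matrix as CSV
#'
#' Sequence ids form both the header and the first column.
#'
#' @param D symmetric matrix with dimnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_csv <- function(D, path) {
  ids <- rownames(D) %||% as.character(seq_len(nrow(D)))
  df <- data.frame(id = ids, D, check.names = FALSE)
  colnames(df) <- c("id", ids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  D <- as.matrix(df[, -1, drop = FALSE])
  rownames(D) <- df[[1]]
  storage.mode(D) <- "double"
  D
}
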