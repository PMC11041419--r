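# ---- k-medoids (PAM) on a precomputed distance matrix -----------------------

# Deterministic farthest-point ("k++"-style) seeding: the first medoid is
# drawn from `seed`, each further medoid is the point maximizing its minimal
# distance to the chosen set (ties -> lowest index).
seed_medoids <- function(D, k, seed) {
  n <- nrow(D)
  first <- with_seed(seed, sample.int(n, 1))
  med <- integer(k)
  med[1] <- first
  if (k > 1) {
    mind <- D[, first]
    for (i in 2:k) {
      mind[med[seq_len(i - 1)]] <- -Inf
      med[i] <- which.max(mind)
      mind <- pmin(mind, D[, med[i]])
    }
  }
  med
}

# One PAM run: assignment + best-swap iterations until no improving swap or
# max_iter. All swap deltas are evaluated against the cached nearest /
# second-nearest medoid distances, vectorized over candidate points.
pam_once <- function(D, k, seed, max_iter = 100) {
  n <- nrow(D)
  med <- seed_medoids(D, k, seed)
  trace <- numeric()
  for (iter in seq_len(max_iter)) {
    Dm <- D[, med, drop = FALSE]
    nearest_pos <- max.col(-Dm, ties.method = "first")
    d1 <- Dm[cbind(seq_len(n), nearest_pos)]
    trace[iter] <- sum(d1)
    if (k == n) break
    if (k == 1) {
      # single medoid: exact update, then stop if stable
      best <- which.min(colSums(D))
      if (best == med[1]) break
      med[1] <- best
      next
    }
    d2 <- apply(Dm, 1, function(r) sort(r, partial = 2)[2])
    nonmed <- setdiff(seq_len(n), med)
    Dn <- D[, nonmed, drop = FALSE]
    base_m <- pmin(Dn, d1)                    # cost if h added, nearest kept
    alt_m <- pmin(Dn, d2)                     # cost if own medoid removed
    base <- colSums(base_m)
    grp <- factor(nearest_pos, levels = seq_len(k))
    adj_r <- rowsum(alt_m - base_m, grp)      # rows only for nonempty clusters
    adj <- matrix(0, k, length(nonmed))
    adj[as.integer(rownames(adj_r)), ] <- adj_r
    cost <- sweep(adj, 2, base, "+")          # cost[m, h] after swapping
    best_idx <- arrayInd(which.min(cost), dim(cost))
    if (cost[best_idx] < sum(d1) - 1e-12) {
      med[best_idx[1]] <- nonmed[best_idx[2]]
    } else break
  }
  Dm <- D[, med, drop = FALSE]
  nearest_pos <- max.col(-Dm, ties.method = "first")
  d1 <- Dm[cbind(seq_len(n), nearest_pos)]
  list(medoid_indices = med, labels = nearest_pos,
       total_within_distance = sum(d1), trace = trace)
}

pam_dist <- function(D, k, seed = 1, restarts = 5, max_iter = 100) {
  n <- nrow(D)
  if (k < 1 || k > n) stop("k must lie in 1..n_windows (k=", k, ", n=", n, ")")
  if (k >= 2 && all(D < 1e-12))
    stop("degenerate data: all windows are identical (zero DTW distances), ",
         "cannot split into k >= 2 patterns")
  if (k == n) {
    return(list(medoid_indices = seq_len(n), labels = seq_len(n),
                total_within_distance = 0, trace = 0))
  }
  best <- NULL
  for (s in derive_seeds(seed, restarts)) {
    fit <- pam_once(D, k, s, max_iter)
    if (is.null(best) ||
        fit$total_within_distance < best$total_within_distance - 1e-12)
      best <- fit
  }
  best
}

# ---- pattern model ----------------------------------------------------------

windows_values <- function(windows) {
  if (is.data.frame(windows)) windows$values else windows
}

#' Extract k glycemic-variability patterns by DTW k-medoids
#'
#' Clusters glucose windows with PAM-style k-medoids on the pairwise DTW
#' distance matrix: deterministic farthest-point seeding from `seed`,
#' iterative best-swap until no improvement (max 100 iterations), best of
#' `restarts` seedings by total within-cluster distance. Patterns are
#' relabeled so that mean glucose of the medoids increases with the pattern
#' number — pattern 1 is the lowest-glucose pattern, pattern k the highest.
#'
#' @param windows window tibble from [extract_windows()] (or a bare list of
#'   numeric sequences).
#' @param k number of patterns, `1 <= k <=` number of windows.
#' @param dtw a [dtw_config()].
#' @param seed integer seed for medoid initialisation.
#' @param restarts number of independent seedings (default 5).
#' @param max_iter swap-iteration cap per run (default 100).
#' @param D optional precomputed DTW distance matrix (skips recomputation).
#' @return an object of class `pattern_model`: `k`, `medoids` (list of value
#'   sequences, ordered by label), `medoid_indices`, `labels` (1..k per
#'   training window), `total_within_distance`, `trace` (objective per
#'   iteration of the winning run), `pattern_order`, `dtw`, `duration`,
#'   `n_windows`.
#' @export
cluster_windows <- function(windows, k, dtw = dtw_config(), seed = 1,
                            restarts = 5, max_iter = 100, D = NULL) {
  vals <- windows_values(windows)
  n <- length(vals)
  if (n < 1) stop("no windows to cluster")
  if (k > n) stop("k must lie in 1..n_windows (k=", k, ", n=", n, ")")
  if (is.null(D)) D <- dtw_distance_matrix(vals, dtw)
  fit <- pam_dist(D, k, seed = seed, restarts = restarts, max_iter = max_iter)
  med_means <- vapply(fit$medoid_indices, function(i) mean(vals[[i]]), 0)
  ord <- order(med_means)                     # internal id -> rank
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(
    k = k,
    medoids = vals[fit$medoid_indices[ord]],
    medoid_indices = fit$medoid_indices[ord],
    labels = relabel[fit$labels],
    total_within_distance = fit$total_within_distance,
    trace = fit$trace,
    pattern_order = relabel,
    dtw = dtw,
    duration = if (is.data.frame(windows)) windows$duration[1] else NA_real_,
    n_windows = n
  ), class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf("DTW k-medoids pattern model: k = %d over %d windows\n",
              x$k, x$n_windows))
  cat(sprintf("  total within-cluster DTW distance: %.4g\n",
              x$total_within_distance))
  means <- vapply(x$medoids, mean, 0)
  cat("  medoid mean glucose (mmol/L): ",
      paste(sprintf("%.1f", means), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- cluster validity indices ----------------------------------------------

#' Internal cluster validity indices on a distance matrix
#'
#' Computes the four indices used for hyperparameter selection. Higher is
#' better for silhouette and Calinski-Harabasz; lower is better for COP and
#' the modified Davies-Bouldin (DB*).
#'
#' * silhouette: mean over points of `(b - a) / max(a, b)` with `a` the mean
#'   distance to the point's own cluster (excluding itself) and `b` the
#'   smallest mean distance to another cluster; singletons score 0.
#' * Calinski-Harabasz: `(B / (k - 1)) / (W / (N - k))` with
#'   `W = sum d(x, own medoid)^2` and
#'   `B = sum_c n_c d(medoid_c, global medoid)^2`, the global medoid being
#'   the point minimizing total distance to all points.
#' * COP: `(1/N) sum_c n_c * mean_{x in c} d(x, medoid_c) /
#'   min_{y not in c} max_{x in c} d(x, y)`.
#' * DB*: `(1/k) sum_i max_{j != i}(S_i + S_j) / min_{j != i}
#'   d(medoid_i, medoid_j)` with `S_i` the mean member-to-medoid distance.
#'
#' @param D symmetric distance matrix.
#' @param labels integer cluster labels (>= 2 nonempty clusters).
#' @param medoid_indices medoid row index per cluster, aligned with the sorted
#'   unique labels.
#' @return named list: `silhouette`, `calinski_harabasz`, `cop`,
#'   `davies_bouldin_star`.
#' @export
compute_cvis <- function(D, labels, medoid_indices) {
  n <- nrow(D)
  labs <- sort(unique(labels))
  k <- length(labs)
  if (k < 2) stop("compute_cvis needs at least 2 nonempty clusters")
  stopifnot(length(medoid_indices) == k, length(labels) == n)
  sizes <- as.integer(table(factor(labels, levels = labs)))

  # silhouette
  grp <- factor(labels, levels = labs)
  sums <- rowsum(D, grp)                      # k x n: total distance from each cluster (D symmetric)
  means <- sums / sizes
  own <- match(labels, labs)
  a <- (sums[cbind(own, seq_len(n))]) / pmax(sizes[own] - 1, 1)
  other <- means
  other[cbind(own, seq_len(n))] <- Inf
  b <- apply(other, 2, min)
  s <- ifelse(sizes[own] == 1, 0,
              ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0))
  sil <- mean(s)

  d_to_medoid <- D[cbind(seq_len(n), medoid_indices[own])]

  # Calinski-Harabasz (medoid-based)
  gm <- which.min(rowSums(D))
  W <- sum(d_to_medoid^2)
  B <- sum(sizes * D[medoid_indices, gm]^2)
  ch <- if (W > 0 && k > 1 && n > k) (B / (k - 1)) / (W / (n - k)) else NaN
  if (!is.finite(ch)) warning("Calinski-Harabasz undefined (zero within-cluster scatter)")

  # COP
  cop_terms <- vapply(seq_len(k), function(ci) {
    members <- which(labels == labs[ci])
    outside <- which(labels != labs[ci])
    intra <- mean(d_to_medoid[members])
    sep <- min(apply(D[members, outside, drop = FALSE], 2, max))
    if (sep == 0) return(NaN)
    sizes[ci] * intra / sep
  }, 0)
  cop <- sum(cop_terms) / n
  if (!is.finite(cop)) warning("COP undefined (zero cluster separation)")

  # modified Davies-Bouldin (DB*)
  S <- vapply(seq_len(k), function(ci) mean(d_to_medoid[labels == labs[ci]]), 0)
  Dmed <- D[medoid_indices, medoid_indices, drop = FALSE]
  db_terms <- vapply(seq_len(k), function(i) {
    num <- max(S[i] + S[-i])
    den <- min(Dmed[i, -i])
    if (den == 0) return(NaN)
    num / den
  }, 0)
  dbs <- mean(db_terms)
  if (!is.finite(dbs)) warning("DB* undefined (coincident medoids)")

  list(silhouette = sil, calinski_harabasz = ch, cop = cop,
       davies_bouldin_star = dbs)
}

# ---- hyperparameter grid search ---------------------------------------------

#' Grid search over window duration and overlap
#'
#' For each (duration, overlap) combination: windows all traces, applies the
#' density filter, optionally subsamples a validation set of windows, fits
#' k-medoids at `k_fixed`, and computes the four cluster validity indices.
#' Configurations are ranked per index (higher better for silhouette and
#' Calinski-Harabasz, lower better for COP and DB*) and the winner is the
#' best mean rank; ties go to the shorter duration, then the lower overlap.
#'
#' @param data deduplicated CGM tibble.
#' @param durations window durations in minutes (default 120, 150, 180).
#' @param overlaps overlap percentages (default 0, 25, 50, 75).
#' @param k_fixed number of patterns used during the search (default 6).
#' @param dtw a [dtw_config()].
#' @param seed integer seed (subsampling and medoid initialisation).
#' @param min_density density-filter threshold, measurements/hour.
#' @param subsample maximum number of windows retained as the validation
#'   set per configuration (`Inf` to disable; default 500).
#' @param restarts PAM restarts per configuration.
#' @return list with `best` (the winning [windowing_config()]) and `report`
#'   (tibble, one row per configuration: indices, ranks, `n_windows`).
#' @export
grid_search <- function(data, durations = c(120, 150, 180),
                        overlaps = c(0, 25, 50, 75), k_fixed = 6,
                        dtw = dtw_config(), seed = 1, min_density = 4,
                        subsample = 500, restarts = 5) {
  grid <- expand.grid(overlap = sort(overlaps), duration = sort(durations))
  grid <- grid[order(grid$duration, grid$overlap), ]
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    dur <- grid$duration[i]; ov <- grid$overlap[i]
    cfg <- windowing_config(duration = dur, overlap_pct = ov,
                            min_density = min_density)
    wins <- density_filter(extract_windows(data, cfg), min_density)$kept
    if (nrow(wins) < k_fixed) {
      warning(sprintf("grid config (%g min, %g%%) yields %d windows < k = %d; skipped",
                      dur, ov, nrow(wins), k_fixed))
      next
    }
    if (nrow(wins) > subsample) {
      idx <- with_seed(seeds[i], sort(sample.int(nrow(wins), subsample)))
      wins <- wins[idx, ]
    }
    D <- dtw_distance_matrix(wins$values, dtw)
    fit <- pam_dist(D, k_fixed, seed = seeds[i], restarts = restarts)
    cvi <- compute_cvis(D, fit$labels, fit$medoid_indices)
    rows[[i]] <- tibble::tibble(
      duration = dur, overlap = ov, k = k_fixed,
      silhouette = cvi$silhouette, calinski_harabasz = cvi$calinski_harabasz,
      cop = cvi$cop, davies_bouldin_star = cvi$davies_bouldin_star,
      total_within_distance = fit$total_within_distance,
      n_windows = nrow(wins)
    )
  }
  report <- dplyr::bind_rows(rows)
  if (nrow(report) == 0) stop("all grid configurations were skipped")
  report$rank_silhouette <- rank(-report$silhouette, ties.method = "min")
  report$rank_calinski_harabasz <- rank(-report$calinski_harabasz, ties.method = "min")
  report$rank_cop <- rank(report$cop, ties.method = "min")
  report$rank_davies_bouldin_star <- rank(report$davies_bouldin_star, ties.method = "min")
  report$mean_rank <- rowMeans(report[, c("rank_silhouette", "rank_calinski_harabasz",
                                          "rank_cop", "rank_davies_bouldin_star")])
  best_row <- which.min(report$mean_rank)  # rows ordered duration, overlap: tie rule
  best <- windowing_config(duration = report$duration[best_row],
                           overlap_pct = report$overlap[best_row],
                           min_density = min_density)
  list(best = best, report = report)
}

# ---- elbow selection of k ---------------------------------------------------

#' Choose the number of patterns by the elbow of the within-distance curve
#'
#' Fits [cluster_windows()] for each k in `k_range` and picks the k with the
#' maximal discrete second difference `W(k-1) - 2 W(k) + W(k+1)` of the total
#' within-cluster distance (the sharpest bend); endpoints are excluded and
#' ties go to the smaller k. A flat (linear) curve has no elbow: the smallest
#' interior k is returned with a warning.
#'
#' @param windows window tibble (or list of sequences).
#' @param k_range candidate pattern counts, at least 3 values (default 3:8).
#' @param dtw a [dtw_config()].
#' @param seed,restarts,max_iter passed to the k-medoids fits.
#' @return list with `k_star`, `curve` (tibble `k`,
#'   `total_within_distance`), and `second_difference` (interior k only).
#' @export
elbow_select_k <- function(windows, k_range = 3:8, dtw = dtw_config(),
                           seed = 1, restarts = 5, max_iter = 100) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3)
    stop("k_range must contain at least 3 values (second difference undefined)")
  vals <- windows_values(windows)
  if (length(vals) < max(k_range))
    stop("need at least max(k_range) windows")
  D <- dtw_distance_matrix(vals, dtw)
  W <- vapply(seq_along(k_range), function(i) {
    pam_dist(D, k_range[i], seed = derive_seeds(seed, length(k_range))[i],
             restarts = restarts, max_iter = max_iter)$total_within_distance
  }, 0)
  interior <- 2:(length(k_range) - 1)
  s2 <- W[interior - 1] - 2 * W[interior] + W[interior + 1]
  if (diff(range(s2)) < 1e-9 * max(1, max(abs(s2))))
    warning("within-distance curve is flat: no distinct elbow; returning smallest interior k")
  k_star <- k_range[interior[which.max(s2)]]  # which.max: first max -> smaller k
  list(k_star = k_star,
       curve = tibble::tibble(k = k_range, total_within_distance = W),
       second_difference = stats::setNames(s2, k_range[interior]))
}

# ---- assignment and envelopes -----------------------------------------------

#' Assign windows to the nearest pattern medoid
#'
#' External-validation path: new windows (which must have passed the same
#' density filter) are labeled with the DTW-nearest medoid of a trained
#' model; ties go to the lowest pattern label.
#'
#' @param model a `pattern_model`.
#' @param windows window tibble or list of sequences.
#' @return integer labels in 1..k, with the DTW distance to the winning
#'   medoid in attribute `"distance"`.
#' @export
assign_windows <- function(model, windows) {
  vals <- windows_values(windows)
  D <- dtw_cross_matrix(vals, model$medoids, model$dtw)
  lab <- max.col(-D, ties.method = "first")
  structure(lab, distance = D[cbind(seq_along(lab), lab)])
}

#' Per-pattern percentile envelopes and TIR-band coverage
#'
#' For each pattern, computes the pointwise lower/upper percentile envelope
#' and the median trend of its assigned windows on a common offset grid
#' (15-minute steps from 0 to duration - 15); each window contributes the
#' sample nearest to each grid offset. Also reports each pattern's scalar
#' glucose range against the time-in-range bands delimited by 3, 3.9, 10 and
#' 13.9 mmol/L.
#'
#' @param model a `pattern_model`.
#' @param windows window tibble (or list of sequences).
#' @param labels pattern label per window; computed with [assign_windows()]
#'   when omitted.
#' @param percentiles lower/upper envelope percentiles (default 20, 80);
#'   linear-interpolation (type 7) quantiles.
#' @param step grid step in minutes (default 15).
#' @return list with `envelopes` (tibble `pattern`, `offset`, `lower`,
#'   `median`, `upper`) and `bands` (tibble `pattern`, `env_min`, `env_max`,
#'   `bands_spanned`, `within_target`).
#' @export
pattern_range_summary <- function(model, windows, labels = NULL,
                                  percentiles = c(20, 80), step = 15) {
  vals <- windows_values(windows)
  if (is.null(labels)) labels <- assign_windows(model, windows)
  dur <- model$duration
  if (is.na(dur)) {
    dur <- if (is.data.frame(windows)) windows$duration[1] else
      step * max(lengths(vals))
  }
  grid <- seq(0, dur - step, by = step)
  offs <- if (is.data.frame(windows)) windows$offsets else
    lapply(vals, function(v) (seq_along(v) - 1) * step)
  # window x grid matrix of nearest-offset samples
  M <- t(mapply(function(off, val) {
    idx <- vapply(grid, function(g) which.min(abs(off - g)), 0L)
    val[idx]
  }, offs, vals))
  env_rows <- list(); band_rows <- list()
  probs <- sort(percentiles) / 100
  for (p in seq_len(model$k)) {
    rows <- which(labels == p)
    if (!length(rows)) {
      warning("pattern ", p, " has no assigned windows; band omitted")
      next
    }
    sub <- M[rows, , drop = FALSE]
    lower <- apply(sub, 2, quantile, probs = probs[1], type = 7, names = FALSE)
    upper <- apply(sub, 2, quantile, probs = probs[2], type = 7, names = FALSE)
    med <- apply(sub, 2, median)
    env_rows[[length(env_rows) + 1]] <- tibble::tibble(
      pattern = p, offset = grid, lower = lower, median = med, upper = upper)
    brk <- c(-Inf, 3, 3.9, 10, 13.9, Inf)
    band_names <- c("<=3", "3-3.9", "3.9-10", "10-13.9", ">=13.9")
    spanned <- band_names[unique(findInterval(c(lower, upper), brk,
                                              left.open = TRUE))]
    band_rows[[length(band_rows) + 1]] <- tibble::tibble(
      pattern = p, env_min = min(lower), env_max = max(upper),
      bands_spanned = paste(spanned, collapse = ","),
      within_target = min(lower) > 3.9 && max(upper) <= 10)
  }
  list(envelopes = dplyr::bind_rows(env_rows),
       bands = dplyr::bind_rows(band_rows))
}

# ---- persistence ------------------------------------------------------------

#' Save / load a pattern model as JSON
#'
#' Persists the medoid sequences and every hyperparameter needed to assign
#' new windows; round-trips through [read_pattern_model()].
#'
#' @param model a `pattern_model`.
#' @param path JSON file path.
#' @return `path` (write) or the model (read).
#' @export
write_pattern_model <- function(model, path) {
  obj <- list(
    format = "gvpatterns/pattern_model",
    version = as.character(utils::packageVersion("gvpatterns")),
    k = model$k,
    medoids = model$medoids,
    medoid_indices = model$medoid_indices,
    total_within_distance = model$total_within_distance,
    pattern_order = model$pattern_order,
    duration = model$duration,
    n_windows = model$n_windows,
    dtw = list(local_cost = model$dtw$local_cost,
               band = model$dtw$band,
               normalize_inputs = model$dtw$normalize_inputs)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pattern_model
#' @export
read_pattern_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  medoids <- if (is.matrix(obj$medoids)) {
    lapply(seq_len(nrow(obj$medoids)), function(i) as.numeric(obj$medoids[i, ]))
  } else {
    lapply(obj$medoids, as.numeric)
  }
  structure(list(
    k = obj$k,
    medoids = medoids,
    medoid_indices = obj$medoid_indices,
    labels = NULL,
    total_within_distance = obj$total_within_distance,
    trace = NULL,
    pattern_order = obj$pattern_order,
    dtw = dtw_config(local_cost = obj$dtw$local_cost,
                     band = obj$dtw$band,
                     normalize_inputs = isTRUE(obj$dtw$normalize_inputs)),
    duration = obj$duration %||% NA_real_,
    n_windows = obj$n_windows
  ), class = "pattern_model")
}
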