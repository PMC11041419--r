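# ---- distances for percentage compositions ----------------------------------

#' Distance between two percentage compositions
#'
#' Time-in-patterns vectors are compositional (nonnegative, constant sum
#' 100), so patient-to-patient dissimilarity uses a distance suited to
#' percentage data rather than the plain Euclidean metric. The default is
#' the Hellinger distance
#' `(1/sqrt(2)) * || sqrt(p/100) - sqrt(q/100) ||_2`, bounded in \[0, 1\]
#' and tolerant of zero shares. Alternatives: Bray-Curtis, Aitchison (with
#' multiplicative zero replacement, delta = half the smallest positive
#' share), and Euclidean on the raw percentages.
#'
#' @param p,q numeric compositions of equal length, entries >= 0, each
#'   summing to 100 (within 1e-6).
#' @param method `"hellinger"` (default), `"bray_curtis"`, `"aitchison"`, or
#'   `"euclidean"`.
#' @return a single nonnegative number.
#' @export
percentage_distance <- function(p, q, method = c("hellinger", "bray_curtis",
                                                 "aitchison", "euclidean")) {
  method <- match.arg(method)
  if (length(p) != length(q)) stop("compositions must have equal length")
  if (any(p < 0) || any(q < 0)) stop("compositions must be nonnegative")
  if (abs(sum(p) - 100) > 1e-6 || abs(sum(q) - 100) > 1e-6)
    stop("compositions must sum to 100")
  switch(method,
    hellinger = sqrt(sum((sqrt(p / 100) - sqrt(q / 100))^2)) / sqrt(2),
    bray_curtis = sum(abs(p - q)) / sum(p + q),
    aitchison = {
      clr <- function(x) {
        x <- zero_replace(x / 100)
        lx <- log(x)
        lx - mean(lx)
      }
      sqrt(sum((clr(p) - clr(q))^2))
    },
    euclidean = sqrt(sum((p - q)^2))
  )
}

# Multiplicative zero replacement for closed compositions (parts sum to 1):
# zeros become delta = 0.5 * smallest positive part, nonzero parts shrink
# proportionally so the total stays 1.
zero_replace <- function(x) {
  z <- x == 0
  if (!any(z)) return(x)
  delta <- 0.5 * min(x[!z])
  x[z] <- delta
  x[!z] <- x[!z] * (1 - delta * sum(z))
  x
}

composition_dist <- function(m, method = "hellinger") {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- percentage_distance(m[i, ], m[j, ], method)
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

# ---- hierarchical clustering of patients ------------------------------------

#' Hierarchically cluster patients on time-in-patterns compositions
#'
#' Agglomerative clustering with complete linkage on the chosen percentage
#' distance. Complete linkage guarantees monotone (non-decreasing) merge
#' heights, which the gap-based cut relies on.
#'
#' @param tip time-in-patterns table from [time_in_patterns()] (or a matrix
#'   of compositions with patient ids as row names).
#' @param method distance for percentage data, see [percentage_distance()].
#' @return an [stats::hclust] tree with attributes `distance_name` and
#'   `distance_matrix`.
#' @export
hcluster_patients <- function(tip, method = "hellinger") {
  m <- if (is.matrix(tip)) tip else tip_matrix(tip)
  if (nrow(m) < 2) stop("need at least 2 patients to cluster")
  D <- composition_dist(m, method)
  tree <- stats::hclust(stats::as.dist(D), method = "complete")
  attr(tree, "distance_name") <- method
  attr(tree, "distance_matrix") <- D
  tree
}

#' Cut a dendrogram at the largest merge-height gap
#'
#' The number of patient clusters is chosen where the difference between
#' successive merge heights (the "total within-cluster distance" increments
#' on the dendrogram) is greatest, subject to the resulting cluster count
#' lying in `[min_clusters, max_clusters]`; ties yield fewer clusters. A
#' flat height sequence has no gap: `min_clusters` is returned with a
#' warning.
#'
#' @param tree an [stats::hclust] tree (from [hcluster_patients()]).
#' @param min_clusters,max_clusters admissible range of cluster counts.
#' @return integer cluster labels (1..m) named by patient id.
#' @export
cut_by_largest_gap <- function(tree, min_clusters = 2, max_clusters = 10) {
  h <- tree$height
  n <- length(h) + 1
  if (min_clusters > max_clusters || min_clusters < 1)
    stop("invalid cluster-count constraints")
  if (min_clusters > n)
    stop("min_clusters exceeds the number of patients")
  if (length(h) < 2) return(stats::cutree(tree, k = min(min_clusters, n)))
  # cutting between merge i and merge i+1 leaves n - i clusters
  cand_i <- seq_len(length(h) - 1)
  m_for <- n - cand_i
  ok <- m_for >= min_clusters & m_for <= max_clusters
  if (!any(ok))
    stop("no admissible cut for ", min_clusters, "..", max_clusters,
         " clusters; merge heights: ", paste(signif(h, 4), collapse = ", "))
  gaps <- diff(h)[cand_i[ok]]
  if (diff(range(gaps)) < 1e-12 && max(gaps) < 1e-12) {
    warning("flat merge-height sequence: no distinct gap; returning min_clusters")
    m <- min_clusters
  } else {
    # ties -> fewer clusters = larger i; pick last argmax
    best <- which(gaps == max(gaps))
    m <- m_for[ok][best[length(best)]]
  }
  stats::cutree(tree, k = m)
}

# ---- statistical comparison across clusters ---------------------------------

#' Compare clinical variables across patient clusters
#'
#' One-way ANOVA (F test) for numeric variables and Pearson chi-square
#' without continuity correction for categorical/binary variables, on the
#' cluster-by-category contingency table. Rows missing a variable are
#' omitted from that variable's test only; p-values are two-tailed and
#' flagged significant below 0.05. Small expected cell counts trigger a
#' warning, not a method switch.
#'
#' @param clinical per-patient table with `patient_id` plus variables.
#' @param labels cluster labels named by patient id (as from
#'   [cut_by_largest_gap()]), or an unnamed vector aligned with `clinical`.
#' @return tibble: `variable`, `type` (`numeric`/`categorical`), `test`,
#'   `statistic`, `df`, `df2` (ANOVA residual df), `p_value`,
#'   `n_missing_omitted`, `n_used`, `significant`, `note`.
#' @export
compare_clusters <- function(clinical, labels) {
  if (!is.null(names(labels))) {
    matched <- names(labels)[match(clinical$patient_id, names(labels))]
    drop <- is.na(matched)
    if (any(drop))
      warning(sum(drop), " patient(s) without a cluster label dropped")
    clinical <- clinical[!drop, , drop = FALSE]
    cl <- labels[clinical$patient_id]
  } else {
    stopifnot(length(labels) == nrow(clinical))
    cl <- labels
  }
  cl <- factor(cl)
  vars <- setdiff(names(clinical), "patient_id")
  rows <- lapply(vars, function(v) {
    x <- clinical[[v]]
    miss <- is.na(x)
    xs <- x[!miss]; cls <- droplevels(cl[!miss])
    base <- tibble::tibble(variable = v,
                           type = if (is.numeric(x)) "numeric" else "categorical",
                           test = NA_character_, statistic = NA_real_,
                           df = NA_real_, df2 = NA_real_, p_value = NA_real_,
                           n_missing_omitted = sum(miss),
                           n_used = length(xs), significant = NA,
                           note = NA_character_)
    if (length(xs) == 0 || nlevels(cls) < 2) {
      base$note <- "insufficient non-missing data"
      return(base)
    }
    if (is.numeric(x)) {
      if (stats::var(xs) == 0) {
        base$test <- "anova"; base$note <- "zero variance"
        return(base)
      }
      if (length(xs) - nlevels(cls) < 1) {
        base$test <- "anova"; base$note <- "no residual degrees of freedom"
        return(base)
      }
      fit <- stats::anova(stats::lm(xs ~ cls))
      base$test <- "anova"
      base$statistic <- fit$`F value`[1]
      base$df <- fit$Df[1]; base$df2 <- fit$Df[2]
      base$p_value <- fit$`Pr(>F)`[1]
    } else {
      xf <- droplevels(factor(xs))
      if (nlevels(xf) < 2) {
        base$test <- "chi_square"; base$note <- "constant variable"
        return(base)
      }
      tab <- table(cls, xf)
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      if (any(ht$expected < 5))
        warning("variable '", v, "': expected cell counts below 5; ",
                "chi-square approximation may be poor")
      base$test <- "chi_square"
      base$statistic <- unname(ht$statistic)
      base$df <- unname(ht$parameter)
      base$p_value <- ht$p.value
    }
    base$significant <- base$p_value < 0.05
    base
  })
  dplyr::bind_rows(rows)
}

#' Compare clinical variables across tertiles of a numeric column
#'
#' Generic grouping path (e.g. duration of CGM use): splits the cohort into
#' `n_groups` approximately equal-sized groups by quantiles of `column`,
#' then runs [compare_clusters()] against those groups (excluding the
#' splitting column itself).
#'
#' @param clinical per-patient table with `patient_id`.
#' @param column name of the numeric column to split on.
#' @param n_groups number of groups (default 3).
#' @return list with `groups` (integer group per patient, named) and
#'   `stats_table` (as from [compare_clusters()]).
#' @export
group_compare <- function(clinical, column, n_groups = 3) {
  x <- clinical[[column]]
  if (!is.numeric(x)) stop("column must be numeric")
  qs <- quantile(x, probs = seq_len(n_groups - 1) / n_groups, na.rm = TRUE,
                 type = 7)
  grp <- findInterval(x, qs, left.open = TRUE) + 1L
  names(grp) <- clinical$patient_id
  keep <- setdiff(names(clinical), column)
  list(groups = grp,
       stats_table = compare_clusters(clinical[, keep, drop = FALSE], grp))
}

#' Persist a linkage tree as JSON
#'
#' Stores merge pairs (hclust convention: negative = leaf), heights, labels
#' and the distance name; round-trips through [read_linkage_json()].
#'
#' @param tree an [stats::hclust] object.
#' @param path JSON file path.
#' @return `path` (write) or the hclust object (read).
#' @export
write_linkage_json <- function(tree, path) {
  obj <- list(format = "gvpatterns/linkage",
              merge = tree$merge, height = tree$height, order = tree$order,
              labels = tree$labels,
              distance_name = attr(tree, "distance_name") %||% "unknown",
              method = tree$method)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_linkage_json
#' @export
read_linkage_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tree <- list(merge = matrix(as.integer(obj$merge), ncol = 2),
               height = as.numeric(obj$height),
               order = as.integer(obj$order),
               labels = obj$labels, method = obj$method,
               call = NULL, dist.method = obj$distance_name)
  class(tree) <- "hclust"
  attr(tree, "distance_name") <- obj$distance_name
  tree
}
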