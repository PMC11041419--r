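# Independent oracles, deliberately naive and separate from the package code.

# Brute-force DTW by recursive path enumeration, no memoization. Only usable
# when the call tree is small; dtw_oracle() below falls back to a plain-R
# textbook DP for longer sequences (a full enumeration at lengths 15x15 would
# need ~7e9 recursive calls).
dtw_enum <- function(a, b, cost = c("abs", "sq")) {
  cost <- match.arg(cost)
  lc <- function(i, j) if (cost == "abs") abs(a[i] - b[j]) else (a[i] - b[j])^2
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(lc(1, 1))
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    lc(i, j) + best
  }
  rec(length(a), length(b))
}

dtw_dp_ref <- function(a, b, cost = c("abs", "sq")) {
  cost <- match.arg(cost)
  n <- length(a); m <- length(b)
  C <- outer(a, b, function(x, y) if (cost == "abs") abs(x - y) else (x - y)^2)
  G <- matrix(Inf, n + 1, m + 1)
  G[1, 1] <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    G[i + 1, j + 1] <- C[i, j] + min(G[i, j + 1], G[i + 1, j], G[i, j])
  }
  G[n + 1, m + 1]
}

dtw_oracle <- function(a, b, cost = "abs") {
  if (length(a) + length(b) <= 14) dtw_enum(a, b, cost) else dtw_dp_ref(a, b, cost)
}

# Quadratic-time, loop-based reference implementations of the validity
# indices, written straight from their formulas.
sil_ref <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(D[i, labels == cl]))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

ch_ref <- function(D, labels, medoids) {
  n <- nrow(D)
  labs <- sort(unique(labels))
  gm <- which.min(sapply(seq_len(n), function(i) sum(D[i, ])))
  W <- 0; B <- 0
  for (ci in seq_along(labs)) {
    members <- which(labels == labs[ci])
    W <- W + sum(D[members, medoids[ci]]^2)
    B <- B + length(members) * D[medoids[ci], gm]^2
  }
  (B / (length(labs) - 1)) / (W / (n - length(labs)))
}

cop_ref <- function(D, labels, medoids) {
  n <- nrow(D)
  labs <- sort(unique(labels))
  total <- 0
  for (ci in seq_along(labs)) {
    members <- which(labels == labs[ci])
    outside <- which(labels != labs[ci])
    intra <- mean(D[members, medoids[ci]])
    sep <- Inf
    for (y in outside) sep <- min(sep, max(D[members, y]))
    total <- total + length(members) * intra / sep
  }
  total / n
}

dbstar_ref <- function(D, labels, medoids) {
  labs <- sort(unique(labels))
  k <- length(labs)
  S <- sapply(seq_along(labs), function(ci)
    mean(D[labels == labs[ci], medoids[ci]]))
  total <- 0
  for (i in seq_len(k)) {
    num <- -Inf; den <- Inf
    for (j in seq_len(k)) if (j != i) {
      num <- max(num, S[i] + S[j])
      den <- min(den, D[medoids[i], medoids[j]])
    }
    total <- total + num / den
  }
  total / k
}

# Textbook one-way ANOVA F and chi-square statistics.
anova_ref <- function(x, g) {
  g <- factor(g)
  N <- length(x); k <- nlevels(g)
  gm <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(statistic = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

chisq_ref <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = x2, df = df,
       p = stats::pchisq(x2, df, lower.tail = FALSE))
}

# Small builders ---------------------------------------------------------------

make_series <- function(values, start = "2023-01-01 00:00:00", by_min = 15,
                        patient_id = "P1") {
  t0 <- as.POSIXct(start, tz = "UTC")
  tibble::tibble(patient_id = patient_id,
                 time = t0 + (seq_along(values) - 1) * by_min * 60,
                 glucose = values)
}

# hand-built hclust object from a merge/height description
make_hclust <- function(merge, height, labels) {
  structure(list(merge = merge, height = height,
                 order = seq_along(labels), labels = labels,
                 method = "complete", call = NULL, dist.method = "test"),
            class = "hclust")
}
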