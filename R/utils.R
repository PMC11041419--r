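#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' throughout the package's planted-structure recovery checks. 1 means the
#' partitions are identical up to relabeling; independent labelings score
#' around 0.
#'
#' @param a,b label vectors of equal length (any atomic type); pairs where
#'   either label is `NA` are dropped.
#' @return a single number in \[-1, 1\].
#' @export
adjustedRandIndex <- function(a, b) {
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sij - expected) / (max_index - expected)
}

# Seeded RNG scope: all stochastic operations take an explicit `seed` and
# leave the caller's RNG state untouched.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream of sub-seeds below 2^31 from one master seed.
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 99991L * seq_len(n)) %% 2147483629L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Dirichlet sampler (no installed package exports one).
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}
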