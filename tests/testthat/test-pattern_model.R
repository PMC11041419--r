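two_template_windows <- function(n_per = 20, seed = 1) {
  lo <- rep(4, 10); hi <- rep(18, 10)
  withr::with_seed(seed, {
    vals <- c(lapply(seq_len(n_per), function(i) lo + rnorm(10, 0, 0.1)),
              lapply(seq_len(n_per), function(i) hi + rnorm(10, 0, 0.1)))
  })
  list(values = vals, truth = rep(1:2, each = n_per))
}

test_that("k-medoids recovers a planted two-template split exactly", {
  tw <- two_template_windows()
  m <- cluster_windows(tw$values, 2, seed = 5)
  expect_equal(adjustedRandIndex(m$labels, tw$truth), 1)
  # medoid property: each medoid is a member of the training set
  for (med in m$medoids)
    expect_true(any(vapply(tw$values, identical, TRUE, med)))
  # labels ordered by ascending medoid mean
  expect_lt(mean(m$medoids[[1]]), mean(m$medoids[[2]]))
  expect_true(all(m$labels[tw$truth == 1] == 1))
})

test_that("k = 1 returns the distance-minimizing medoid", {
  tw <- two_template_windows(n_per = 8)
  m <- cluster_windows(tw$values, 1, seed = 2)
  D <- dtw_distance_matrix(tw$values)
  expect_equal(m$medoid_indices, which.min(colSums(D)))
  expect_equal(m$total_within_distance, min(colSums(D)))
})

test_that("k = n makes every window its own medoid at zero cost", {
  vals <- list(c(4, 5), c(8, 9), c(14, 15))
  m <- cluster_windows(vals, 3, seed = 1)
  expect_equal(m$total_within_distance, 0)
  expect_equal(sort(m$medoid_indices), 1:3)
  expect_equal(length(unique(m$labels)), 3)
})

test_that("degenerate and invalid clustering inputs error", {
  vals <- list(c(1, 2), c(3, 4))
  expect_error(cluster_windows(vals, 3, seed = 1), "k must lie")
  same <- replicate(5, c(6, 7, 8), simplify = FALSE)
  expect_error(cluster_windows(same, 2, seed = 1), "identical")
})

test_that("the PAM objective never increases across swap iterations", {
  sim <- simulate_pattern_windows(120, seed = 31)
  m <- cluster_windows(sim$values, 4, seed = 9, restarts = 1)
  expect_true(all(diff(m$trace) <= 1e-9))
})

test_that("medoid-mean relabeling makes labels seed-invariant for a stable partition", {
  tw <- two_template_windows(seed = 3)
  m1 <- cluster_windows(tw$values, 2, seed = 11)
  m2 <- cluster_windows(tw$values, 2, seed = 97)
  expect_equal(m1$labels, m2$labels)
  expect_equal(m1$medoid_indices, m2$medoid_indices)
})

test_that("our PAM objective is no worse than cluster::pam's", {
  skip_if_not_installed("cluster")
  sim <- simulate_pattern_windows(80, seed = 13)
  D <- dtw_distance_matrix(sim$values)
  ours <- cluster_windows(sim$values, 6, seed = 4, D = D)
  ref <- cluster::pam(stats::as.dist(D), 6)
  ref_cost <- sum(apply(D[, ref$id.med, drop = FALSE], 1, min))
  expect_lte(ours$total_within_distance, ref_cost + 1e-9)
  expect_equal(adjustedRandIndex(ours$labels, ref$clustering), 1)
})

test_that("planted six-template recovery holds across seeds", {
  for (s in 1:3) {
    sim <- simulate_pattern_windows(240, noise_sd = 0.5, seed = s)
    m <- cluster_windows(sim$values, 6, seed = s)
    expect_gte(adjustedRandIndex(m$labels, sim$truth), 0.9)
  }
})

test_that("validity indices match their hand-evaluated toys", {
  # two well-separated duplicate pairs
  D <- matrix(10, 4, 4); D[1, 2] <- D[2, 1] <- 0; D[3, 4] <- D[4, 3] <- 0
  diag(D) <- 0
  cv <- suppressWarnings(compute_cvis(D, c(1, 1, 2, 2), c(1, 3)))
  expect_equal(cv$silhouette, 1)
  expect_equal(cv$davies_bouldin_star, 0)
  # symmetric 4-point toy: within 1, between 10
  D2 <- matrix(10, 4, 4); D2[1, 2] <- D2[2, 1] <- 1; D2[3, 4] <- D2[4, 3] <- 1
  diag(D2) <- 0
  cv2 <- compute_cvis(D2, c(1, 1, 2, 2), c(1, 3))
  expect_equal(cv2$silhouette, 0.9)
})

test_that("random labels on an equidistant set give near-zero silhouette", {
  n <- 12
  D <- matrix(1, n, n); diag(D) <- 0
  for (s in 1:20) {
    labels <- withr::with_seed(s, sample(rep(1:2, n / 2)))
    med <- c(which(labels == 1)[1], which(labels == 2)[1])
    cv <- compute_cvis(D, labels, med)
    expect_lt(abs(cv$silhouette), 0.2)
  }
})

test_that("validity indices agree with loop-based reference formulas", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(10:18, 1); k <- sample(2:4, 1)
    pts <- runif(n, 0, 10)
    D <- as.matrix(stats::dist(pts))
    labels <- cut(pts, k, labels = FALSE)
    if (length(unique(labels)) < 2) next
    labs <- sort(unique(labels))
    med <- vapply(labs, function(l) {
      members <- which(labels == l)
      members[which.min(colSums(D[members, members, drop = FALSE]))]
    }, 0L)
    cv <- compute_cvis(D, labels, med)
    expect_equal(cv$silhouette, sil_ref(D, labels), tolerance = 1e-9)
    expect_equal(cv$calinski_harabasz, ch_ref(D, labels, med), tolerance = 1e-9)
    expect_equal(cv$cop, cop_ref(D, labels, med), tolerance = 1e-9)
    expect_equal(cv$davies_bouldin_star, dbstar_ref(D, labels, med),
                 tolerance = 1e-9)
  }
})

test_that("grid search returns a single config unchanged and orders its report", {
  cfg <- synthetic_config(n_patients = 4, days_per_patient = 2, seed = 21)
  data <- dedup_minute_median(generate_cohort(cfg)$data)
  gs <- grid_search(data, durations = 150, overlaps = 50, k_fixed = 4,
                    seed = 3, subsample = 80, restarts = 2)
  expect_equal(gs$best$duration, 150)
  expect_equal(gs$best$overlap_pct, 50)
  expect_equal(nrow(gs$report), 1)
  gs2 <- grid_search(data, durations = c(150, 120), overlaps = c(50, 0),
                     k_fixed = 4, seed = 3, subsample = 60, restarts = 2)
  # rows ordered by duration then overlap so rank ties resolve to the
  # shorter duration / lower overlap
  expect_equal(gs2$report$duration, c(120, 120, 150, 150))
  expect_equal(gs2$report$overlap, c(0, 50, 0, 50))
  expect_true(all(c("silhouette", "calinski_harabasz", "cop",
                    "davies_bouldin_star", "mean_rank") %in% names(gs2$report)))
})

test_that("elbow selection finds a planted k and validates its inputs", {
  sim <- simulate_pattern_windows(150, noise_sd = 0.3,
                                  weights = c(1, 0, 1, 0, 1, 0) / 3, seed = 17)
  e <- elbow_select_k(sim$values, 2:6, seed = 5)
  expect_equal(e$k_star, 3)
  expect_true(all(diff(e$curve$total_within_distance) < 0))
  expect_error(elbow_select_k(sim$values, 3:4, seed = 1), "at least 3")
})

test_that("assignment reproduces training labels and breaks ties low", {
  tw <- two_template_windows(n_per = 10)
  m <- cluster_windows(tw$values, 2, seed = 8)
  expect_equal(as.integer(assign_windows(m, tw$values)), m$labels)
  # window identical to a medoid
  lab <- assign_windows(m, list(m$medoids[[2]]))
  expect_equal(as.integer(lab), 2L)
  expect_equal(attr(lab, "distance"), 0)
  # exact halfway tie goes to the lower pattern label
  m2 <- structure(list(k = 2, medoids = list(c(0, 0), c(2, 2)),
                       dtw = dtw_config(), duration = 30), class = "pattern_model")
  expect_equal(as.integer(assign_windows(m2, list(c(1, 1)))), 1L)
})

test_that("pattern envelopes use interpolated percentiles on the common grid", {
  vals <- list(rep(4, 10), rep(6, 10))
  m <- structure(list(k = 1, medoids = list(rep(5, 10)), dtw = dtw_config(),
                      duration = 150), class = "pattern_model")
  prs <- pattern_range_summary(m, vals, labels = c(1, 1))
  expect_equal(unique(prs$envelopes$lower), 4.4)   # 20th pct of {4, 6}
  expect_equal(unique(prs$envelopes$upper), 5.6)   # 80th pct of {4, 6}
  expect_equal(unique(prs$envelopes$median), 5)
  expect_equal(prs$envelopes$offset, seq(0, 135, by = 15))
  expect_true(prs$bands$within_target)             # envelope inside (3.9, 10]
  # identical windows collapse the band
  prs2 <- pattern_range_summary(m, list(rep(7, 10), rep(7, 10)),
                                labels = c(1, 1))
  expect_equal(prs2$envelopes$lower, prs2$envelopes$upper)
  # hyperglycemic pattern is not flagged within target
  prs3 <- pattern_range_summary(m, list(rep(15, 10)), labels = 1)
  expect_false(prs3$bands$within_target)
  expect_match(prs3$bands$bands_spanned, ">=13.9")
})

test_that("pattern models survive a JSON round trip", {
  tw <- two_template_windows(n_per = 6)
  m <- cluster_windows(tw$values, 2, seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_pattern_model(m, f)
  m2 <- read_pattern_model(f)
  expect_equal(m2$k, m$k)
  expect_equal(m2$medoids, m$medoids, tolerance = 1e-12)
  expect_equal(m2$dtw$local_cost, m$dtw$local_cost)
  expect_equal(as.integer(assign_windows(m2, tw$values)),
               as.integer(assign_windows(m, tw$values)))
})
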