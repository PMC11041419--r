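test_that("percentage distances match hand evaluations and are symmetric", {
  p <- c(60, 40); q <- c(60, 40)
  expect_equal(percentage_distance(p, q), 0)
  expect_equal(percentage_distance(c(100, 0), c(0, 100)), 1)
  set.seed(1)
  for (i in 1:10) {
    a <- as.numeric(rmultinom(1, 100, runif(4)))
    b <- as.numeric(rmultinom(1, 100, runif(4)))
    for (mth in c("hellinger", "bray_curtis", "aitchison", "euclidean")) {
      d1 <- percentage_distance(a, b, mth)
      expect_equal(d1, percentage_distance(b, a, mth))
      expect_gte(d1, 0)
    }
    expect_lte(percentage_distance(a, b, "hellinger"), 1)
  }
})

test_that("percentage distance validates its inputs", {
  expect_error(percentage_distance(c(50, 50), c(100, 0, 0)), "equal length")
  expect_error(percentage_distance(c(-10, 110), c(50, 50)), "nonnegative")
  expect_error(percentage_distance(c(30, 30), c(50, 50)), "sum to 100")
})

test_that("complete linkage reproduces a hand-agglomerated 3-point toy", {
  # euclidean distances between these compositions: d(1,2)=sqrt(2),
  # d(1,3)=5*sqrt(2), d(2,3)=6*sqrt(2) -- merge (1,2) first, final at max
  comps <- rbind(P1 = c(90, 10), P2 = c(91, 9), P3 = c(85, 15))
  comps <- 100 * comps / rowSums(comps)
  tree <- hcluster_patients(comps, method = "euclidean")
  expect_equal(tree$height, c(sqrt(2), 6 * sqrt(2)), tolerance = 1e-9)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))
})

test_that("identical compositions merge first at height zero", {
  comps <- rbind(A = c(50, 30, 20), B = c(50, 30, 20), C = c(10, 10, 80),
                 D = c(80, 15, 5))
  tree <- hcluster_patients(comps)
  expect_equal(tree$height[1], 0)
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))
})

test_that("patient order permutation leaves the tree and cut invariant", {
  tipd <- simulate_compositions(6, seed = 31)
  tree1 <- hcluster_patients(tipd)
  perm <- withr::with_seed(9, sample(nrow(tipd)))
  tree2 <- hcluster_patients(tipd[perm, ])
  expect_equal(sort(tree1$height), sort(tree2$height), tolerance = 1e-12)
  c1 <- cut_by_largest_gap(tree1); c2 <- cut_by_largest_gap(tree2)
  expect_equal(adjustedRandIndex(c1[names(c2)], c2), 1)
})

test_that("pattern relabeling applied consistently does not change clusters", {
  tipd <- simulate_compositions(8, seed = 13)
  m <- tip_cols <- as.matrix(tipd[paste0("tip_", 1:6)])
  rownames(m) <- tipd$patient_id
  perm <- c(3, 1, 6, 2, 4, 5)
  c1 <- cut_by_largest_gap(hcluster_patients(m))
  c2 <- cut_by_largest_gap(hcluster_patients(m[, perm]))
  expect_equal(adjustedRandIndex(c1, c2), 1)
})

test_that("largest-gap cut matches the worked height examples", {
  tree <- make_hclust(merge = rbind(c(-1, -2), c(-3, -4), c(1, 2)),
                      height = c(0.10, 0.12, 0.90), labels = paste0("P", 1:4))
  cl <- cut_by_largest_gap(tree)
  expect_equal(max(cl), 2)
  flat <- make_hclust(merge = rbind(c(-1, -2), c(-3, -4), c(1, 2)),
                      height = c(0.2, 0.2, 0.2), labels = paste0("P", 1:4))
  expect_warning(clf <- cut_by_largest_gap(flat), "flat")
  expect_equal(max(clf), 2)
})

test_that("the planted 4-archetype structure is recoverable at the 4-cut", {
  for (s in 1:3) {
    tipd <- simulate_compositions(15, seed = s)
    tree <- hcluster_patients(tipd)
    expect_true(all(diff(tree$height) >= -1e-12))  # monotone heights
    cl4 <- stats::cutree(tree, k = 4)
    expect_gte(adjustedRandIndex(cl4, tipd$archetype), 0.9)
  }
})

test_that("compare_clusters handles the worked statistical examples", {
  clin <- tibble::tibble(patient_id = as.character(1:6),
                         same = c(1, 2, 3, 1, 2, 3),
                         const = rep(4.2, 6))
  labels <- stats::setNames(rep(1:2, each = 3), clin$patient_id)
  st <- compare_clusters(clin, labels)
  same_row <- st[st$variable == "same", ]
  expect_equal(same_row$statistic, 0)
  expect_equal(same_row$p_value, 1)
  const_row <- st[st$variable == "const", ]
  expect_equal(const_row$note, "zero variance")
  expect_true(is.na(const_row$p_value))
  # diagonal contingency table
  clin2 <- tibble::tibble(patient_id = as.character(1:20),
                          cat = rep(c("x", "y"), each = 10))
  st2 <- compare_clusters(clin2, stats::setNames(rep(1:2, each = 10),
                                                 clin2$patient_id))
  expect_equal(st2$statistic, 20)
  expect_equal(st2$df, 1)
  expect_equal(st2$test, "chi_square")
})

test_that("missing values are omitted per variable and counted", {
  clin <- tibble::tibble(patient_id = as.character(1:8),
                         x = c(1, 2, NA, 4, 5, 6, NA, 8),
                         g = c("a", "a", "b", NA, "b", "a", "b", "a"))
  labels <- stats::setNames(rep(1:2, each = 4), clin$patient_id)
  expect_warning(st <- compare_clusters(clin, labels), "expected cell counts")
  expect_equal(st$n_missing_omitted, c(2L, 1L))
  expect_equal(st$n_used, c(6L, 7L))
  # reference on the complete cases
  ref <- anova_ref(clin$x[!is.na(clin$x)], labels[!is.na(clin$x)])
  expect_equal(st$statistic[1], ref$statistic, tolerance = 1e-12)
})

test_that("ANOVA and chi-square agree with reference formulas on random tables", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(12:40, 1)
    k <- sample(2:4, 1)
    cl <- stats::setNames(sample(k, n, replace = TRUE), as.character(seq_len(n)))
    if (length(unique(cl)) < 2) next
    clin <- tibble::tibble(patient_id = as.character(seq_len(n)),
                           num = rnorm(n, mean = cl),
                           cat = sample(letters[1:3], n, replace = TRUE))
    st <- suppressWarnings(compare_clusters(clin, cl))
    ref_a <- anova_ref(clin$num, cl)
    expect_equal(st$statistic[st$variable == "num"], ref_a$statistic,
                 tolerance = 1e-8)
    expect_equal(st$p_value[st$variable == "num"], ref_a$p, tolerance = 1e-8)
    tab <- table(factor(cl), clin$cat)
    if (all(dim(tab) >= 2)) {
      ref_c <- chisq_ref(tab)
      expect_equal(st$statistic[st$variable == "cat"], ref_c$statistic,
                   tolerance = 1e-8)
      expect_equal(st$p_value[st$variable == "cat"], ref_c$p, tolerance = 1e-8)
      expect_equal(st$df[st$variable == "cat"], ref_c$df)
    }
  }
})

test_that("tertile grouping splits into near-equal groups and excludes the column", {
  set.seed(3)
  clin <- tibble::tibble(patient_id = as.character(1:30),
                         days = runif(30, 10, 900),
                         hba1c = rnorm(30, 60, 10))
  gc <- group_compare(clin, "days")
  expect_equal(length(unique(gc$groups)), 3)
  expect_true(max(table(gc$groups)) - min(table(gc$groups)) <= 1)
  expect_false("days" %in% gc$stats_table$variable)
  expect_true("hba1c" %in% gc$stats_table$variable)
})

test_that("linkage trees survive a JSON round trip", {
  tipd <- simulate_compositions(5, seed = 8)
  tree <- hcluster_patients(tipd)
  f <- withr::local_tempfile(fileext = ".json")
  write_linkage_json(tree, f)
  back <- read_linkage_json(f)
  expect_equal(back$height, tree$height, tolerance = 1e-12)
  expect_equal(stats::cutree(back, 4), stats::cutree(tree, 4))
  expect_equal(attr(back, "distance_name"), "hellinger")
})
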