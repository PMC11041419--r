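test_that("templates respect their stated glucose bands and trends", {
  tl <- pattern_templates(150)
  expect_length(tl, 6)
  expect_true(all(lengths(tl) == 10))
  expect_true(all(tl[[1]] >= 3 & tl[[1]] <= 6))
  expect_true(all(tl[[2]] >= 6 & tl[[2]] <= 8))
  expect_true(all(diff(tl[[3]]) < 0))     # declining
  expect_true(all(diff(tl[[4]]) > 0))     # rising
  expect_true(all(tl[[5]] >= 14 & tl[[5]] <= 19))
  expect_true(all(tl[[6]] >= 19 & tl[[6]] <= 28))
  means <- vapply(tl, mean, 0)
  expect_true(all(diff(means) > 0))       # strictly increasing means
  expect_error(pattern_templates(20), "duration")
})

test_that("templates scale with duration at 15-minute resolution", {
  expect_true(all(lengths(pattern_templates(120)) == 8))
  expect_true(all(lengths(pattern_templates(180)) == 12))
})

test_that("cluster archetype compositions sum to 100", {
  A <- gv_archetypes()
  expect_equal(dim(A), c(4, 6))
  expect_equal(unname(rowSums(A)), rep(100, 4), tolerance = 1e-9)
})

test_that("cohort generation is reproducible from the seed", {
  cfg <- synthetic_config(n_patients = 3, days_per_patient = 2, seed = 5)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$data, c2$data)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(synthetic_config(n_patients = 3, days_per_patient = 2,
                                         seed = 6))
  expect_false(identical(c1$data$glucose, c3$data$glucose))
})

test_that("noiseless single-template patients emit exact template copies", {
  onehot <- matrix(0, 1, 6); onehot[1, 3] <- 100
  rownames(onehot) <- "T3"; colnames(onehot) <- paste0("tip_", 1:6)
  cfg <- synthetic_config(n_patients = 2, days_per_patient = 1, noise_sd = 0,
                          dropout_rate = 0, archetypes = onehot,
                          cluster_weights = 1, meal_boost = 1, night_boost = 1,
                          seed = 4)
  coh <- generate_cohort(cfg)
  wins <- extract_windows(dedup_minute_median(coh$data),
                          windowing_config(150, 0))
  tmpl <- pattern_templates(150)[[3]]
  for (v in wins$values) expect_equal(v, tmpl[seq_along(v)], tolerance = 1e-12)
})

test_that("generated glucose stays inside the physiological clip range", {
  cfg <- synthetic_config(n_patients = 5, days_per_patient = 3, noise_sd = 3,
                          seed = 7)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$data$glucose >= 1 & coh$data$glucose <= 30))
})

test_that("heavy dropout pushes most windows under the density threshold", {
  cfg <- synthetic_config(n_patients = 4, days_per_patient = 3,
                          dropout_rate = 0.8, seed = 3)
  w <- extract_windows(dedup_minute_median(generate_cohort(cfg)$data),
                       windowing_config(150, 50))
  filt <- density_filter(w, 4)
  expect_gt(filt$n_discarded / nrow(w), 0.5)
})

test_that("pooled template shares track the drawn mixtures (no diurnal boost)", {
  cfg <- synthetic_config(n_patients = 20, days_per_patient = 14,
                          meal_boost = 1, night_boost = 1, seed = 9)
  coh <- generate_cohort(cfg)
  pooled_share <- 100 * tabulate(coh$truth$template, 6) /
    nrow(coh$truth)
  pooled_mix <- colMeans(coh$mixtures)
  expect_true(all(abs(pooled_share - pooled_mix) <= 5))
  expect_equal(unname(rowSums(coh$mixtures)), rep(100, 20), tolerance = 1e-9)
})

test_that("standalone window simulation is seeded and labeled", {
  s1 <- simulate_pattern_windows(50, seed = 2)
  s2 <- simulate_pattern_windows(50, seed = 2)
  expect_identical(s1, s2)
  expect_true(all(s1$truth %in% 1:6))
  expect_true(all(lengths(s1$values) == 10))
  one <- simulate_pattern_windows(30, noise_sd = 0,
                                  weights = c(0, 1, 0, 0, 0, 0), seed = 1)
  tmpl <- pattern_templates(150)[[2]]
  for (v in one$values) expect_equal(v, tmpl)
})

test_that("window ground truth is NA only for boundary-straddling windows", {
  cfg <- synthetic_config(n_patients = 2, days_per_patient = 1, noise_sd = 0,
                          dropout_rate = 0, seed = 11)
  coh <- generate_cohort(cfg)
  wins <- extract_windows(dedup_minute_median(coh$data),
                          windowing_config(150, 50))
  truth <- window_ground_truth(wins, coh$truth)
  offs <- as.numeric(difftime(wins$start,
                              min(coh$truth$segment_start), units = "mins")) %% 150
  aligned <- offs == 0
  expect_true(all(!is.na(truth[aligned & wins$n_samples == 10])))
  # straddling windows are ambiguous exactly when their halves disagree
  straddle <- which(!aligned & wins$n_samples == 10)
  expect_true(all(is.na(truth[straddle]) |
                    vapply(straddle, function(i) {
                      ti <- coh$truth[coh$truth$patient_id == wins$patient_id[i], ]
                      seg <- floor((as.numeric(difftime(wins$start[i],
                                                        min(ti$segment_start),
                                                        units = "mins")) +
                                      wins$offsets[[i]]) / 150) + 1
                      length(unique(ti$template[seg])) == 1
                    }, TRUE)))
})
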