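test_that("confusion metrics reproduce hand arithmetic and flag undefined cases", {
  m <- confusion_metrics(tp = 46, fp = 2, tn = 78, fn = 1)
  expect_equal(unname(m["accuracy"]), 124 / 127)
  expect_equal(unname(m["sensitivity"]), 46 / 47)
  expect_equal(unname(m["specificity"]), 78 / 80)

  none <- confusion_metrics(tp = 0, fp = 3, tn = 5, fn = 0)
  expect_true(is.na(none["sensitivity"]))
  expect_false(is.na(none["specificity"]))
})

test_that("cross-validation separates a planted signal and is reproducible", {
  sim <- simulate_profiles(panel_config(n_antigens = 100, n_subgrid_rows = 2,
                                        spots_per_subgrid = 40,
                                        n_group1 = 15, n_group2 = 15,
                                        effect_size = 60, noise_sd = 10,
                                        seed = 41L))
  cv1 <- cross_validate(sim$profiles, sim$groups, folds = 5,
                        repetitions = 3, seed = 5)
  cv2 <- cross_validate(sim$profiles, sim$groups, folds = 5,
                        repetitions = 3, seed = 5)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_identical(cv1$scores, cv2$scores)
  expect_gte(cv1$median["accuracy"], 0.9)
  expect_true(all(cv1$median >= cv1$ci["lower", ] - 1e-12))
  expect_true(all(cv1$median <= cv1$ci["upper", ] + 1e-12))

  # each serum is tested exactly once per repetition
  n <- nrow(sim$profiles)
  expect_true(all(rowSums(cv1$metrics[, c("tp", "fp", "tn", "fn")]) == n))
})

test_that("metrics are invariant under serum reordering", {
  sim <- simulate_profiles(panel_config(n_antigens = 60, n_subgrid_rows = 2,
                                        spots_per_subgrid = 30,
                                        n_group1 = 12, n_group2 = 12,
                                        seed = 42L))
  set.seed(1)
  ord <- sample(nrow(sim$profiles))
  cv_a <- cross_validate(sim$profiles, sim$groups, folds = 4,
                         repetitions = 2, seed = 9, calibrate = FALSE)
  cv_b <- cross_validate(sim$profiles[ord, ], sim$groups[ord], folds = 4,
                         repetitions = 2, seed = 9, calibrate = FALSE)
  expect_identical(cv_a$metrics, cv_b$metrics)
})

test_that("a null task sits at chance and degenerate input errors", {
  sim <- simulate_profiles(panel_config(n_antigens = 60, n_subgrid_rows = 2,
                                        spots_per_subgrid = 30,
                                        n_group1 = 15, n_group2 = 15,
                                        effect_size = 0, seed = 43L))
  cv <- cross_validate(sim$profiles, sim$groups, folds = 5,
                       repetitions = 4, seed = 2, calibrate = FALSE)
  expect_lt(abs(cv$median["accuracy"] - 0.5), 0.2)

  expect_error(cross_validate(sim$profiles,
                              rep("g", nrow(sim$profiles)), seed = 1),
               "two serum groups")
  expect_warning(cross_validate(sim$profiles[c(1:3, 16:30), ],
                                sim$groups[c(1:3, 16:30)], folds = 10,
                                repetitions = 1, seed = 1,
                                calibrate = FALSE),
                 "reducing folds")
})

test_that("fold-wise normalization leaks nothing from held-out sera", {
  sim <- simulate_profiles(panel_config(n_antigens = 60, n_subgrid_rows = 2,
                                        spots_per_subgrid = 30,
                                        n_group1 = 10, n_group2 = 10,
                                        seed = 44L))
  x <- sim$profiles
  cv <- cross_validate(x, sim$groups, folds = 5, repetitions = 1, seed = 8)
  # Perturb one serum drastically. Sera sharing its test fold are scored
  # by a model and a normalization reference fitted entirely without it,
  # so with leakage-free fold normalization their scores cannot move.
  x2 <- x
  x2[1, ] <- rev(x2[1, ])  # rank-changing perturbation of one serum
  cv2 <- cross_validate(x2, sim$groups, folds = 5, repetitions = 1, seed = 8)

  # reconstruct fold membership of serum 1
  set.seed(8)
  rep_seed <- sample.int(.Machine$integer.max - 1L, 1)
  set.seed(rep_seed)
  fold_id <- seroarray:::stratified_folds(sim$groups, 5, rownames(x))
  peers <- which(fold_id == fold_id[1])[-1]
  expect_gt(length(peers), 0)
  expect_equal(cv2$scores$score[peers], cv$scores$score[peers],
               tolerance = 1e-9)
  # the perturbed serum itself is evaluated on shifted data: its own
  # score is free to move (and virtually always does)
  expect_false(isTRUE(all.equal(cv2$scores$score[1], cv$scores$score[1])))
})

test_that("decision scores are calibrated probabilities with a 0.5 threshold", {
  sim <- simulate_profiles(panel_config(n_antigens = 80, n_subgrid_rows = 2,
                                        spots_per_subgrid = 40,
                                        n_group1 = 12, n_group2 = 12,
                                        effect_size = 80, noise_sd = 5,
                                        seed = 45L))
  cv <- cross_validate(sim$profiles, sim$groups, folds = 4,
                       repetitions = 2, seed = 4)
  sc <- decision_scores(cv)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_equal(attr(sc, "threshold"), 0.5)
  # a strongly separated task puts every serum on the correct side
  expect_true(all(sc$score[sc$group == "group1"] > 0.5))
  expect_true(all(sc$score[sc$group == "group2"] < 0.5))
  expect_identical(as.character(sc$predicted), as.character(sc$group))

  plain <- cross_validate(sim$profiles, sim$groups, folds = 4,
                          repetitions = 1, seed = 4, calibrate = FALSE)
  expect_error(decision_scores(plain), "calibrate")
})

test_that("permutation test is stratified, reproducible and detects signal", {
  sim <- simulate_profiles(panel_config(n_antigens = 80, n_subgrid_rows = 2,
                                        spots_per_subgrid = 40,
                                        n_group1 = 12, n_group2 = 12,
                                        effect_size = 80, noise_sd = 5,
                                        seed = 46L))
  pt1 <- permutation_test(sim$profiles, sim$groups, n_permutations = 12,
                          folds = 4, seed = 6)
  pt2 <- permutation_test(sim$profiles, sim$groups, n_permutations = 12,
                          folds = 4, seed = 6)
  expect_identical(pt1$accuracies, pt2$accuracies)
  expect_length(pt1$accuracies, 12)
  expect_true(all(pt1$accuracies >= 0 & pt1$accuracies <= 1))
  # strong signal: every true-label repetition beats every permutation
  expect_gt(min(pt1$observed$metrics$accuracy), max(pt1$accuracies))
  expect_lt(pt1$p_value, 1e-3)
})
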