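grid <- test_grid()

test_that("ROC-area separability counts pairs exhaustively and folds direction", {
  # class A {0.2, 0.4} vs class B {0.3, 0.5}: 3 of 4 pairs concordant one way
  expect_equal(auc_separability(c(0.2, 0.4, 0.3, 0.5), c(1, 1, -1, -1)), 0.75)
  # direction-free: the mirrored assignment scores identically
  expect_equal(auc_separability(c(0.2, 0.4, 0.3, 0.5), c(-1, -1, 1, 1)), 0.75)
  # perfect separation
  expect_equal(auc_separability(c(1, 2, 3, 7, 8, 9), c(-1, -1, -1, 1, 1, 1)), 1)
  # constant column scores exactly 0.5
  expect_identical(auc_separability(rep(2, 6), c(1, 1, 1, -1, -1, -1)), 0.5)
  # ties contribute 1/2
  expect_equal(auc_separability(c(1, 2, 2, 3), c(-1, -1, 1, 1)), 0.875)
  expect_error(auc_separability(1:3, c(1, 1, 1)), "both classes")
  # identical distributions: close to 0.5 for large n
  set.seed(4)
  x <- rnorm(400)
  y400 <- rep(c(1, -1), 200)
  auc <- auc_separability(x, y400)
  expect_lt(abs(auc - 0.5), 3 * sqrt(1 / 12 / 200))  # folded, so one-sided
  # independent library oracle on the same data
  proc <- as.numeric(pROC::auc(pROC::roc(y400, x, quiet = TRUE,
                                         direction = "<", levels = c(-1, 1))))
  expect_equal(auc, max(proc, 1 - proc), tolerance = 1e-12)
})

test_that("feature ranking puts a planted column first and breaks ties stably", {
  hits <- sum(vapply(1:10, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(30 * 20), 30, 20)
    y <- rep(c(1, -1), each = 15)
    x[y > 0, 7] <- x[y > 0, 7] + 2
    rank_features(as_feature_set(x, y))[1] == 7
  }, logical(1)))
  expect_gte(hits, 9)
  # all-constant features are all tied at 0.5: original column order
  xc <- matrix(1, 8, 5)
  expect_equal(rank_features(as_feature_set(xc, rep(c(1, -1), 4))), 1:5)
})

test_that("training-fold ranking differs from full-data ranking when the held-out subject is extreme", {
  # leakage canary: feature 1 separates perfectly except for one extreme
  # subject; with that subject held out the two rankings must differ
  x <- cbind(c(5, 1.1, 1.2, 1.3, -1.1, -1.2, -1.3, -5),
             c(0.9, 1.0, 1.1, 1.2, -0.9, -1.0, -1.1, -1.2))
  x[1, 1] <- -30  # extreme patient flips feature 1's direction benefit
  y <- rep(c(1, -1), each = 4)
  full_rank <- rank_features(as_feature_set(x, y))
  train_rank <- rank_features(as_feature_set(x[-1, ], y[-1]))
  expect_false(identical(full_rank, train_rank))
})

test_that("the linear max-margin fit separates, fails on XOR, and is scale-stable", {
  set.seed(2)
  x <- rbind(matrix(rnorm(20, mean = 3), 10, 2),
             matrix(rnorm(20, mean = -3), 10, 2))
  y <- rep(c(1, -1), each = 10)
  fit <- fit_linear_maxmargin(x, y)
  pred <- predict(fit, x)
  expect_equal(pred$predicted, y)
  # patient side is positive
  expect_true(all(pred$distance[y > 0] > 0))
  # XOR is not linearly separable: training accuracy bounded at 75%
  xor_x <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1)) + 0.01 * matrix(rnorm(8), 4, 2)
  xor_y <- c(-1, 1, 1, -1)
  fit_xor <- fit_linear_maxmargin(xor_x, xor_y, cost = 100)
  expect_lte(mean(predict(fit_xor, xor_x)$predicted == xor_y), 0.75)
  # scaling the data with cost rescaled leaves predictions unchanged
  fit_scaled <- fit_linear_maxmargin(10 * x, y, cost = 1 / 100)
  expect_equal(predict(fit_scaled, 10 * x)$predicted, pred$predicted)
  expect_error(fit_linear_maxmargin(x, rep(1, 20)), "both classes")
})

test_that("leave-one-out holds each subject out exactly once and aggregates correctly", {
  out <- tensor_cohort(seed = 2, n_a = 6, n_b = 7, n_regions = 6)
  feats <- feature_set(out$tensor, out$subjects, nearest_freq(grid, 11))
  cv <- loocv(feats)
  expect_setequal(cv$folds$subject_id, out$subjects$subject_id)
  expect_equal(nrow(cv$folds), 13)
  p <- sum(cv$folds$truth > 0)
  n <- sum(cv$folds$truth < 0)
  expect_equal(cv$accuracy, (cv$sensitivity * p + cv$specificity * n) / (p + n))
  # predictions agree with the sign of the recorded distance
  expect_equal(cv$folds$predicted, ifelse(cv$folds$distance > 0, 1, -1))
  # k_best clamps with a warning
  expect_warning(loocv(feats, k_best = 10000), "clamped")
})

test_that("a strongly planted effect is recovered and shuffled labels are not", {
  # kappa gap 0.5 on four pairs, ranking-based selection as in the pipeline
  pairs4 <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
  accs <- vapply(1:5, function(seed) {
    out <- tensor_cohort(seed = seed, n_a = 20, n_b = 20, pairs = pairs4)
    feats <- feature_set(out$tensor, out$subjects, nearest_freq(grid, 11))
    loocv(feats, k_best = 4)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
  out <- tensor_cohort(seed = 6, n_a = 20, n_b = 20, pairs = pairs4)
  feats <- feature_set(out$tensor, out$subjects, nearest_freq(grid, 11))
  # shuffled labels drop to chance in most runs
  over <- sum(vapply(1:5, function(seed) {
    perm <- feats
    perm$labels <- withr::with_seed(seed, sample(feats$labels))
    loocv(perm)$accuracy > 0.7
  }, logical(1)))
  expect_lte(over, 1)
})

test_that("per-wavelet accuracy peaks at the planted alpha frequency", {
  pairs4 <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
  hits <- vapply(1:5, function(seed) {
    out <- tensor_cohort(seed = seed, n_a = 15, n_b = 15, pairs = pairs4)
    acc <- accuracy_by_wavelet(out$tensor, out$subjects)
    as.character(acc$band[which.max(acc$accuracy)]) == "alpha"
  }, logical(1))
  expect_gte(sum(hits), 4)
  out <- tensor_cohort(seed = 1, n_a = 6, n_b = 6)
  acc <- accuracy_by_wavelet(out$tensor, out$subjects)
  expect_equal(nrow(acc), nrow(grid))
  expect_named(acc, c("freq_index", "frequency_hz", "band",
                      "sensitivity", "specificity", "accuracy"))
})

test_that("per-band accuracy covers the five bands and matches the singleton-band case", {
  out <- tensor_cohort(seed = 3, n_a = 8, n_b = 8)
  acc <- accuracy_by_band(out$tensor, out$subjects)
  expect_equal(nrow(acc), 5)
  expect_equal(as.character(acc$band),
               c("delta", "theta", "alpha", "beta", "gamma"))
  # a band holding exactly one grid point equals that wavelet's run
  g5 <- make_frequency_grid(5, 2, 48)   # alpha band has a single point
  out5 <- tensor_cohort(seed = 3, n_a = 8, n_b = 8, grid = g5)
  alpha_idx <- g5$freq_index[g5$band == "alpha"]
  expect_length(alpha_idx, 1)
  by_band <- accuracy_by_band(out5$tensor, out5$subjects)
  by_wave <- accuracy_by_wavelet(out5$tensor, out5$subjects)
  expect_equal(by_band$accuracy[by_band$band == "alpha"],
               by_wave$accuracy[alpha_idx])
})

test_that("the permutation null floors at the add-one estimate and rejects n_perm = 0", {
  out <- tensor_cohort(seed = 4, n_a = 8, n_b = 8, kappa_a = 0.95, kappa_b = 0.1)
  feats <- feature_set(out$tensor, out$subjects, nearest_freq(grid, 11))
  null <- permutation_null(feats, n_perm = 19, seed = 1)
  expect_equal(null$p_value, (1 + sum(null$accuracies >= null$observed)) / 20)
  expect_length(null$accuracies, 19)
  # perfectly recovered effect beats every shuffle: p at its floor
  expect_equal(null$p_value, 1 / 20)
  expect_error(permutation_null(feats, n_perm = 0), "n_perm")
})

test_that("permutation p-values are calibrated under exchangeable labels", {
  hits <- sum(vapply(1:10, function(seed) {
    out <- null_cohort(seed = seed, n_a = 5, n_b = 5, n_regions = 6)
    feats <- feature_set(out$tensor, out$subjects, nearest_freq(grid, 11))
    permutation_null(feats, n_perm = 19, seed = seed + 100)$p_value <= 0.05
  }, logical(1)))
  expect_lte(hits, 2)
})

test_that("accuracy-vs-k curves are complete and consistent with plain LOOCV at k = n", {
  out <- tensor_cohort(seed = 5, n_a = 8, n_b = 8, n_regions = 5)
  feats <- feature_set(out$tensor, out$subjects, nearest_freq(grid, 11))
  n_feat <- ncol(feats$x)
  kc <- accuracy_vs_k(feats, k_max = n_feat)
  expect_equal(nrow(kc$curves), n_feat)
  expect_equal(kc$curves$k, seq_len(n_feat))
  plain <- loocv(feats, k_best = NULL)
  expect_equal(kc$curves$accuracy[n_feat], plain$accuracy)
  expect_equal(kc$distances[, n_feat], plain$folds$distance, tolerance = 1e-9)
  # ties in best accuracy resolve to the smaller k
  expect_equal(kc$best_k,
               min(kc$curves$k[kc$curves$accuracy == max(kc$curves$accuracy)]))
})

test_that("selection curves peak near the planted feature count and then decline", {
  peaks <- vapply(1:5, function(seed) {
    set.seed(seed)
    m <- 40
    x <- matrix(rnorm(m * 100), m, 100)
    y <- rep(c(1, -1), each = m / 2)
    x[y > 0, 1:10] <- x[y > 0, 1:10] + 1.2   # 10 informative features
    kc <- accuracy_vs_k(as_feature_set(x, y), k_max = 100)
    kc$best_k
  }, numeric(1))
  expect_gte(mean(peaks >= 5 & peaks <= 30), 0.8)
})

test_that("confidence correlates with scores under the documented sign convention", {
  out <- tensor_cohort(seed = 9, n_a = 12, n_b = 12)
  feats <- feature_set(out$tensor, out$subjects, nearest_freq(grid, 11))
  kc <- accuracy_vs_k(feats, k_max = 5)
  # scores equal to the distances give r = 1
  fake <- out$subjects
  fake$severity <- kc$distances[, 3][match(out$subjects$subject_id, kc$subject_id)]
  r <- confidence_score_correlation(kc, fake)
  expect_equal(r$r[3], 1)
  # zero-variance scores are flagged undefined
  fake$severity <- 1
  expect_warning(r0 <- confidence_score_correlation(kc, fake), "zero-variance")
  expect_true(all(is.na(r0$r)))
  # misclassified patients carry negative distances
  sc <- confidence_scatter(kc, out$subjects, k = 3)
  expect_equal(sc$misclassified, sc$distance < 0)
})

test_that("generator score coupling produces positive confidence-severity correlation", {
  hits <- sum(vapply(1:10, function(seed) {
    out <- tensor_cohort(seed = seed, n_a = 15, n_b = 15)
    feats <- feature_set(out$tensor, out$subjects, nearest_freq(grid, 11))
    kc <- accuracy_vs_k(feats, k_max = 3)
    r <- confidence_score_correlation(kc, out$subjects)
    r$r[3] > 0
  }, logical(1)))
  expect_gte(hits, 8)
})

test_that("the robustness map averages -1/0 selection indicators over folds and wavelets", {
  # single-wavelet alpha band so a dominant feature can be selected in every
  # (fold, wavelet) cell
  g5 <- make_frequency_grid(5, 2, 48)
  out <- tensor_cohort(seed = 7, n_a = 6, n_b = 6, n_regions = 5,
                       kappa_a = 0.95, kappa_b = 0.05,
                       pairs = cbind(c(1, 3), c(2, 4)), grid = g5)
  k_best <- 2
  rob <- feature_robustness_map(out$tensor, out$subjects, band = "alpha",
                                k_best = k_best)
  expect_true(all(rob$weight >= -1 & rob$weight <= 0))
  # every (fold, wavelet) selects exactly k_best features
  expect_equal(sum(rob$weight), -k_best)
  # the two dominant planted pairs are selected everywhere, others never
  expect_equal(rob$weight[rob$pair %in% c(pair_index(1, 2, 5), pair_index(3, 4, 5))],
               c(-1, -1))
  expect_true(all(rob$weight[!rob$pair %in% c(pair_index(1, 2, 5), pair_index(3, 4, 5))] == 0))
})
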