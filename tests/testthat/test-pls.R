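grid <- test_grid()

test_that("the element matrix flattens the tensor frequency-major with exact round trip", {
  out <- tensor_cohort(seed = 1, n_a = 2, n_b = 2, n_regions = 3,
                       pairs = cbind(1, 2),
                       grid = make_frequency_grid(2, 8, 12))
  em <- build_element_matrix(out$tensor, out$subjects)
  expect_equal(dim(em$x), c(4, 2 * 3))
  expect_equal(nrow(em$labels), 6)
  # exhaustive round trip: every element maps back to its tensor cell
  for (e in seq_len(6)) {
    f <- em$labels$freq_index[e]
    p <- em$labels$pair[e]
    for (s in seq_len(4)) {
      row <- match(em$subject_id[s], out$tensor$subject_ids)
      expect_equal(em$x[s, e], unname(out$tensor$plv[row, f, p]))
    }
  }
  # rows are blocked patients first
  expect_equal(as.character(unique(em$group)), c("patient", "control"))
  # element count formula at full scale: 30 x 4005
  expect_equal(30 * 90 * 89 / 2, 120150)
})

test_that("two-group contrast PLS is rank one with conserved energy", {
  out <- tensor_cohort(seed = 2, n_a = 6, n_b = 6)
  em <- build_element_matrix(out$tensor, out$subjects)
  fit <- contrast_pls(em)
  d <- fit$singular_values
  # exactly one nonzero singular value
  expect_gt(d[1], 0)
  expect_lt(d[2] / d[1], 1e-10)
  # energy conservation and reconstruction
  expect_equal(sum(d^2), sum(fit$cross^2), tolerance = 1e-10)
  rec <- fit$left %*% diag(d) %*% t(fit$saliences)
  expect_equal(unname(rec), unname(fit$cross), tolerance = 1e-10)
  # left vector is antisymmetric across the two groups
  expect_equal(fit$left[1, 1], -fit$left[2, 1], tolerance = 1e-10)
})

test_that("contrast saliences concentrate on a planted element and vanish without effects", {
  # rank-1 construction: one element carries the whole group difference
  x <- matrix(1, 6, 5)
  x[1:3, 4] <- 3
  em <- structure(list(
    x = x, group = factor(rep(c("patient", "control"), each = 3),
                          levels = c("patient", "control")),
    subject_id = sprintf("S%d", 1:6),
    labels = tibble::tibble(element = 1:5, freq_index = 1L,
                            frequency_hz = 10, pair = 1:5, i = 1L, j = 2L),
    grid = grid, n_regions = 3), class = "plv_elements")
  fit <- contrast_pls(em)
  sal <- abs(fit$saliences[, 1])
  expect_gte(sal[4]^2 / sum(sal^2), 0.99)
  # identical group means: zero singular values
  em$x <- matrix(rep(1:5, each = 6), 6, 5)
  expect_lt(max(contrast_pls(em)$singular_values), 1e-12)
  # a group with fewer than 2 subjects is rejected
  bad <- em
  bad$group <- factor(c("patient", rep("control", 5)),
                      levels = c("patient", "control"))
  expect_error(contrast_pls(bad), ">= 2")
})

test_that("behavioural PLS recovers a behaviour that copies one element", {
  out <- tensor_cohort(seed = 3, n_a = 8, n_b = 4)
  em <- build_element_matrix(out$tensor, out$subjects)
  pat <- em$group == "patient"
  beh <- rep(NA_real_, length(em$group))
  beh[pat] <- em$x[pat, 17]
  fit <- behavioural_pls(em, beh)
  expect_equal(which.max(abs(fit$saliences[, 1])), 17L)
  expect_equal(drop(fit$left), 1, tolerance = 0.02)
  # zero-variance behaviour rejected
  expect_error(behavioural_pls(em, ifelse(pat, 1, NA)), "zero-variance")
})

test_that("latent-variable permutation p-values detect planted contrasts and stay at the add-one floor", {
  out <- tensor_cohort(seed = 4, n_a = 10, n_b = 10)
  em <- build_element_matrix(out$tensor, out$subjects)
  ps <- vapply(1:5, function(seed) {
    o <- tensor_cohort(seed = seed + 40, n_a = 10, n_b = 10)
    e <- build_element_matrix(o$tensor, o$subjects)
    lv_permutation_test(e, "contrast", n_perm = 199, seed = seed)$p_value[1]
  }, numeric(1))
  expect_true(all(ps <= 0.01))
  # observed beating every permutation gives exactly 1/(n_perm + 1)
  res <- lv_permutation_test(em, "contrast", n_perm = 199, seed = 1)
  null <- attr(res, "null")
  expect_equal(res$p_value[1],
               (1 + sum(null[1, ] >= res$singular_value[1])) / 200)
  expect_equal(res$p_value[1], 1 / 200)
})

test_that("permutation p-values are calibrated for null contrasts and behaviours", {
  p_contrast <- vapply(1:10, function(seed) {
    o <- null_cohort(seed = seed, n_a = 6, n_b = 6, n_regions = 6)
    e <- build_element_matrix(o$tensor, o$subjects)
    lv_permutation_test(e, "contrast", n_perm = 49, seed = seed)$p_value[1]
  }, numeric(1))
  expect_lte(sum(p_contrast <= 0.05), 2)
  # behaviour independent of all elements
  p_beh <- vapply(1:10, function(seed) {
    o <- null_cohort(seed = seed + 50, n_a = 10, n_b = 4, n_regions = 6)
    e <- build_element_matrix(o$tensor, o$subjects)
    beh <- rep(NA_real_, length(e$group))
    beh[e$group == "patient"] <- withr::with_seed(seed, rnorm(10))
    lv_permutation_test(e, "behavioural", behaviour = beh,
                        n_perm = 49, seed = seed)$p_value[1]
  }, numeric(1))
  expect_lte(sum(p_beh <= 0.05), 2)
})

test_that("bootstrap ratios flag planted elements and spare noise elements", {
  hits <- 0
  noise_ok <- 0
  for (seed in 1:10) {
    out <- tensor_cohort(seed = seed, n_a = 10, n_b = 10)
    em <- build_element_matrix(out$tensor, out$subjects)
    bsr <- bootstrap_ratios(em, "contrast", n_boot = 99, seed = seed)
    planted <- bsr$table$freq_index == nearest_freq(grid, 11) &
      bsr$table$pair %in% c(pair_index(1, 2, 8), pair_index(3, 4, 8))
    if (all(abs(bsr$table$ratio[planted]) >= 3)) hits <- hits + 1
    if (mean(abs(bsr$table$ratio[!planted]) < 3, na.rm = TRUE) >= 0.95) {
      noise_ok <- noise_ok + 1
    }
  }
  expect_gte(hits, 9)
  expect_gte(noise_ok, 9)
  out <- tensor_cohort(seed = 1)
  em <- build_element_matrix(out$tensor, out$subjects)
  expect_error(bootstrap_ratios(em, "contrast", n_boot = 1), "n_boot")
})

test_that("tail counts respect the quantile definition and symmetry", {
  out <- null_cohort(seed = 5, n_a = 8, n_b = 8, n_regions = 8)
  em <- build_element_matrix(out$tensor, out$subjects)
  bsr <- bootstrap_ratios(em, "contrast", n_boot = 60, seed = 2)
  tails <- tail_counts(bsr, tail_q = 0.05)
  n_elem <- nrow(bsr$table)
  # each tail totals floor(q * n) within 1 (ties fall inside)
  expect_lte(abs(sum(tails$lower_tail) - floor(0.05 * n_elem)), 1)
  expect_lte(abs(sum(tails$upper_tail) - floor(0.05 * n_elem)), 1)
  # symmetric null ratios give near-equal tails
  expect_lt(abs(sum(tails$lower_tail) - sum(tails$upper_tail)),
            0.5 * sum(tails$upper_tail) + 5)
  expect_error(tail_counts(bsr, tail_q = 0.6), "tail_q")
})

test_that("planted alpha hyperconnectivity shows up in the expected tail at alpha", {
  # patients hyperconnected (kappa_a > kappa_b): group contrast places
  # planted elements in one tail, concentrated at the planted frequency
  out <- tensor_cohort(seed = 6, n_a = 10, n_b = 10,
                       pairs = cbind(c(1, 3, 5, 7), c(2, 4, 6, 8)))
  em <- build_element_matrix(out$tensor, out$subjects)
  bsr <- bootstrap_ratios(em, "contrast", n_boot = 99, seed = 3)
  tails <- tail_counts(bsr, tail_q = 0.02)
  planted_f <- nearest_freq(grid, 11)
  richer <- pmax(tails$lower_tail, tails$upper_tail)
  expect_equal(which.max(richer), planted_f)
})

test_that("the proportion z-test matches an independent oracle", {
  res <- proportion_ztest(100, 4005, 60, 4005)
  expect_equal(res$z, 3.19, tolerance = 0.01)
  expect_equal(res$p_value, 0.0014, tolerance = 0.05)
  # independent oracle: chi-square equivalence without continuity correction
  pt <- prop.test(c(100, 60), c(4005, 4005), correct = FALSE)
  expect_equal(res$z^2, unname(pt$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, pt$p.value, tolerance = 1e-12)
  # degenerate cases
  expect_equal(proportion_ztest(50, 4005, 50, 4005)$z, 0)
  expect_equal(proportion_ztest(0, 100, 0, 100)$p_value, 1)
  expect_error(proportion_ztest(10, 5, 1, 5), "count")
})

test_that("band-averaged threshold maps equal a brute-force filter", {
  out <- tensor_cohort(seed = 7, n_a = 6, n_b = 6, n_regions = 6)
  em <- build_element_matrix(out$tensor, out$subjects)
  bsr <- bootstrap_ratios(em, "contrast", n_boot = 50, seed = 4)
  m <- band_threshold_map(bsr, "alpha", threshold = 1, side = "above")
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 6))
  # brute force over all pairs
  f_idx <- grid$freq_index[grid$band == "alpha"]
  for (p in seq_len(15)) {
    ij <- pair_unindex(p, 6)
    avg <- mean(bsr$table$ratio[bsr$table$pair == p &
                                  bsr$table$freq_index %in% f_idx])
    expect_equal(m[ij$i, ij$j], if (avg > 1) avg else 0)
  }
  # constant ratios: all survive above a low threshold, none a high one
  bsr2 <- bsr
  bsr2$table$ratio <- rep(2, nrow(bsr$table))
  m2 <- band_threshold_map(bsr2, "alpha", threshold = 1)
  expect_true(all(m2[upper.tri(m2)] == 2))
  bsr2$table$ratio <- rep(0.5, nrow(bsr$table))
  expect_true(all(band_threshold_map(bsr2, "alpha", threshold = 1) == 0))
})

test_that("tidiers expose cross-validation, PLS and bootstrap results as tibbles", {
  out <- tensor_cohort(seed = 8, n_a = 5, n_b = 5, n_regions = 5)
  feats <- feature_set(out$tensor, out$subjects, nearest_freq(grid, 11))
  cv <- loocv(feats)
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(glance(cv)$n_folds, 10)
  em <- build_element_matrix(out$tensor, out$subjects)
  fit <- contrast_pls(em)
  expect_equal(nrow(tidy(fit)), nrow(em$labels))
  expect_equal(glance(fit)$prop_var[1], 1, tolerance = 1e-10)
  bsr <- bootstrap_ratios(em, "contrast", n_boot = 30, seed = 1)
  expect_true(all(c("salience", "se", "ratio") %in% names(tidy(bsr))))
  null <- permutation_null(feats, n_perm = 5, seed = 1)
  expect_equal(nrow(tidy(null)), 5)
  expect_equal(glance(null)$n_perm, 5)
})
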