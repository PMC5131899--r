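# Mean-centred (contrast) and behavioural partial least squares on the
# subjects x elements matrix, with permutation tests for latent-variable
# significance, bootstrap ratios for element stability, tail-count
# profiling across frequencies, and two-sample proportion z-tests.

#' Build the subjects-by-elements matrix
#'
#' Flattens a connectivity tensor into the PLS data matrix: rows are
#' subjects blocked by group (patients first), columns are elements --
#' every (frequency, pair) combination, frequency-major. With 30
#' frequencies and 90 regions this gives 30 x 4005 = 120,150 elements.
#'
#' @param tensor A `plv_tensor`.
#' @param subjects Subject tibble with `subject_id`, `group`.
#'
#' @return An object of class `plv_elements`: `x` (matrix), `group`
#'   (factor patient/control per row), `subject_id`, `labels` (tibble:
#'   `element`, `freq_index`, `frequency_hz`, `pair`, `i`, `j`), `grid`.
#' @export
build_element_matrix <- function(tensor, subjects) {
  stopifnot(inherits(tensor, "plv_tensor"))
  check_subject_table(subjects)
  if (!setequal(subjects$subject_id, tensor$subject_ids) ||
      anyNA(subjects$group)) {
    plv_abort("every tensor subject needs a group")
  }
  ord <- order(match(subjects$group, c("patient", "control")))
  subj <- subjects[ord, ]
  row_idx <- match(subj$subject_id, tensor$subject_ids)
  n_freq <- nrow(tensor$grid)
  n_pairs <- nrow(tensor$pairs)
  x <- matrix(NA_real_, length(row_idx), n_freq * n_pairs)
  for (f in seq_len(n_freq)) {
    x[, (f - 1) * n_pairs + seq_len(n_pairs)] <- tensor$plv[row_idx, f, ]
  }
  labels <- tibble::tibble(
    element = seq_len(n_freq * n_pairs),
    freq_index = rep(seq_len(n_freq), each = n_pairs),
    frequency_hz = rep(tensor$grid$frequency_hz, each = n_pairs),
    pair = rep(tensor$pairs$pair, times = n_freq),
    i = rep(tensor$pairs$i, times = n_freq),
    j = rep(tensor$pairs$j, times = n_freq)
  )
  structure(
    list(x = x, group = factor(subj$group, levels = c("patient", "control")),
         subject_id = subj$subject_id, labels = labels, grid = tensor$grid,
         n_regions = tensor$n_regions),
    class = "plv_elements"
  )
}

# Cross-block matrix for the two modes.
# contrast: deviations of group means from their grand mean (one row per
# group); behavioural: per-element Pearson correlations with the behaviour
# (one row). Returns list(cross, groups_used).
cross_block <- function(x, group = NULL, behaviour = NULL) {
  if (!is.null(behaviour)) {
    if (sd(behaviour) == 0) plv_abort("zero-variance behaviour")
    xc <- sweep(x, 2, colMeans(x))
    bc <- behaviour - mean(behaviour)
    sx <- sqrt(colSums(xc^2))
    r <- drop(crossprod(xc, bc)) / (sx * sqrt(sum(bc^2)))
    r[sx == 0] <- 0
    matrix(r, 1, ncol(x))
  } else {
    gm <- rowsum(x, group) / as.vector(table(group))
    sweep(gm, 2, colMeans(gm))
  }
}

new_pls <- function(mode, d, u, v, labels, extra = list()) {
  structure(
    c(list(mode = mode, singular_values = d, left = u, saliences = v,
           labels = labels), extra),
    class = "plv_pls"
  )
}

#' Mean-centred contrast PLS
#'
#' Centres the per-group element means on their grand mean and takes the
#' singular value decomposition of the resulting groups x elements matrix.
#' With two groups exactly one singular value is nonzero; its left vector
#' is the (antisymmetric) group contrast and its right vector holds the
#' element saliences.
#'
#' @param em A `plv_elements` matrix from [build_element_matrix()].
#' @return A `plv_pls` object with `singular_values`, `left` (groups x LV),
#'   `saliences` (elements x LV), `labels`.
#' @export
contrast_pls <- function(em) {
  stopifnot(inherits(em, "plv_elements"))
  sizes <- table(em$group)
  if (length(sizes) < 2 || any(sizes < 2)) {
    plv_abort("need >= 2 groups with >= 2 subjects each")
  }
  m <- cross_block(em$x, group = em$group)
  sv <- svd(m)
  new_pls("contrast", sv$d, sv$u, sv$v, em$labels,
          list(group_levels = rownames(m), cross = m))
}

#' Behavioural PLS
#'
#' Correlates every element with a continuous per-subject behaviour (days
#' since injury in the motivating application), forming a 1 x elements
#' cross-block of Pearson correlations; its SVD has a single latent
#' variable whose saliences are proportional to the per-element
#' correlations. The left value reported is the overall correlation between
#' the latent brain score and the behaviour.
#'
#' @param em A `plv_elements` matrix.
#' @param behaviour Numeric per-subject values, in `em` row order (may be
#'   NA outside `subset`).
#' @param subset Which rows to use: "patient" (default, the typical
#'   behavioural design) or "all".
#' @return A `plv_pls` object; `left` holds the overall correlation.
#' @export
behavioural_pls <- function(em, behaviour, subset = c("patient", "all")) {
  stopifnot(inherits(em, "plv_elements"))
  subset <- match.arg(subset)
  rows <- if (subset == "patient") which(em$group == "patient") else
    seq_along(em$group)
  b <- behaviour[rows]
  if (anyNA(b)) plv_abort("behaviour missing for included subjects")
  x <- em$x[rows, , drop = FALSE]
  m <- cross_block(x, behaviour = b)
  s <- sqrt(sum(m^2))
  v <- if (s > 0) t(m) / s else t(m)
  overall <- if (s > 0) cor(drop(x %*% v), b) else NA_real_
  new_pls("behavioural", s, matrix(overall, 1, 1), v, em$labels,
          list(rows = rows, behaviour = b))
}

#' Permutation test for latent-variable significance
#'
#' Contrast mode permutes subjects across groups; behavioural mode shuffles
#' the behaviour vector. Each permutation recomputes the cross-block and
#' its singular values; `p = (1 + #{permuted s >= observed s}) / (n_perm + 1)`
#' per latent variable.
#'
#' @param em A `plv_elements` matrix.
#' @param mode "contrast" or "behavioural".
#' @param behaviour Required for behavioural mode (full-length, `em` row
#'   order).
#' @param subset Passed to [behavioural_pls()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#'
#' @return A tibble with `lv`, `singular_value`, `p_value`; the permuted
#'   singular values are attached as attribute `"null"`.
#' @export
lv_permutation_test <- function(em, mode = c("contrast", "behavioural"),
                                behaviour = NULL, subset = "patient",
                                n_perm = 500, seed = 1) {
  mode <- match.arg(mode)
  n_perm <- check_count(n_perm, "n_perm")
  if (mode == "contrast") {
    obs <- contrast_pls(em)$singular_values
    null <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        perm <- em
        perm$group <- sample(em$group)
        contrast_pls(perm)$singular_values
      }, numeric(length(obs)))
    })
  } else {
    fit <- behavioural_pls(em, behaviour, subset)
    obs <- fit$singular_values
    rows <- fit$rows
    null <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        beh <- behaviour
        beh[rows] <- sample(beh[rows])
        behavioural_pls(em, beh, subset)$singular_values
      }, numeric(length(obs)))
    })
  }
  null <- matrix(null, nrow = length(obs))
  out <- tibble::tibble(
    lv = seq_along(obs),
    singular_value = obs,
    p_value = vapply(seq_along(obs), function(l) {
      (1 + sum(null[l, ] >= obs[l])) / (n_perm + 1)
    }, numeric(1))
  )
  attr(out, "null") <- null
  out
}

#' Bootstrap ratios for element stability
#'
#' Resamples subjects with replacement within groups (or within the
#' behavioural subset), recomputes the first latent variable's saliences,
#' aligns each resample's sign to the original saliences, and reports
#' original salience / bootstrap SE per element -- interpreted like a
#' z-score (|ratio| >= 3 is roughly 95% confidence).
#'
#' @inheritParams lv_permutation_test
#' @param n_boot Number of bootstrap samples (>= 2).
#'
#' @return An object of class `plv_bsr`: tibble-like list with `table`
#'   (tibble: `element`, `freq_index`, `frequency_hz`, `pair`, `i`, `j`,
#'   `salience`, `se`, `ratio`), `n_boot`, `grid`, `n_regions`.
#' @export
bootstrap_ratios <- function(em, mode = c("contrast", "behavioural"),
                             behaviour = NULL, subset = "patient",
                             n_boot = 500, seed = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(n_boot) || n_boot < 2) {
    plv_abort("n_boot must be at least 2 (SE undefined otherwise)")
  }
  n_boot <- check_count(n_boot, "n_boot", min = 2)
  saliences_of <- function(rows_idx, beh = NULL) {
    if (mode == "contrast") {
      m <- cross_block(em$x[rows_idx, , drop = FALSE], group = em$group[rows_idx])
      sv <- svd(m, nu = 0, nv = 1)
      sv$v[, 1]
    } else {
      m <- cross_block(em$x[rows_idx, , drop = FALSE], behaviour = beh)
      s <- sqrt(sum(m^2))
      if (s > 0) drop(m) / s else drop(m)
    }
  }
  if (mode == "contrast") {
    groups <- split(seq_along(em$group), em$group)
    groups <- groups[lengths(groups) > 0]
    if (any(lengths(groups) < 2)) plv_abort("each group needs >= 2 subjects")
    v0 <- saliences_of(seq_along(em$group))
  } else {
    fit <- behavioural_pls(em, behaviour, subset)
    rows <- fit$rows
    if (length(rows) < 2) plv_abort("behavioural subset needs >= 2 subjects")
    v0 <- drop(fit$saliences)
  }
  boots <- withr::with_seed(seed, {
    out <- matrix(NA_real_, length(v0), n_boot)
    for (b in seq_len(n_boot)) {
      for (retry in 1:100) {
        if (mode == "contrast") {
          idx <- unlist(lapply(groups, function(g) sample(g, replace = TRUE)),
                        use.names = FALSE)
          distinct_ok <- all(vapply(groups, function(g) {
            length(unique(intersect(idx, g))) >= 2
          }, logical(1)))
          beh_b <- NULL
        } else {
          take <- sample(seq_along(rows), replace = TRUE)
          idx <- rows[take]
          beh_b <- fit$behaviour[take]
          distinct_ok <- length(unique(idx)) >= 2 && sd(beh_b) > 0
        }
        if (distinct_ok) break
        if (retry == 100) plv_abort("degenerate bootstrap resamples")
      }
      vb <- saliences_of(idx, beh_b)
      if (sum(vb * v0) < 0) vb <- -vb
      out[, b] <- vb
    }
    out
  })
  se <- apply(boots, 1, sd)
  ratio <- ifelse(se > 0, v0 / se, NA_real_)
  tab <- em$labels
  tab$salience <- v0
  tab$se <- se
  tab$ratio <- ratio
  structure(list(table = tab, n_boot = n_boot, grid = em$grid,
                 n_regions = em$n_regions),
            class = "plv_bsr")
}

#' @export
print.plv_bsr <- function(x, ...) {
  cat(sprintf("<plv_bsr> %d elements, %d bootstrap samples; |ratio| >= 3: %d\n",
              nrow(x$table), x$n_boot,
              sum(abs(x$table$ratio) >= 3, na.rm = TRUE)))
  invisible(x)
}

#' Tail counts of bootstrap ratios per frequency
#'
#' Thresholds are the empirical `tail_q` and `1 - tail_q` quantiles
#' (linear interpolation) of the pooled bootstrap-ratio distribution; per
#' grid frequency, the number of elements at or beyond each threshold is
#' counted (ties at the threshold fall inside the tail).
#'
#' @param bsr A `plv_bsr` object.
#' @param tail_q Tail fraction, `0 < tail_q < 0.5` (default 0.01).
#' @return A tibble with `freq_index`, `frequency_hz`, `band`,
#'   `lower_tail`, `upper_tail`.
#' @export
tail_counts <- function(bsr, tail_q = 0.01) {
  stopifnot(inherits(bsr, "plv_bsr"))
  if (tail_q <= 0 || tail_q >= 0.5) plv_abort("tail_q must lie in (0, 0.5)")
  r <- bsr$table$ratio
  thr <- quantile(r, c(tail_q, 1 - tail_q), na.rm = TRUE, names = FALSE)
  tab <- bsr$table
  out <- bsr$grid
  out$lower_tail <- vapply(out$freq_index, function(f) {
    sum(tab$ratio[tab$freq_index == f] <= thr[1], na.rm = TRUE)
  }, numeric(1))
  out$upper_tail <- vapply(out$freq_index, function(f) {
    sum(tab$ratio[tab$freq_index == f] >= thr[2], na.rm = TRUE)
  }, numeric(1))
  attr(out, "thresholds") <- thr
  class(out) <- setdiff(class(out), "plv_grid")
  out
}

#' Two-sample proportion z-test
#'
#' Pooled-variance two-sample z statistic for a difference in proportions,
#' without continuity correction, with a two-sided normal p-value. Used to
#' compare per-frequency tail counts (each out of the 4005 connections).
#'
#' @param count1,n1 Successes and total in sample 1.
#' @param count2,n2 Successes and total in sample 2.
#' @return A tibble with `z`, `p_value`, `prop1`, `prop2`.
#' @export
#' @examples
#' proportion_ztest(100, 4005, 60, 4005)
proportion_ztest <- function(count1, n1, count2, n2) {
  if (n1 <= 0 || n2 <= 0 || count1 > n1 || count2 > n2 ||
      count1 < 0 || count2 < 0) {
    plv_abort("counts must satisfy 0 <= count <= n with n > 0")
  }
  p1 <- count1 / n1
  p2 <- count2 / n2
  pp <- (count1 + count2) / (n1 + n2)
  var_p <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  if (var_p == 0) {
    return(tibble::tibble(z = 0, p_value = 1, prop1 = p1, prop2 = p2))
  }
  z <- (p1 - p2) / sqrt(var_p)
  tibble::tibble(z = z, p_value = 2 * pnorm(-abs(z)), prop1 = p1, prop2 = p2)
}

#' Band-averaged thresholded bootstrap-ratio map
#'
#' Averages each connection's bootstrap ratio across the wavelets of a
#' canonical band, zeroes entries failing a one-sided threshold (`ratio >
#' threshold` for side "above", `ratio < threshold` for side "below"), and
#' returns the symmetric region x region matrix.
#'
#' @param bsr A `plv_bsr` object.
#' @param band Canonical band name.
#' @param threshold One-sided threshold (e.g. 1, or -1 with side "below").
#' @param side "above" keeps mean ratios strictly greater than `threshold`;
#'   "below" keeps those strictly smaller.
#' @param region_names Optional region names for dimnames.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
band_threshold_map <- function(bsr, band, threshold = 1,
                               side = c("above", "below"),
                               region_names = NULL) {
  stopifnot(inherits(bsr, "plv_bsr"))
  side <- match.arg(side)
  f_idx <- bsr$grid$freq_index[bsr$grid$band == band]
  if (length(f_idx) == 0) plv_abort(sprintf("band '%s' is empty", band))
  tab <- bsr$table[bsr$table$freq_index %in% f_idx, ]
  agg <- rowsum(tab$ratio, tab$pair) / length(f_idx)
  pairs <- pair_unindex(as.integer(rownames(agg)), bsr$n_regions)
  keep <- if (side == "above") agg[, 1] > threshold else agg[, 1] < threshold
  vals <- ifelse(keep, agg[, 1], 0)
  n <- bsr$n_regions
  nm <- region_names %||% default_region_names(n)
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  m[cbind(pairs$i, pairs$j)] <- vals
  m + t(m)
}
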