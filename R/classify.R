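# Nested leave-one-out SVM classification with ROC-area feature ranking,
# label-shuffle permutation nulls, decision-boundary confidence, and the
# feature-robustness connection map.

# ---- feature sets -----------------------------------------------------------

#' Assemble a feature set from a connectivity tensor
#'
#' Flattens the requested frequency slices of a tensor into a subjects x
#' features matrix with class labels (+1 = patient, -1 = control) and
#' per-column (frequency, pair) provenance.
#'
#' @param tensor A `plv_tensor`.
#' @param subjects Subject tibble with `subject_id` and `group`
#'   ("patient"/"control"), in tensor subject order.
#' @param freq_index Frequency indices to include (default: all).
#'
#' @return An object of class `plv_features`: list with `x` (matrix),
#'   `labels` (+1/-1), `subject_id`, `info` (tibble: `feature`,
#'   `freq_index`, `frequency_hz`, `pair`).
#' @export
feature_set <- function(tensor, subjects, freq_index = NULL) {
  stopifnot(inherits(tensor, "plv_tensor"))
  check_subject_table(subjects)
  if (!identical(subjects$subject_id, tensor$subject_ids)) {
    plv_abort("subject table does not match tensor subject order")
  }
  freq_index <- freq_index %||% tensor$grid$freq_index
  n_pairs <- nrow(tensor$pairs)
  x <- do.call(cbind, lapply(freq_index, function(f) tensor$plv[, f, ]))
  fidx <- rep(freq_index, each = n_pairs)
  pidx <- rep(tensor$pairs$pair, times = length(freq_index))
  info <- tibble::tibble(
    feature = seq_len(ncol(x)),
    freq_index = fidx,
    frequency_hz = tensor$grid$frequency_hz[fidx],
    pair = pidx
  )
  labels <- ifelse(subjects$group == "patient", 1, -1)
  if (length(unique(labels)) < 2) plv_abort("both classes must be present")
  if (anyNA(x)) plv_abort("feature matrix contains missing values")
  structure(list(x = x, labels = labels, subject_id = subjects$subject_id,
                 info = info),
            class = "plv_features")
}

#' Build a feature set from a plain matrix
#'
#' For feature matrices that do not come from a connectivity tensor (or in
#' resampling loops): wraps a samples x features matrix and labels into the
#' `plv_features` container the classification functions consume.
#'
#' @param x Numeric matrix, samples x features.
#' @param labels Class labels, +1 (patient) / -1 (control).
#' @param info Optional per-column provenance tibble (`feature`,
#'   `freq_index`, `frequency_hz`, `pair`).
#' @param subject_id Optional subject identifiers.
#' @return A `plv_features` object.
#' @export
as_feature_set <- function(x, labels, info = NULL, subject_id = NULL) {
  x <- as.matrix(x)
  stopifnot(length(labels) == nrow(x))
  info <- info %||% tibble::tibble(feature = seq_len(ncol(x)),
                                   freq_index = 1L,
                                   frequency_hz = NA_real_,
                                   pair = seq_len(ncol(x)))
  structure(list(x = x, labels = labels,
                 subject_id = subject_id %||% sprintf("S%02d", seq_len(nrow(x))),
                 info = info),
            class = "plv_features")
}

# internal alias
new_features <- as_feature_set

# ---- univariate separability ------------------------------------------------

#' ROC-area separability of one feature
#'
#' Mann-Whitney area under the ROC curve by exhaustive pair counting (ties
#' contribute 1/2), folded as `max(AUC, 1 - AUC)` so that a feature
#' discriminating in either direction scores equally. A constant column
#' scores exactly 0.5.
#'
#' @param x Numeric feature column.
#' @param labels Class labels, +1 (patient) / -1 (control).
#' @return Separability in `[0.5, 1]`.
#' @export
#' @examples
#' auc_separability(c(0.2, 0.4, 0.3, 0.5), c(1, 1, -1, -1))  # 0.75
auc_separability <- function(x, labels) {
  pos <- x[labels > 0]
  neg <- x[labels <= 0]
  if (length(pos) == 0 || length(neg) == 0) {
    plv_abort("both classes must be present")
  }
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- sum(cmp) / (length(pos) * length(neg))
  max(auc, 1 - auc)
}

#' Rank features by ROC-area separability
#'
#' Orders feature columns by folded AUC, descending; ties break
#' deterministically by (lower frequency index, lower pair index, lower
#' column index).
#'
#' @param features A `plv_features` object (training data only).
#' @return Integer vector of column indices, best first.
#' @export
rank_features <- function(features) {
  stopifnot(inherits(features, "plv_features"))
  scores <- apply(features$x, 2, auc_separability, labels = features$labels)
  order(-scores, features$info$freq_index, features$info$pair,
        features$info$feature)
}

# ---- linear max-margin classifier -------------------------------------------

#' Fit a linear max-margin (soft-margin SVM) classifier
#'
#' Thin wrapper around a linear-kernel support vector machine. The returned
#' weight vector and bias are sign-normalised so that the positive side of
#' the hyperplane `w'x + b = 0` is the patient (+1) class.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Labels, +1 / -1; both classes required.
#' @param cost Soft-margin cost parameter (default 1).
#' @return An object of class `plv_svm`: list with `weights`, `bias`, `cost`.
#' @export
fit_linear_maxmargin <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2) plv_abort("both classes must be present")
  fit <- e1071::svm(x = x, y = factor(y, levels = c(-1, 1)),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  d <- drop(x %*% w) + b
  if (mean(d[y > 0]) < mean(d[y <= 0])) {
    w <- -w
    b <- -b
  }
  structure(list(weights = w, bias = b, cost = cost), class = "plv_svm")
}

#' Predict with a linear max-margin model
#'
#' @param object A `plv_svm` model.
#' @param newdata Numeric matrix or vector of features.
#' @param ... Unused.
#' @return A tibble with `decision` (`w'x + b`), `distance` (signed
#'   Euclidean distance `(w'x + b) / ||w||`), `predicted` (+1/-1).
#' @export
predict.plv_svm <- function(object, newdata, ...) {
  x <- matrix(newdata, ncol = length(object$weights))
  dec <- drop(x %*% object$weights) + object$bias
  nrm <- sqrt(sum(object$weights^2))
  tibble::tibble(
    decision = dec,
    distance = if (nrm > 0) dec / nrm else 0,
    predicted = ifelse(dec > 0, 1, -1)
  )
}

# ---- leave-one-out cross-validation -----------------------------------------

# Column-wise z-scoring with training statistics; zero-SD columns pass
# through centred only.
scale_train_test <- function(train, test) {
  mu <- colMeans(train)
  sg <- apply(train, 2, sd)
  sg[sg == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sg, "/"),
       test = (test - mu) / sg)
}

#' Leave-one-out cross-validated classification
#'
#' Each subject is held out once; feature ranking (when `k_best` is given)
#' and column standardisation use the training fold only, so the held-out
#' subject never leaks into selection or fitting. Records per-fold
#' predictions, signed distances to the decision boundary, and selected
#' features.
#'
#' @param features A `plv_features` object with `m >= 4` subjects.
#' @param k_best Number of top-ranked features to keep per fold (`NULL`
#'   keeps all; values above the feature count clamp with a warning).
#' @param cost Soft-margin cost (default 1).
#' @param standardize Z-score columns with training-fold statistics
#'   (default TRUE).
#'
#' @return An object of class `plv_cv`: `folds` tibble (`subject_id`,
#'   `truth`, `predicted`, `distance`, `selected` list-column), and
#'   aggregate `accuracy`, `sensitivity`, `specificity` (patient = positive
#'   class).
#' @export
loocv <- function(features, k_best = NULL, cost = 1, standardize = TRUE) {
  stopifnot(inherits(features, "plv_features"))
  m <- nrow(features$x)
  if (m < 4) plv_abort("need at least 4 subjects for leave-one-out")
  n_feat <- ncol(features$x)
  if (!is.null(k_best)) {
    k_best <- check_count(k_best, "k_best")
    if (k_best > n_feat) {
      warn(sprintf("k_best = %d exceeds %d features; clamped", k_best, n_feat))
      k_best <- n_feat
    }
  }
  folds <- purrr::map(seq_len(m), function(j) {
    tr_x <- features$x[-j, , drop = FALSE]
    tr_y <- features$labels[-j]
    te_x <- features$x[j, ]
    sel <- seq_len(n_feat)
    if (!is.null(k_best)) {
      tr_feats <- new_features(tr_x, tr_y, features$info)
      sel <- rank_features(tr_feats)[seq_len(k_best)]
    }
    tr_x <- tr_x[, sel, drop = FALSE]
    te_x <- te_x[sel]
    if (standardize) {
      sc <- scale_train_test(tr_x, te_x)
      tr_x <- sc$train
      te_x <- sc$test
    }
    model <- fit_linear_maxmargin(tr_x, tr_y, cost)
    pred <- predict(model, te_x)
    tibble::tibble(subject_id = features$subject_id[j],
                   truth = features$labels[j],
                   predicted = pred$predicted,
                   distance = pred$distance,
                   selected = list(sort(sel)))
  })
  folds <- dplyr::bind_rows(folds)
  new_cv(folds)
}

new_cv <- function(folds) {
  tp <- sum(folds$truth > 0 & folds$predicted > 0)
  tn <- sum(folds$truth < 0 & folds$predicted < 0)
  p <- sum(folds$truth > 0)
  n <- sum(folds$truth < 0)
  structure(
    list(folds = folds,
         accuracy = (tp + tn) / (p + n),
         sensitivity = tp / p,
         specificity = tn / n),
    class = "plv_cv"
  )
}

#' @export
print.plv_cv <- function(x, ...) {
  cat(sprintf(
    "<plv_cv> %d folds | accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
    nrow(x$folds), x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

# ---- feature-subset schemes -------------------------------------------------

#' Classification accuracy per wavelet frequency
#'
#' One leave-one-out run per grid frequency, using all region pairs at that
#' frequency as features (no further selection).
#'
#' @inheritParams feature_set
#' @param cost Soft-margin cost.
#' @return A tibble with one row per frequency: `freq_index`,
#'   `frequency_hz`, `band`, `sensitivity`, `specificity`, `accuracy`.
#' @export
accuracy_by_wavelet <- function(tensor, subjects, cost = 1) {
  purrr::map_dfr(tensor$grid$freq_index, function(f) {
    cv <- loocv(feature_set(tensor, subjects, f), cost = cost)
    tibble::tibble(freq_index = f,
                   frequency_hz = tensor$grid$frequency_hz[f],
                   band = tensor$grid$band[f],
                   sensitivity = cv$sensitivity,
                   specificity = cv$specificity,
                   accuracy = cv$accuracy)
  })
}

#' Classification accuracy per canonical band
#'
#' One leave-one-out run per canonical band, pooling all (frequency, pair)
#' features whose grid frequency falls in the band.
#'
#' @inheritParams accuracy_by_wavelet
#' @return A tibble with one row per non-empty band.
#' @export
accuracy_by_band <- function(tensor, subjects, cost = 1) {
  bands <- levels(tensor$grid$band)
  present <- bands[bands %in% as.character(tensor$grid$band)]
  purrr::map_dfr(present, function(b) {
    f_idx <- tensor$grid$freq_index[tensor$grid$band == b]
    cv <- loocv(feature_set(tensor, subjects, f_idx), cost = cost)
    tibble::tibble(band = factor(b, levels = bands),
                   n_frequencies = length(f_idx),
                   sensitivity = cv$sensitivity,
                   specificity = cv$specificity,
                   accuracy = cv$accuracy)
  })
}

# ---- permutation null -------------------------------------------------------

#' Label-shuffle permutation null for classification accuracy
#'
#' Each permutation shuffles the class labels across subjects and re-runs
#' the full nested leave-one-out pipeline, including per-fold feature
#' ranking, so selection bias is reproduced under the null. The p-value uses
#' the add-one estimator `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param features A `plv_features` object.
#' @param k_best,cost Passed to [loocv()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the shuffles.
#'
#' @return An object of class `plv_null`: `observed`, `accuracies` (length
#'   `n_perm`), `p_value`, `n_perm`.
#' @export
permutation_null <- function(features, k_best = NULL, cost = 1,
                             n_perm = 500, seed = 1) {
  n_perm <- check_count(n_perm, "n_perm")
  observed <- loocv(features, k_best, cost)$accuracy
  accs <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- features
      perm$labels <- sample(features$labels)
      loocv(perm, k_best, cost)$accuracy
    }, numeric(1))
  })
  structure(
    list(observed = observed, accuracies = accs,
         p_value = (1 + sum(accs >= observed)) / (n_perm + 1),
         n_perm = n_perm),
    class = "plv_null"
  )
}

#' @export
print.plv_null <- function(x, ...) {
  cat(sprintf("<plv_null> observed accuracy %.3f, p = %.4f (%d permutations)\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}

# ---- accuracy as a function of k --------------------------------------------

#' Accuracy curves over the number of selected features
#'
#' For every `k = 1, ..., k_max`, run leave-one-out classification keeping
#' the `k` features with the highest training-fold ROC area. Per-fold
#' rankings are computed once and reused across `k`.
#'
#' @param features A `plv_features` object (typically one band's features).
#' @param k_max Largest number of features (default 100; clamped to the
#'   feature count).
#' @param cost Soft-margin cost.
#'
#' @return An object of class `plv_kcurve`: `curves` tibble (`k`,
#'   `sensitivity`, `specificity`, `accuracy`), `best_k` (maximum accuracy,
#'   ties to the smaller k), `distances` matrix (subjects x k of signed
#'   fold distances), `selected` (list over k of per-fold selections),
#'   `labels`, `subject_id`.
#' @export
accuracy_vs_k <- function(features, k_max = 100, cost = 1) {
  stopifnot(inherits(features, "plv_features"))
  m <- nrow(features$x)
  n_feat <- ncol(features$x)
  if (k_max > n_feat) {
    warn(sprintf("k_max = %d exceeds %d features; clamped", k_max, n_feat))
    k_max <- n_feat
  }
  rankings <- purrr::map(seq_len(m), function(j) {
    rank_features(new_features(features$x[-j, , drop = FALSE],
                               features$labels[-j], features$info))
  })
  distances <- matrix(NA_real_, m, k_max)
  predicted <- matrix(NA_real_, m, k_max)
  selected <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    sel_k <- vector("list", m)
    for (j in seq_len(m)) {
      sel <- rankings[[j]][seq_len(k)]
      sel_k[[j]] <- sort(sel)
      sc <- scale_train_test(features$x[-j, sel, drop = FALSE],
                             features$x[j, sel])
      model <- fit_linear_maxmargin(sc$train, features$labels[-j], cost)
      pred <- predict(model, sc$test)
      distances[j, k] <- pred$distance
      predicted[j, k] <- pred$predicted
    }
    selected[[k]] <- sel_k
  }
  truth <- features$labels
  curves <- purrr::map_dfr(seq_len(k_max), function(k) {
    tibble::tibble(
      k = k,
      sensitivity = sum(truth > 0 & predicted[, k] > 0) / sum(truth > 0),
      specificity = sum(truth < 0 & predicted[, k] < 0) / sum(truth < 0),
      accuracy = mean(sign(predicted[, k]) == sign(truth))
    )
  })
  structure(
    list(curves = curves,
         best_k = curves$k[which.max(curves$accuracy)],
         distances = distances, selected = selected,
         labels = truth, subject_id = features$subject_id),
    class = "plv_kcurve"
  )
}

# ---- confidence vs clinical scores ------------------------------------------

#' Correlation between classification confidence and clinical scores
#'
#' For each number of selected features k, the Pearson correlation between
#' the signed distance to the decision boundary (positive = patient side;
#' negative distances mark misclassified patients) and a clinical score,
#' over patients only.
#'
#' @param kcurve A `plv_kcurve` from [accuracy_vs_k()].
#' @param subjects Subject tibble (same order as the features the curve was
#'   fit on) with the score column.
#' @param score Name of the score column (default "severity").
#'
#' @return A tibble with columns `k`, `r`, `n`; the per-k scatter data are
#'   available via [confidence_scatter()].
#' @export
confidence_score_correlation <- function(kcurve, subjects,
                                         score = "severity") {
  stopifnot(inherits(kcurve, "plv_kcurve"))
  pat <- which(kcurve$labels > 0)
  s <- subjects[[score]][match(kcurve$subject_id[pat], subjects$subject_id)]
  if (anyNA(s)) plv_abort("score missing for some patients")
  if (sd(s) == 0) {
    warn("zero-variance scores: correlation undefined")
    return(tibble::tibble(k = seq_len(ncol(kcurve$distances)),
                          r = NA_real_, n = length(pat)))
  }
  purrr::map_dfr(seq_len(ncol(kcurve$distances)), function(k) {
    tibble::tibble(k = k, r = cor(kcurve$distances[pat, k], s),
                   n = length(pat))
  })
}

#' Scatter data of confidence against a clinical score at one k
#'
#' @inheritParams confidence_score_correlation
#' @param k Number of selected features.
#' @return A tibble with `subject_id`, `distance`, `score`, `misclassified`.
#' @export
confidence_scatter <- function(kcurve, subjects, k, score = "severity") {
  pat <- which(kcurve$labels > 0)
  s <- subjects[[score]][match(kcurve$subject_id[pat], subjects$subject_id)]
  tibble::tibble(subject_id = kcurve$subject_id[pat],
                 distance = kcurve$distances[pat, k],
                 score = s,
                 misclassified = kcurve$distances[pat, k] < 0)
}

# ---- feature robustness map -------------------------------------------------

#' Feature-robustness connection map
#'
#' For every wavelet frequency in a band, run leave-one-out classification
#' with `k_best` selection; assign -1 to a connection whenever it was
#' selected in a fold, 0 otherwise, and average over (fold, wavelet) cells.
#' A weight of -1 means the connection was selected in every fold at every
#' wavelet.
#'
#' @inheritParams accuracy_by_wavelet
#' @param band Canonical band name (e.g. "alpha").
#' @param k_best Number of features kept per fold.
#' @return A tibble with `pair`, `region_i`, `region_j`, `weight` in
#'   `[-1, 0]`.
#' @export
feature_robustness_map <- function(tensor, subjects, band = "alpha",
                                   k_best = 33, cost = 1) {
  f_idx <- tensor$grid$freq_index[tensor$grid$band == band]
  if (length(f_idx) == 0) plv_abort(sprintf("band '%s' is empty", band))
  n_pairs <- nrow(tensor$pairs)
  count <- numeric(n_pairs)
  cells <- 0L
  for (f in f_idx) {
    feats <- feature_set(tensor, subjects, f)
    cv <- loocv(feats, k_best = k_best, cost = cost)
    for (sel in cv$folds$selected) {
      count[feats$info$pair[sel]] <- count[feats$info$pair[sel]] + 1
      cells <- cells + 1L
    }
  }
  tibble::tibble(pair = tensor$pairs$pair,
                 region_i = tensor$pairs$region_i,
                 region_j = tensor$pairs$region_j,
                 weight = -count / cells)
}
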