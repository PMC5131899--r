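# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-fold cross-validation records
#'
#' @param x A `plv_cv`.
#' @param ... Unused.
#' @return The folds tibble: `subject_id`, `truth`, `predicted`,
#'   `distance`, `selected`.
#' @method tidy plv_cv
#' @export
tidy.plv_cv <- function(x, ...) x$folds

#' One-row cross-validation summary
#'
#' @param x A `plv_cv`.
#' @param ... Unused.
#' @return A tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `n_folds`.
#' @method glance plv_cv
#' @export
glance.plv_cv <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity, n_folds = nrow(x$folds))
}

#' Tidy element saliences of a PLS model
#'
#' @param x A `plv_pls`.
#' @param lv Latent variable index (default 1).
#' @param ... Unused.
#' @return A tibble with element labels and `salience`.
#' @method tidy plv_pls
#' @export
tidy.plv_pls <- function(x, lv = 1, ...) {
  out <- x$labels
  out$salience <- x$saliences[, lv]
  out
}

#' Latent-variable level summary of a PLS model
#'
#' @param x A `plv_pls`.
#' @param ... Unused.
#' @return A tibble with `lv`, `singular_value`, `prop_var` (share of
#'   squared singular values), and for behavioural models the overall
#'   correlation.
#' @method glance plv_pls
#' @export
glance.plv_pls <- function(x, ...) {
  d <- x$singular_values
  out <- tibble::tibble(lv = seq_along(d), singular_value = d,
                        prop_var = d^2 / sum(d^2))
  if (x$mode == "behavioural") out$overall_correlation <- drop(x$left)
  out
}

#' Tidy bootstrap ratios
#'
#' @param x A `plv_bsr`.
#' @param ... Unused.
#' @return Tibble with element labels, `salience`, `se`, `ratio`.
#' @method tidy plv_bsr
#' @export
tidy.plv_bsr <- function(x, ...) x$table

#' Tidy a classification permutation null
#'
#' @param x A `plv_null`.
#' @param ... Unused.
#' @return Tibble with one row per permutation (`accuracy`).
#' @method tidy plv_null
#' @export
tidy.plv_null <- function(x, ...) tibble::tibble(accuracy = x$accuracies)

#' One-row permutation-null summary
#'
#' @param x A `plv_null`.
#' @param ... Unused.
#' @return Tibble with `observed`, `p_value`, `n_perm`.
#' @method glance plv_null
#' @export
glance.plv_null <- function(x, ...) {
  tibble::tibble(observed = x$observed, p_value = x$p_value,
                 n_perm = x$n_perm)
}
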