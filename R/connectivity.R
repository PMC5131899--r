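# Subject- and cohort-level phase-locking connectivity.

# Construct a plv_tensor container. plv: array [subjects, frequencies, pairs].
new_plv_tensor <- function(plv, grid, n_regions, subject_ids, region_names) {
  pairs <- all_pairs(n_regions)
  pairs$region_i <- region_names[pairs$i]
  pairs$region_j <- region_names[pairs$j]
  stopifnot(dim(plv)[2] == nrow(grid), dim(plv)[3] == nrow(pairs))
  dimnames(plv) <- list(subject_ids, NULL, NULL)
  structure(
    list(plv = plv, grid = grid, pairs = pairs,
         n_regions = n_regions, subject_ids = subject_ids,
         region_names = region_names),
    class = "plv_tensor"
  )
}

#' @export
print.plv_tensor <- function(x, ...) {
  cat(sprintf(
    "<plv_tensor> %d subjects x %d frequencies (%.3g-%.3g Hz) x %d pairs (%d regions)\n",
    dim(x$plv)[1], nrow(x$grid), min(x$grid$frequency_hz),
    max(x$grid$frequency_hz), nrow(x$pairs), x$n_regions))
  invisible(x)
}

#' Tidy a connectivity tensor into long format
#'
#' @param x A `plv_tensor`.
#' @param ... Unused.
#' @return A tibble with one row per (subject, frequency, pair).
#' @method tidy plv_tensor
#' @export
tidy.plv_tensor <- function(x, ...) {
  d <- dim(x$plv)
  tibble::tibble(
    subject_id = rep(x$subject_ids, times = d[2] * d[3]),
    freq_index = rep(rep(x$grid$freq_index, each = d[1]), times = d[3]),
    frequency_hz = rep(rep(x$grid$frequency_hz, each = d[1]), times = d[3]),
    pair = rep(x$pairs$pair, each = d[1] * d[2]),
    region_i = rep(x$pairs$region_i, each = d[1] * d[2]),
    region_j = rep(x$pairs$region_j, each = d[1] * d[2]),
    plv = as.vector(x$plv)
  )
}

# PLV for one epoch from precomputed per-region wavelet stacks.
# coefs: list over regions of complex matrices [n_freq, n_time];
# valid: logical matrix [n_freq, n_time] (mask is region-independent).
epoch_plv <- function(coefs, valid, n_regions) {
  n_freq <- nrow(valid)
  n_pairs <- n_regions * (n_regions - 1) / 2
  reorder <- order_upper_tri(n_regions)
  out <- matrix(NA_real_, n_freq, n_pairs)
  for (r in seq_len(n_freq)) {
    tv <- which(valid[r, ])
    if (length(tv) == 0) next
    u <- matrix(0i, n_regions, length(tv))
    for (g in seq_len(n_regions)) {
      w <- coefs[[g]][r, tv]
      m <- Mod(w)
      u[g, ] <- ifelse(m > 0, w / m, 0i)
    }
    cross <- u %*% Conj(t(u)) / length(tv)
    out[r, ] <- Mod(cross[upper.tri(cross)])[reorder]
  }
  out
}

# upper.tri() extracts column-major, i.e. pairs ordered by (j, i); this
# index vector maps that listing onto row-major pair_index order.
order_upper_tri <- function(n_regions) {
  p <- all_pairs(n_regions)
  match(seq_len(nrow(p)), order(p$j, p$i))
}

#' Per-subject phase-locking connectivity
#'
#' Compute the PLV between every unordered pair of regions at every grid
#' frequency, within each epoch, then average arithmetically across epochs.
#'
#' @param epochs Numeric array `[epochs, regions, samples]` for one subject.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param grid Frequency grid from [make_frequency_grid()].
#' @param n_cycles Wavelet width in cycles (default 7).
#'
#' @return A numeric matrix `[frequencies, pairs]` of PLV values in `[0, 1]`
#'   (NA at frequencies fully masked in every epoch).
#' @export
subject_connectivity <- function(epochs, sampling_rate_hz, grid, n_cycles = 7) {
  stopifnot(inherits(grid, "plv_grid"))
  if (!is.array(epochs) || length(dim(epochs)) != 3) {
    plv_abort("epochs must be an [epochs, regions, samples] array")
  }
  n_epochs <- dim(epochs)[1]
  n_regions <- dim(epochs)[2]
  if (n_epochs < 1) plv_abort("need at least one epoch")
  if (n_regions < 2) {
    warn("fewer than two regions: empty pair set")
    return(matrix(numeric(0), nrow(grid), 0))
  }
  acc <- NULL
  cnt <- NULL
  for (e in seq_len(n_epochs)) {
    coefs <- vector("list", n_regions)
    valid <- NULL
    for (g in seq_len(n_regions)) {
      w <- wavelet_transform(epochs[e, g, ], sampling_rate_hz, grid, n_cycles)
      coefs[[g]] <- w$coefficients
      valid <- w$valid
    }
    p <- epoch_plv(coefs, valid, n_regions)
    ok <- !is.na(p)
    if (is.null(acc)) {
      acc <- ifelse(ok, p, 0)
      cnt <- ok * 1
    } else {
      acc <- acc + ifelse(ok, p, 0)
      cnt <- cnt + ok
    }
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Cohort connectivity tensor
#'
#' Apply [subject_connectivity()] to every subject of a source time-series
#' set, producing the subjects x frequencies x pairs PLV tensor that all
#' downstream analyses consume.
#'
#' @param tsset A `plv_timeseries` set (e.g. from [simulate_cohort()]).
#' @param grid Frequency grid; default the 30-point 1--75 Hz grid.
#' @param n_cycles Wavelet width in cycles (default 7).
#'
#' @return A `plv_tensor`.
#' @export
compute_connectivity <- function(tsset, grid = make_frequency_grid(),
                                 n_cycles = 7) {
  stopifnot(inherits(tsset, "plv_timeseries"))
  ids <- names(tsset$subjects)
  n_regions <- dim(tsset$subjects[[1]])[2]
  n_pairs <- n_regions * (n_regions - 1) / 2
  plv <- array(NA_real_, c(length(ids), nrow(grid), n_pairs))
  for (s in seq_along(ids)) {
    plv[s, , ] <- subject_connectivity(tsset$subjects[[s]],
                                       tsset$sampling_rate_hz, grid, n_cycles)
  }
  new_plv_tensor(plv, grid, n_regions, ids, tsset$region_names)
}

# Reconstruct a symmetric region x region matrix (unit diagonal by
# convention) from one frequency slice of a tensor.
#' Single-frequency connectivity matrix
#'
#' @param tensor A `plv_tensor`.
#' @param freq_index Grid frequency index.
#' @param subject Subject id or index; default averages across subjects.
#' @return A symmetric `n_regions x n_regions` matrix with unit diagonal.
#' @export
connectivity_matrix <- function(tensor, freq_index, subject = NULL) {
  stopifnot(inherits(tensor, "plv_tensor"))
  vals <- if (is.null(subject)) {
    colMeans(tensor$plv[, freq_index, , drop = FALSE][, 1, ])
  } else {
    tensor$plv[subject, freq_index, ]
  }
  n <- tensor$n_regions
  m <- matrix(0, n, n, dimnames = list(tensor$region_names, tensor$region_names))
  m[cbind(tensor$pairs$i, tensor$pairs$j)] <- vals
  m <- m + t(m)
  diag(m) <- 1
  m
}
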