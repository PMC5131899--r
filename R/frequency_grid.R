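#' Canonical frequency bands
#'
#' The five canonical bands used throughout the package: delta 1--4 Hz,
#' theta 4--8 Hz, alpha 8--14 Hz, beta 14--28 Hz and lower gamma 28--75 Hz.
#' Band intervals are half-open `[low, high)` except the last, which is
#' closed, so a boundary frequency such as exactly 8 Hz belongs to the
#' higher band.
#'
#' @return A tibble with columns `band`, `low_hz`, `high_hz`.
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function() {
  tibble::tibble(
    band = band_levels(),
    low_hz = c(1, 4, 8, 14, 28),
    high_hz = c(4, 8, 14, 28, 75)
  )
}

band_levels <- function() c("delta", "theta", "alpha", "beta", "gamma")

# Assign each frequency to a canonical band. Frequencies below the first
# edge fall in delta; at or above the last edge, gamma.
band_of <- function(frequency_hz) {
  bands <- canonical_bands()
  idx <- findInterval(frequency_hz, bands$low_hz)
  idx[idx < 1] <- 1L
  idx[idx > nrow(bands)] <- nrow(bands)
  factor(bands$band[idx], levels = band_levels())
}

#' Logarithmic frequency grid
#'
#' Build a geometric progression of analysis frequencies inclusive of both
#' endpoints, the default being 30 points covering 1--75 Hz. Each grid point
#' is labelled with its canonical band.
#'
#' @param n_points Number of grid frequencies (>= 2). Default 30.
#' @param f_min_hz Lowest frequency in Hz. Default 1.
#' @param f_max_hz Highest frequency in Hz. Default 75.
#'
#' @return A tibble with columns `freq_index`, `frequency_hz`, `band`,
#'   carrying class `plv_grid`.
#' @export
#' @examples
#' grid <- make_frequency_grid()
#' range(grid$frequency_hz)
#' table(grid$band)
make_frequency_grid <- function(n_points = 30, f_min_hz = 1, f_max_hz = 75) {
  n_points <- check_count(n_points, "n_points", min = 2)
  if (!is.numeric(f_min_hz) || !is.numeric(f_max_hz) ||
      f_min_hz <= 0 || f_max_hz <= f_min_hz) {
    plv_abort("frequencies must satisfy 0 < f_min_hz < f_max_hz")
  }
  freqs <- exp(seq(log(f_min_hz), log(f_max_hz), length.out = n_points))
  freqs[1] <- f_min_hz
  freqs[n_points] <- f_max_hz
  out <- tibble::tibble(
    freq_index = seq_len(n_points),
    frequency_hz = freqs,
    band = band_of(freqs)
  )
  class(out) <- c("plv_grid", class(out))
  out
}

#' Band-central wavelet frequencies
#'
#' For each canonical band's central target frequency (2, 6, 11, 23, 48 Hz by
#' default) find the nearest grid frequency by absolute difference. Ties are
#' resolved toward the lower frequency; targets outside the grid range clamp
#' to the nearest endpoint.
#'
#' @param grid A frequency grid from [make_frequency_grid()].
#' @param targets_hz Named numeric vector of per-band target frequencies.
#'
#' @return A tibble with columns `band`, `target_hz`, `freq_index`,
#'   `frequency_hz`.
#' @export
#' @examples
#' band_central_wavelets(make_frequency_grid())
band_central_wavelets <- function(grid,
                                  targets_hz = c(delta = 2, theta = 6,
                                                 alpha = 11, beta = 23,
                                                 gamma = 48)) {
  stopifnot(inherits(grid, "plv_grid"))
  idx <- vapply(targets_hz, function(target) {
    d <- abs(grid$frequency_hz - target)
    # which.min already favours the earlier (lower-frequency) point on ties
    which.min(d)
  }, integer(1))
  tibble::tibble(
    band = names(targets_hz),
    target_hz = unname(targets_hz),
    freq_index = unname(idx),
    frequency_hz = grid$frequency_hz[idx]
  )
}
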