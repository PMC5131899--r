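# Constant-Q complex Morlet decomposition and phase-locking values.
#
# The time-frequency kernel at centre frequency f is a Gaussian-windowed
# complex exponential with temporal SD sigma_t = n_cycles / (2 pi f), so
# every kernel spans the same number of cycles and bandwidth scales with f.
# The kernel is forced exactly zero-mean (a DC offset produces |W| = 0) and
# scaled so a unit-amplitude sinusoid at f yields |W| ~ 1.

# Build one Morlet kernel; support truncated at +/- 3.5 sigma_t.
morlet_kernel <- function(frequency_hz, sampling_rate_hz, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * frequency_hz)
  half <- ceiling(3.5 * sigma_t * sampling_rate_hz)
  t <- seq(-half, half) / sampling_rate_hz
  env <- exp(-t^2 / (2 * sigma_t^2))
  k <- env * exp(2i * pi * frequency_hz * t)
  # exact zero-mean: remove the envelope-shaped DC component
  k <- k - env * (sum(k) / sum(env))
  # unit response to a unit sinusoid at f: |sum cos * conj(k)| ~ sum(env)/2
  k / (sum(env) / 2)
}

#' Constant-Q wavelet transform
#'
#' Convolve a signal with complex Morlet wavelets at every grid frequency,
#' giving complex coefficients whose modulus is the instantaneous amplitude
#' and whose argument is the instantaneous phase. Samples closer than half
#' the wavelet support to either boundary are flagged invalid
#' (edge-contaminated); a frequency whose kernel exceeds the signal is
#' fully masked.
#'
#' @param signal Numeric vector, one epoch of one source.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param grid Frequency grid from [make_frequency_grid()].
#' @param n_cycles Wavelet width in cycles (default 7).
#'
#' @return An object of class `plv_wavelet`: list with `coefficients`
#'   (complex matrix, frequencies x time), `valid` (logical matrix, same
#'   shape), `grid`, `sampling_rate_hz`, `n_cycles`.
#' @export
#' @examples
#' grid <- make_frequency_grid(12, 2, 48)
#' x <- sin(2 * pi * 11 * seq(0, 5, by = 1 / 150))
#' w <- wavelet_transform(x, 150, grid)
#' dim(w$coefficients)
wavelet_transform <- function(signal, sampling_rate_hz, grid, n_cycles = 7) {
  stopifnot(inherits(grid, "plv_grid"))
  if (length(signal) == 0) plv_abort("empty signal")
  if (!is.numeric(signal) || anyNA(signal)) {
    plv_abort("signal must be numeric without missing values")
  }
  n <- length(signal)
  n_freq <- nrow(grid)
  max_half <- ceiling(3.5 * (n_cycles / (2 * pi * min(grid$frequency_hz))) *
                        sampling_rate_hz)
  nfft <- stats::nextn(n + 2 * max_half + 1, 2)
  xf <- fft(c(signal, rep(0, nfft - n)))

  coef <- matrix(0i, n_freq, n)
  valid <- matrix(FALSE, n_freq, n)
  for (r in seq_len(n_freq)) {
    k <- morlet_kernel(grid$frequency_hz[r], sampling_rate_hz, n_cycles)
    half <- (length(k) - 1L) %/% 2L
    # cross-correlation with the kernel: W(tau) = sum_u x(tau + u) conj(k(u)).
    # The symmetric-envelope zero-mean kernel satisfies rev(Conj(k)) == k, so
    # this equals circular convolution with k itself, wrapped about zero lag.
    kf <- fft(c(k[(half + 1):length(k)], rep(0, nfft - length(k)),
                k[1:half]))
    y <- fft(xf * kf, inverse = TRUE) / nfft
    coef[r, ] <- y[seq_len(n)]
    if (n > 2 * half) valid[r, (half + 1):(n - half)] <- TRUE
  }
  structure(
    list(coefficients = coef, valid = valid, grid = grid,
         sampling_rate_hz = sampling_rate_hz, n_cycles = n_cycles),
    class = "plv_wavelet"
  )
}

#' Relative phase of two wavelet decompositions
#'
#' The phase difference at each (time, frequency) cell is the argument of
#' `W_x * conj(W_y)`, wrapped to `(-pi, pi]`. Validity masks of the two
#' inputs are intersected.
#'
#' @param wx,wy `plv_wavelet` objects with matching shape.
#'
#' @return An object of class `plv_phase`: list with `dphi` (radians,
#'   frequencies x time), `valid`, `grid`.
#' @export
relative_phase <- function(wx, wy) {
  stopifnot(inherits(wx, "plv_wavelet"), inherits(wy, "plv_wavelet"))
  if (!identical(dim(wx$coefficients), dim(wy$coefficients))) {
    plv_abort("wavelet coefficient shapes differ")
  }
  structure(
    list(dphi = Arg(wx$coefficients * Conj(wy$coefficients)),
         valid = wx$valid & wy$valid,
         grid = wx$grid),
    class = "plv_phase"
  )
}

#' Phase-locking value
#'
#' The PLV at a frequency is the modulus of the time average of the unit
#' phasor of the relative phase: 1 when the phase difference is constant,
#' near 0 when phases scatter uniformly. Only valid (non-edge) samples enter
#' the average; a frequency with no valid samples is reported as `NA`
#' (missing, not zero).
#'
#' @param phase A `plv_phase` object from [relative_phase()], or a numeric
#'   vector of phase differences in radians (single frequency).
#'
#' @return For a `plv_phase` input, a tibble with columns `freq_index`,
#'   `frequency_hz`, `band`, `n_valid`, `plv`; for a numeric vector, a
#'   single PLV value.
#' @export
#' @examples
#' plv(c(0, 0, pi))  # 1/3
plv <- function(phase) {
  if (is.numeric(phase)) {
    if (length(phase) == 0) plv_abort("no phase samples")
    return(Mod(mean(exp(1i * phase))))
  }
  stopifnot(inherits(phase, "plv_phase"))
  n_valid <- rowSums(phase$valid)
  vals <- vapply(seq_len(nrow(phase$dphi)), function(r) {
    v <- phase$valid[r, ]
    if (!any(v)) return(NA_real_)
    Mod(mean(exp(1i * phase$dphi[r, v])))
  }, numeric(1))
  out <- phase$grid
  out$n_valid <- as.integer(n_valid)
  out$plv <- vals
  class(out) <- setdiff(class(out), "plv_grid")
  out
}
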