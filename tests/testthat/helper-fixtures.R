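# Shared reduced-scale fixtures. The test grid spans 2-48 Hz over 12 points
# so every canonical band is populated while a 7-cycle wavelet still fits
# short epochs.

test_grid <- function() make_frequency_grid(12, 2, 48)

# Grid index nearest a target frequency.
nearest_freq <- function(grid, target) which.min(abs(grid$frequency_hz - target))

# Fast-path cohort: alpha effect on disjoint pairs of a small region set.
tensor_cohort <- function(seed = 1, n_a = 10, n_b = 10, n_regions = 8,
                          kappa_a = 0.8, kappa_b = 0.3,
                          pairs = cbind(c(1, 3), c(2, 4)),
                          effects = NULL, grid = test_grid()) {
  if (is.null(effects)) effects <- list(effect_spec(11, pairs, kappa_a, kappa_b))
  cfg <- sim_config(n_group_a = n_a, n_group_b = n_b, n_regions = n_regions,
                    n_epochs = 5, epoch_duration_s = 10,
                    sampling_rate_hz = 600, effects = effects, seed = seed)
  simulate_plv_tensor(cfg, grid)
}

# No-effect fast-path cohort (label-exchangeable null).
null_cohort <- function(seed = 1, n_a = 10, n_b = 10, n_regions = 8,
                        grid = test_grid()) {
  cfg <- sim_config(n_group_a = n_a, n_group_b = n_b, n_regions = n_regions,
                    n_epochs = 5, epoch_duration_s = 10,
                    sampling_rate_hz = 600, effects = list(), seed = seed)
  simulate_plv_tensor(cfg, grid)
}

# Analytic-signal (quadrature) PLV oracle for narrowband signals: the
# analytic signal of a mono-component oscillation cos(phi(t)) is e^{i phi},
# so its argument recovers the instantaneous phase directly. A sharp
# band-pass would ring (sinc smearing biases PLV upward), so only the
# negative frequencies are zeroed; edges are discarded.
analytic_plv <- function(x, y, f0, fs) {
  n <- length(x)
  analytic <- function(s) {
    sf <- fft(s)
    h <- numeric(n)
    h[1] <- 1
    h[2:floor(n / 2)] <- 2
    if (n %% 2 == 0) h[n / 2 + 1] <- 1
    fft(sf * h, inverse = TRUE) / n
  }
  ax <- analytic(x)
  ay <- analytic(y)
  core <- seq(round(n * 0.15), round(n * 0.85))
  Mod(mean(exp(1i * (Arg(ax[core]) - Arg(ay[core])))))
}
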