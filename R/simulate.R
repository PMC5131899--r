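# Synthetic cohort generator: coupled-oscillator source signals (and a fast
# path drawing PLV tensors directly) with planted group differences,
# clinical-score coupling, and a days-since-injury covariate.
#
# Phase-coupling model: each planted pair (or pair-graph component) owns a
# slow common Wiener drift C(t) (rate 1 rad/sqrt(s), keeping the signals
# narrowband); the two sides carry instantaneous phase
#   phi_i(t) = theta_i + 2 pi f t + C(t) + (1 - kappa) D_i(t)
# with independent fast diffusions D_i (phase_diffusion_rate). The common
# drift cancels in the phase difference, which drifts with variance
# 2 (1-kappa)^2 rate^2 t: PLV = 1 at kappa = 1 (identical narrowband
# phases, constant lag) and decays to a finite-sample floor as kappa -> 0,
# monotonically in kappa. Amplitudes are uncorrelated throughout, as
# phase-locking requires.
common_drift_rate <- 1

#' Expected phase-locking value of the coupling model
#'
#' Closed-form (root-mean-square) PLV of one epoch of the Wiener phase-driver
#' model: with relative-phase diffusion constant `lambda = (1 - kappa)^2 *
#' rate^2`, `E|PLV|^2 = 2 (T/lambda - (1 - exp(-lambda T)) / lambda^2) / T^2`.
#'
#' @param kappa Coupling weight in `[0, 1]`.
#' @param duration_s Epoch duration in seconds.
#' @param rate Phase-diffusion rate in rad/sqrt(s).
#' @return Expected PLV in `[0, 1]`.
#' @export
expected_plv <- function(kappa, duration_s, rate = 8) {
  lam <- (1 - kappa)^2 * rate^2
  t_s <- duration_s
  ifelse(lam * t_s < 1e-12, 1,
         pmin(1, sqrt(2 * (t_s / lam - (1 - exp(-lam * t_s)) / lam^2) / t_s^2)))
}

# 1/f^alpha background noise via spectral shaping of white noise.
pink_noise <- function(n, exponent = 1, sd = 1) {
  if (sd <= 0 || n < 2) return(rep(0, n))
  white <- rnorm(n)
  xf <- fft(white)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)          # two-sided frequency index
  scale <- ifelse(f == 0, 0, 1 / f^(exponent / 2))
  x <- Re(fft(xf * scale, inverse = TRUE) / n)
  x * sd / stats::sd(x)
}

#' Simulate one coupled oscillator pair
#'
#' Two zero-mean oscillations at `frequency_hz` whose instantaneous phases
#' share a common stochastic driver with mixing weight `kappa` plus
#' independent phase diffusion. At `kappa = 1` the two phases differ by a
#' constant lag (PLV 1); at `kappa = 0` they diffuse independently and the
#' PLV falls to the finite-sample floor.
#'
#' @param frequency_hz Oscillation frequency; must be below Nyquist.
#' @param kappa Coupling weight in `[0, 1]`.
#' @param duration_s Record duration in seconds.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param seed Integer seed; fully determines the output.
#' @param phase_diffusion_rate Phase-diffusion rate in rad/sqrt(s).
#' @param noise_sd SD of additive pink noise (0 disables).
#'
#' @return A tibble with columns `time_s`, `x`, `y`.
#' @export
#' @examples
#' sig <- simulate_coupled_pair(11, 0.9, 2, 150, seed = 1)
simulate_coupled_pair <- function(frequency_hz, kappa, duration_s,
                                  sampling_rate_hz, seed,
                                  phase_diffusion_rate = 8, noise_sd = 0) {
  if (frequency_hz >= sampling_rate_hz / 2) {
    plv_abort("frequency_hz must be below the Nyquist frequency")
  }
  if (kappa < 0 || kappa > 1) plv_abort("kappa must lie in [0, 1]")
  n <- round(duration_s * sampling_rate_hz)
  dt <- 1 / sampling_rate_hz
  withr::with_seed(seed, {
    tt <- (seq_len(n) - 1) * dt
    common <- cumsum(rnorm(n, 0, common_drift_rate * sqrt(dt)))
    d1 <- cumsum(rnorm(n, 0, phase_diffusion_rate * sqrt(dt)))
    d2 <- cumsum(rnorm(n, 0, phase_diffusion_rate * sqrt(dt)))
    theta <- runif(2, -pi, pi)
    phi1 <- theta[1] + 2 * pi * frequency_hz * tt + common + (1 - kappa) * d1
    phi2 <- theta[2] + 2 * pi * frequency_hz * tt + common + (1 - kappa) * d2
    x <- cos(phi1)
    y <- cos(phi2)
    if (noise_sd > 0) {
      x <- x + pink_noise(n, sd = noise_sd)
      y <- y + pink_noise(n, sd = noise_sd)
    }
    tibble::tibble(time_s = tt, x = x, y = y)
  })
}

#' Planted connectivity effect
#'
#' Describes one frequency-specific coupling effect: a set of unordered
#' region pairs, a centre frequency, and per-group coupling strengths. The
#' empirical pattern this encodes in the default configuration is alpha-band
#' hyperconnectivity together with delta/gamma hypoconnectivity in the
#' patient group.
#'
#' @param band_center_hz Centre frequency of the effect in Hz.
#' @param pairs Two-column matrix or data frame of region index pairs
#'   (`i < j`), unique.
#' @param kappa_group_a Coupling in group a (patients), in `[0, 1]`.
#' @param kappa_group_b Coupling in group b (controls), in `[0, 1]`.
#'
#' @return An object of class `plv_effect`.
#' @export
effect_spec <- function(band_center_hz, pairs, kappa_group_a, kappa_group_b) {
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  if (ncol(pairs) != 2 || any(pairs[, 1] >= pairs[, 2]) || any(pairs < 1)) {
    plv_abort("pairs must be rows (i, j) with 1 <= i < j")
  }
  if (anyDuplicated(paste(pairs[, 1], pairs[, 2]))) {
    plv_abort("pairs must be unique")
  }
  for (k in c(kappa_group_a, kappa_group_b)) {
    if (k < 0 || k > 1) plv_abort("kappa must lie in [0, 1]")
  }
  structure(
    list(band_center_hz = band_center_hz, pairs = pairs,
         kappa_group_a = kappa_group_a, kappa_group_b = kappa_group_b,
         band = as.character(band_of(band_center_hz))),
    class = "plv_effect"
  )
}

#' Default planted effects
#'
#' The study-condition pattern: alpha (11 Hz) hyperconnectivity in patients
#' (kappa 0.8 vs 0.3) on up to 10 disjoint pairs, and delta (2 Hz) and lower
#' gamma (48 Hz) hypoconnectivity (kappa 0.25 vs 0.6) on up to 6 disjoint
#' pairs each, allocated from non-overlapping region blocks.
#'
#' @param n_regions Number of regions available (>= 6).
#' @return A list of [effect_spec()] objects.
#' @export
default_effects <- function(n_regions = 90) {
  n_regions <- check_count(n_regions, "n_regions", min = 6)
  budget <- floor(n_regions / 2)
  n_alpha <- min(10, max(1, floor(budget / 2)))
  n_delta <- min(6, max(1, floor((budget - n_alpha) / 2)))
  n_gamma <- min(6, max(1, budget - n_alpha - n_delta))
  block <- function(start, n_pairs) {
    cbind(start + 2 * seq_len(n_pairs) - 2, start + 2 * seq_len(n_pairs) - 1)
  }
  a <- block(1, n_alpha)
  d <- block(2 * n_alpha + 1, n_delta)
  g <- block(2 * (n_alpha + n_delta) + 1, n_gamma)
  list(
    effect_spec(11, a, kappa_group_a = 0.8, kappa_group_b = 0.3),
    effect_spec(2, d, kappa_group_a = 0.25, kappa_group_b = 0.6),
    effect_spec(48, g, kappa_group_a = 0.25, kappa_group_b = 0.6)
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort. Defaults mirror the study
#' conditions: 20 patients vs 21 controls, 90 regions, 27 epochs of 10 s at
#' 600 Hz, and the default planted effect pattern.
#'
#' @param n_group_a Patients (default 20).
#' @param n_group_b Controls (default 21).
#' @param n_regions Regions (default 90).
#' @param n_epochs Epochs per subject (default 27).
#' @param epoch_duration_s Epoch length in seconds (default 10).
#' @param sampling_rate_hz Sampling rate (default 600).
#' @param effects List of [effect_spec()]; default [default_effects()].
#' @param noise_sd Pink-noise amplitude relative to unit oscillators
#'   (default 1).
#' @param pink_noise_exponent Spectral slope of the background (default 1).
#' @param kappa_subject_sd Between-subject SD of coupling strength
#'   (default 0.05).
#' @param phase_diffusion_rate Phase-diffusion rate, rad/sqrt(s)
#'   (default 8).
#' @param plv_concentration Beta concentration of the tensor fast path
#'   (default 60).
#' @param score_coupling,score_noise_sd Severity = `score_coupling` x
#'   (subject's planted alpha PLV deviation) + N(0, `score_noise_sd`),
#'   truncated at 0. Defaults 70 and 17 target the reported severity
#'   moments (about 20 +/- 19).
#' @param symptom_coupling,symptom_noise_sd Same for the symptom count
#'   (defaults 31 and 5, targeting about 9 +/- 6).
#' @param days_range Days-since-injury range (default 3--90, within three
#'   months of injury).
#' @param days_alpha_cor Target rank correlation between days since injury
#'   and the subject's alpha coupling (default -0.5; negative).
#' @param seed Integer seed; fully determines the cohort.
#'
#' @return An object of class `plv_sim_config`.
#' @export
sim_config <- function(n_group_a = 20, n_group_b = 21, n_regions = 90,
                       n_epochs = 27, epoch_duration_s = 10,
                       sampling_rate_hz = 600,
                       effects = default_effects(n_regions),
                       noise_sd = 1, pink_noise_exponent = 1,
                       kappa_subject_sd = 0.05, phase_diffusion_rate = 8,
                       plv_concentration = 60,
                       score_coupling = 70, score_noise_sd = 17,
                       symptom_coupling = 31, symptom_noise_sd = 5,
                       days_range = c(3, 90), days_alpha_cor = -0.5,
                       seed = 1) {
  n_group_a <- check_count(n_group_a, "n_group_a")
  n_group_b <- check_count(n_group_b, "n_group_b")
  n_regions <- check_count(n_regions, "n_regions", min = 2)
  n_epochs <- check_count(n_epochs, "n_epochs")
  n_samples <- epoch_duration_s * sampling_rate_hz
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    plv_abort("epoch_duration_s * sampling_rate_hz must be an integer")
  }
  for (e in effects) {
    stopifnot(inherits(e, "plv_effect"))
    if (any(e$pairs > n_regions)) {
      plv_abort("effect references regions beyond n_regions")
    }
    if (e$band_center_hz >= sampling_rate_hz / 2) {
      plv_abort("effect frequency at or above Nyquist")
    }
  }
  structure(
    list(n_group_a = n_group_a, n_group_b = n_group_b, n_regions = n_regions,
         n_epochs = n_epochs, epoch_duration_s = epoch_duration_s,
         sampling_rate_hz = sampling_rate_hz, effects = effects,
         noise_sd = noise_sd, pink_noise_exponent = pink_noise_exponent,
         kappa_subject_sd = kappa_subject_sd,
         phase_diffusion_rate = phase_diffusion_rate,
         plv_concentration = plv_concentration,
         score_coupling = score_coupling, score_noise_sd = score_noise_sd,
         symptom_coupling = symptom_coupling,
         symptom_noise_sd = symptom_noise_sd,
         days_range = days_range, days_alpha_cor = days_alpha_cor,
         seed = as.integer(seed)),
    class = "plv_sim_config"
  )
}

# Per-subject realized coupling: matrix [n_subjects, n_effects], clipped to
# [0, 1]. Must be called inside the config's seeded RNG scope.
draw_subject_kappas <- function(config) {
  n <- config$n_group_a + config$n_group_b
  grp_kappa <- function(e, patient) if (patient) e$kappa_group_a else e$kappa_group_b
  k <- matrix(0, n, length(config$effects))
  for (j in seq_along(config$effects)) {
    e <- config$effects[[j]]
    base <- c(rep(grp_kappa(e, TRUE), config$n_group_a),
              rep(grp_kappa(e, FALSE), config$n_group_b))
    k[, j] <- pmin(1, pmax(0, base + rnorm(n, 0, config$kappa_subject_sd)))
  }
  k
}

# Subject metadata coupled to the realized alpha coupling. Called inside the
# seeded scope, after draw_subject_kappas.
make_subject_table <- function(config, kappas) {
  n <- config$n_group_a + config$n_group_b
  group <- c(rep("patient", config$n_group_a), rep("control", config$n_group_b))
  alpha_cols <- which(vapply(config$effects, function(e) e$band == "alpha",
                             logical(1)))
  use_cols <- if (length(alpha_cols)) alpha_cols else seq_along(config$effects)
  floor_plv <- expected_plv(0, config$epoch_duration_s,
                            config$phase_diffusion_rate)
  dev <- if (length(use_cols)) {
    rowMeans(expected_plv(kappas[, use_cols, drop = FALSE],
                          config$epoch_duration_s,
                          config$phase_diffusion_rate)) - floor_plv
  } else {
    rep(0, n)
  }
  severity <- pmax(0, round(config$score_coupling * dev +
                              rnorm(n, 0, config$score_noise_sd)))
  symptoms <- pmax(0, round(config$symptom_coupling * dev +
                              rnorm(n, 0, config$symptom_noise_sd)))
  days <- rep(NA_real_, n)
  pat <- which(group == "patient")
  if (length(pat)) {
    raw <- sort(round(runif(length(pat), config$days_range[1],
                            config$days_range[2])))
    rho <- abs(config$days_alpha_cor)
    z <- if (length(pat) > 1 && isTRUE(sd(dev[pat]) > 0)) {
      scale(dev[pat])[, 1]
    } else {
      rnorm(length(pat))
    }
    target <- sign(config$days_alpha_cor) * rho * z +
      sqrt(max(0, 1 - rho^2)) * rnorm(length(pat))
    days[pat] <- raw[rank(target, ties.method = "first")]
  }
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = group,
    severity = severity,
    symptoms = symptoms,
    days_since_injury = days,
    alpha_coupling = dev
  )
}

# Connected components of an effect's pair graph: integer component id per
# region (0 = not planted in this effect).
pair_components <- function(pairs, n_regions) {
  comp <- seq_len(n_regions)
  repeat {
    changed <- FALSE
    for (p in seq_len(nrow(pairs))) {
      a <- comp[pairs[p, 1]]
      b <- comp[pairs[p, 2]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  planted <- unique(as.vector(pairs))
  out <- integer(n_regions)
  out[planted] <- match(comp[planted], sort(unique(comp[planted])))
  out
}

#' Simulate a cohort of source time series
#'
#' Generates epoched multi-region signals for every subject. Every region
#' carries one unit-amplitude oscillator per effect frequency plus 1/f
#' background noise. Within each effect, the connected components of the
#' planted pair graph share a common phase driver mixed at the subject's
#' coupling weight, so planted pairs are coupled and pairs across
#' components (or to unplanted regions) are not. When a component is not a
#' clique, pairs inside it that were not listed inherit coupling (phase
#' synchrony is transitive within a driver); listing disjoint pairs or
#' cliques avoids this. Subject metadata (severity, symptoms, days since
#' injury) are coupled to the realized alpha coupling.
#'
#' @param config A [sim_config()].
#'
#' @return A list with elements `timeseries` (class `plv_timeseries`: named
#'   list of `[epochs, regions, samples]` arrays, `sampling_rate_hz`,
#'   `region_names`) and `subjects` (tibble).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "plv_sim_config"))
  n_sub <- config$n_group_a + config$n_group_b
  n_samp <- round(config$epoch_duration_s * config$sampling_rate_hz)
  dt <- 1 / config$sampling_rate_hz
  tt <- (seq_len(n_samp) - 1) * dt
  rate <- config$phase_diffusion_rate

  withr::with_seed(config$seed, {
    kappas <- draw_subject_kappas(config)
    subjects <- make_subject_table(config, kappas)
    ts_list <- vector("list", n_sub)
    wiener <- function() cumsum(rnorm(n_samp, 0, rate * sqrt(dt)))
    comps <- lapply(config$effects, function(e) {
      pair_components(e$pairs, config$n_regions)
    })
    for (s in seq_len(n_sub)) {
      arr <- array(0, c(config$n_epochs, config$n_regions, n_samp))
      for (ep in seq_len(config$n_epochs)) {
        sig <- matrix(0, config$n_regions, n_samp)
        for (j in seq_along(config$effects)) {
          e <- config$effects[[j]]
          kap <- kappas[s, j]
          omega <- 2 * pi * e$band_center_hz * tt
          comp <- comps[[j]]
          drift <- function() {
            cumsum(rnorm(n_samp, 0, common_drift_rate * sqrt(dt)))
          }
          drivers <- lapply(seq_len(max(comp, 1)), function(cc) drift())
          for (r in seq_len(config$n_regions)) {
            # planted: shared slow drift + (1 - kappa)-scaled fast diffusion;
            # unplanted: own slow drift + full fast diffusion (kappa = 0)
            phi <- runif(1, -pi, pi) + omega +
              if (comp[r] > 0) drivers[[comp[r]]] + (1 - kap) * wiener()
              else drift() + wiener()
            sig[r, ] <- sig[r, ] + cos(phi)
          }
        }
        if (config$noise_sd > 0) {
          for (r in seq_len(config$n_regions)) {
            sig[r, ] <- sig[r, ] +
              pink_noise(n_samp, config$pink_noise_exponent, config$noise_sd)
          }
        }
        arr[ep, , ] <- sig
      }
      ts_list[[s]] <- arr
    }
    names(ts_list) <- subjects$subject_id
    list(
      timeseries = structure(
        list(subjects = ts_list,
             sampling_rate_hz = config$sampling_rate_hz,
             region_names = default_region_names(config$n_regions)),
        class = "plv_timeseries"),
      subjects = subjects
    )
  })
}

#' Simulate a PLV tensor directly (fast path)
#'
#' Bypasses signal synthesis: PLV values are drawn from Beta distributions
#' whose means follow the closed-form [expected_plv()] of the coupling
#' model -- the noise floor everywhere, lifted to the planted level at each
#' effect's nearest grid frequency and listed pairs. Metadata contract is
#' identical to [simulate_cohort()].
#'
#' @param config A [sim_config()].
#' @param grid Frequency grid (default the 30-point 1--75 Hz grid).
#'
#' @return A list with elements `tensor` (a `plv_tensor`) and `subjects`
#'   (tibble).
#' @export
simulate_plv_tensor <- function(config, grid = make_frequency_grid()) {
  stopifnot(inherits(config, "plv_sim_config"), inherits(grid, "plv_grid"))
  n_sub <- config$n_group_a + config$n_group_b
  n_pairs <- config$n_regions * (config$n_regions - 1) / 2
  nu <- config$plv_concentration
  floor_plv <- expected_plv(0, config$epoch_duration_s,
                            config$phase_diffusion_rate)
  withr::with_seed(config$seed, {
    kappas <- draw_subject_kappas(config)
    subjects <- make_subject_table(config, kappas)
    mu <- array(floor_plv, c(n_sub, nrow(grid), n_pairs))
    for (j in seq_along(config$effects)) {
      e <- config$effects[[j]]
      f_idx <- which.min(abs(grid$frequency_hz - e$band_center_hz))
      p_idx <- pair_index(e$pairs[, 1], e$pairs[, 2], config$n_regions)
      mu[, f_idx, p_idx] <- expected_plv(kappas[, j], config$epoch_duration_s,
                                         config$phase_diffusion_rate)
    }
    mu[] <- pmin(1 - 1e-6, pmax(1e-6, mu))
    plv_arr <- array(rbeta(length(mu), mu * nu, (1 - mu) * nu),
                     c(n_sub, nrow(grid), n_pairs))
    tensor <- new_plv_tensor(plv_arr, grid, config$n_regions,
                             subjects$subject_id,
                             default_region_names(config$n_regions))
    list(tensor = tensor, subjects = subjects)
  })
}
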