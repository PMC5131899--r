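# One-command reproducible pipeline over synthetic data:
# simulate -> connectivity -> classification -> PLS, with a run manifest.

#' Pipeline configuration
#'
#' Bundles every stage's settings. Per-stage seeds are derived from the
#' global seed by fixed offsets (simulate +1, classification null +2, PLS
#' permutation +3, PLS bootstrap +4), so stages are independently
#' rerunnable. Defaults are reduced-scale (10+10 subjects, 12 regions,
#' 12 frequencies over 2--48 Hz, 99 permutations); the full study scale is
#' reachable by passing a full-size [sim_config()] and grid settings.
#'
#' @param simulation A [sim_config()]; its seed is overridden by
#'   `seed + 1`.
#' @param n_freq,f_min_hz,f_max_hz Frequency grid settings.
#' @param n_cycles Wavelet width in cycles.
#' @param band Band used for k-curve classification and the robustness map.
#' @param k_max Largest feature count for the accuracy-vs-k curves.
#' @param cost SVM soft-margin cost.
#' @param n_perm Permutations for classification and PLS significance.
#' @param n_boot Bootstrap samples for PLS element stability.
#' @param tail_q Tail fraction for bootstrap-ratio profiling.
#' @param tensor_fast_path If TRUE draw the PLV tensor directly instead of
#'   synthesising signals (default FALSE).
#' @param seed Global integer seed.
#'
#' @return An object of class `plv_pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL,
                            n_freq = 12, f_min_hz = 2, f_max_hz = 48,
                            n_cycles = 7, band = "alpha",
                            k_max = 15, cost = 1, n_perm = 99, n_boot = 99,
                            tail_q = 0.05, tensor_fast_path = FALSE,
                            seed = 1) {
  if (!band %in% band_levels()) {
    plv_abort(sprintf("unknown band '%s'; valid: %s", band,
                      paste(band_levels(), collapse = ", ")))
  }
  if (tail_q <= 0 || tail_q >= 0.5) plv_abort("tail_q must lie in (0, 0.5)")
  seed <- check_count(seed, "seed", min = 0)
  simulation <- simulation %||% sim_config(
    n_group_a = 10, n_group_b = 10, n_regions = 12, n_epochs = 5,
    epoch_duration_s = 5, sampling_rate_hz = 150,
    effects = default_effects(12))
  simulation$seed <- seed + 1L
  structure(
    list(simulation = simulation, n_freq = n_freq, f_min_hz = f_min_hz,
         f_max_hz = f_max_hz, n_cycles = n_cycles, band = band,
         k_max = k_max, cost = cost, n_perm = n_perm, n_boot = n_boot,
         tail_q = tail_q, tensor_fast_path = tensor_fast_path, seed = seed),
    class = "plv_pipeline_config"
  )
}

# Canonical JSON of a config, used for hashing and serialization.
config_json <- function(config) {
  ser <- rapply(unclass(config), function(x) x, how = "replace")
  jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, force = TRUE)
}

# md5 digest of a character scalar (via tools::md5sum on a temp file).
text_md5 <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' Executes simulate -> connectivity -> classification -> PLS, writing every
#' artifact plus a run manifest (config hash, per-stage seeds and wall
#' times, output file digests) to `out_dir`. A rerun with the same config
#' reproduces all numeric outputs exactly; a stage failure halts the run
#' with the failing stage named and leaves a `FAILED` marker.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Writable output directory (created if needed).
#'
#' @return A list with `manifest` and the in-memory stage `results`,
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "plv_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = text_md5(config_json(config)),
                   seeds = list(simulate = config$seed + 1L,
                                classify_null = config$seed + 2L,
                                pls_permutation = config$seed + 3L,
                                pls_bootstrap = config$seed + 4L),
                   stages = list())
  results <- list()
  stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      plv_abort(sprintf("pipeline stage '%s' failed: %s", name,
                        conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(
      wall_time_s = proc.time()[["elapsed"]] - t0)
    out
  }

  grid <- make_frequency_grid(config$n_freq, config$f_min_hz, config$f_max_hz)

  sim <- stage("simulate", function() {
    if (config$tensor_fast_path) {
      out <- simulate_plv_tensor(config$simulation, grid)
      list(tensor = out$tensor, subjects = out$subjects)
    } else {
      out <- simulate_cohort(config$simulation)
      list(timeseries = out$timeseries, subjects = out$subjects)
    }
  })
  write_subject_table(sim$subjects, file.path(out_dir, "subjects.csv"))

  tensor <- stage("connectivity", function() {
    if (!is.null(sim$tensor)) sim$tensor else
      compute_connectivity(sim$timeseries, grid, config$n_cycles)
  })
  write_plv_tensor(tensor, file.path(out_dir, "plv_tensor.csv"))
  results$tensor <- tensor
  results$subjects <- sim$subjects

  cls <- stage("classify", function() {
    by_wavelet <- accuracy_by_wavelet(tensor, sim$subjects, config$cost)
    by_band <- accuracy_by_band(tensor, sim$subjects, config$cost)
    f_idx <- grid$freq_index[grid$band == config$band]
    band_feats <- feature_set(tensor, sim$subjects, f_idx)
    kcurve <- accuracy_vs_k(band_feats, config$k_max, config$cost)
    null <- permutation_null(band_feats, k_best = kcurve$best_k,
                             cost = config$cost, n_perm = config$n_perm,
                             seed = config$seed + 2L)
    conf <- confidence_score_correlation(kcurve, sim$subjects, "severity")
    list(by_wavelet = by_wavelet, by_band = by_band, kcurve = kcurve,
         null = null, confidence = conf)
  })
  readr::write_csv(cls$by_wavelet, file.path(out_dir, "accuracy_by_wavelet.csv"),
                   progress = FALSE)
  readr::write_csv(cls$by_band, file.path(out_dir, "accuracy_by_band.csv"),
                   progress = FALSE)
  readr::write_csv(cls$kcurve$curves, file.path(out_dir, "accuracy_vs_k.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(observed = cls$null$observed, p_value = cls$null$p_value,
         n_perm = cls$null$n_perm, null_accuracies = cls$null$accuracies),
    file.path(out_dir, "classification_null.json"),
    auto_unbox = TRUE, digits = NA)
  results$classification <- cls

  pls <- stage("pls", function() {
    em <- build_element_matrix(tensor, sim$subjects)
    perm <- lv_permutation_test(em, "contrast", n_perm = config$n_perm,
                                seed = config$seed + 3L)
    bsr <- bootstrap_ratios(em, "contrast", n_boot = config$n_boot,
                            seed = config$seed + 4L)
    tails <- tail_counts(bsr, config$tail_q)
    beh <- sim$subjects$days_since_injury[
      match(em$subject_id, sim$subjects$subject_id)]
    beh_fit <- behavioural_pls(em, beh)
    beh_perm <- lv_permutation_test(em, "behavioural", behaviour = beh,
                                    n_perm = config$n_perm,
                                    seed = config$seed + 3L)
    beh_bsr <- bootstrap_ratios(em, "behavioural", behaviour = beh,
                                n_boot = config$n_boot,
                                seed = config$seed + 4L)
    beh_tails <- tail_counts(beh_bsr, config$tail_q)
    list(contrast_perm = perm, contrast_bsr = bsr, contrast_tails = tails,
         behavioural = beh_fit, behavioural_perm = beh_perm,
         behavioural_tails = beh_tails)
  })
  readr::write_csv(pls$contrast_tails, file.path(out_dir, "contrast_tail_counts.csv"),
                   progress = FALSE)
  readr::write_csv(pls$behavioural_tails,
                   file.path(out_dir, "behavioural_tail_counts.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(contrast = list(singular_value = pls$contrast_perm$singular_value[1],
                         p_value = pls$contrast_perm$p_value[1]),
         behavioural = list(singular_value = pls$behavioural_perm$singular_value[1],
                            p_value = pls$behavioural_perm$p_value[1],
                            overall_correlation = drop(pls$behavioural$left))),
    file.path(out_dir, "pls_summary.json"), auto_unbox = TRUE, digits = NA)
  results$pls <- pls

  files <- setdiff(list.files(out_dir), c("manifest.json", "FAILED"))
  manifest$file_digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$file_digests) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results))
}
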