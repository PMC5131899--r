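# plvnet

Frequency-resolved phase-synchronization analysis of resting-state
source-level MEG/EEG recordings, with the two statistical engines most often
layered on top of it: nested cross-validated linear SVM classification and
partial least squares (PLS).

Resting-state neurophysiological recordings carry frequency-specific
inter-regional coupling that conventional imaging misses — for example,
altered alpha-band synchrony after mild traumatic brain injury. `plvnet`
implements the full analysis chain a researcher needs to quantify such
coupling and test whether it separates clinical groups, starting from
source-level time series:

1. **Connectivity.** Each signal is decomposed with constant-Q complex
   Morlet wavelets on a logarithmic frequency grid (30 points over 1–75 Hz
   by default), and the phase-locking value between regions *x* and *y* at
   frequency *f* is the resultant length of the relative-phase phasor

   PLV<sub>x,y</sub>(f) = | ⟨ e<sup>iΔφ<sub>x,y</sub>(τ,f)</sup> ⟩<sub>τ</sub> | ∈ [0, 1],

   computed within epochs over edge-valid samples and averaged across
   epochs. With 90 AAL regions this yields 30 matrices of 90×90 (4005
   unordered pairs) per subject.
2. **Classification.** Leave-one-out cross-validated linear soft-margin SVM
   over feature subsets: per wavelet frequency, per canonical band (δ, θ,
   α, β, lower γ), or the top-k features ranked per training fold by the
   direction-folded ROC area max(AUC, 1−AUC). Significance comes from
   label-shuffle permutation nulls that re-run the entire nested pipeline;
   per-subject confidence is the signed distance (ωᵀx + b)/‖ω‖ to the
   decision boundary, which can be correlated with clinical scores.
3. **PLS.** Mean-centred contrast PLS and behavioural PLS on the subjects ×
   elements matrix (elements = frequency × pair combinations; 30 × 4005 =
   120,150 at full scale), with permutation tests on singular values,
   bootstrap ratios (salience / bootstrap SE, read like z-scores), 1 %
   tail-count profiles across frequencies, and pooled-variance two-sample
   proportion z-tests between band-central frequencies.
4. **Synthetic cohorts.** A coupled-oscillator generator plants
   frequency-specific effects (e.g. alpha hyperconnectivity with
   delta/gamma hypoconnectivity in a patient group), couples clinical
   scores to the realized alpha coupling, and draws a days-since-injury
   covariate negatively correlated with it — so every stage of the pipeline
   is testable end to end without access to raw recordings. A Beta-model
   fast path draws PLV tensors directly when signal synthesis is not
   needed.

## Worked example

A synthetic cohort of 20 patients vs 21 controls over 12 regions, with an
alpha-band (11 Hz) coupling effect (κ = 0.8 vs 0.3) planted on four region
pairs, analysed on a 12-point 2–48 Hz grid:

```r
library(plvnet)

grid <- make_frequency_grid(12, 2, 48)
cfg <- sim_config(
  n_group_a = 20, n_group_b = 21, n_regions = 12,
  n_epochs = 5, epoch_duration_s = 10, sampling_rate_hz = 600,
  effects = list(effect_spec(11, cbind(c(1, 3, 5, 7), c(2, 4, 6, 8)),
                             kappa_group_a = 0.8, kappa_group_b = 0.3)),
  seed = 42)
out <- simulate_plv_tensor(cfg, grid)   # fast path; simulate_cohort() +
out$tensor                              # compute_connectivity() for signals
#> <plv_tensor> 41 subjects x 12 frequencies (2-48 Hz) x 66 pairs (12 regions)

accuracy_by_band(out$tensor, out$subjects)
#> # A tibble: 5 × 5
#>   band  n_frequencies sensitivity specificity accuracy
#> 1 delta             3        0.45       0.381    0.415
#> 2 theta             2        0.45       0.429    0.439
#> 3 alpha             2        0.8        0.952    0.878
#> 4 beta              3        0.5        0.429    0.463
#> 5 gamma             2        0.6        0.524    0.561
```

Only the band holding the planted effect classifies above chance (88 %
accuracy in α; the others hover at the 21/41 majority rate). A
label-shuffle null on the alpha features confirms it:

```r
alpha_feats <- feature_set(out$tensor, out$subjects,
                           grid$freq_index[grid$band == "alpha"])
glance(permutation_null(alpha_feats, k_best = 8, n_perm = 99, seed = 1))
#>   observed p_value n_perm
#> 1    0.927    0.01     99
```

Contrast PLS finds exactly one significant latent variable (a two-group
mean-centred cross-block has rank 1), and the bootstrap-ratio tails
concentrate at the planted frequency:

```r
em <- build_element_matrix(out$tensor, out$subjects)
lv_permutation_test(em, "contrast", n_perm = 199, seed = 1)
#>      lv singular_value p_value
#> 1     1       4.01e- 1   0.005
#> 2     2       1.14e-16   0.645

bsr <- bootstrap_ratios(em, "contrast", n_boot = 199, seed = 1)
bsr
#> <plv_bsr> 792 elements, 199 bootstrap samples; |ratio| >= 3: 12
tail_counts(bsr, tail_q = 0.02)   # peaks at the 11.3 Hz grid point
```

`autoplot()` methods cover the accuracy-vs-k curves, null distributions and
bootstrap-ratio histograms; `plot_tail_counts()` and
`plot_connectivity_matrix()` display frequency profiles and connectivity
maps; `tidy()`/`glance()` turn every fitted object into a tibble.
`run_pipeline(pipeline_config(...), out_dir)` chains simulate → PLV →
classify → PLS with a reproducibility manifest.

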