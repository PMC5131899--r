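---
title: "Phase-locking networks: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking networks: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvnet)
```

`plvnet` quantifies frequency-specific phase coupling between reconstructed
brain sources and tests group and behavioural effects on the resulting
connectivity tensors. This vignette explains the models behind each stage,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical decisions taken where the methodology left
the design open.

## Phase-locking connectivity

### Time–frequency decomposition

A source signal $x(t)$ is convolved with constant-Q complex Morlet
wavelets: at centre frequency $f$ the kernel is a Gaussian-windowed complex
exponential with temporal SD $\sigma_t = n_c / (2\pi f)$, so every kernel
spans the same number of cycles $n_c$ and bandwidth scales with frequency.
The complex coefficients $W_x(\tau, f)$ carry instantaneous amplitude
$|W_x|$ and phase $\arg W_x$.

Three choices deserve comment:

* **Complex kernel.** Phase extraction requires a complex (analytic)
  kernel; a real kernel such as the Mexican hat has no instantaneous
  phase. The package therefore uses the complex Morlet family, the
  standard choice for constant-cycle phase analysis.
* **Cycles, $n_c = 7$ by default.** A 7-cycle kernel at 1 Hz spans
  $\pm 3.5\,\sigma_t \approx \pm 3.9$ s, which still fits a 10-s epoch
  with a usable valid region, while giving a frequency resolution of
  $f/7$. The value is exposed everywhere (`n_cycles`).
* **Edge masking.** Samples closer than half the kernel support to an
  epoch boundary are flagged invalid and excluded from every average;
  unmasked edges would bias the PLV upward. A frequency whose kernel
  exceeds the epoch is reported as missing (`NA`), never as zero.

The kernel is forced exactly zero-mean (the envelope-shaped DC component is
subtracted), so constant offsets contribute nothing, and scaled so a
unit-amplitude tone at the centre frequency yields $|W| \approx 1$.

### Phase-locking value

The relative phase is $\Delta\phi_{x,y}(\tau, f) =
\arg\left(W_x \overline{W_y}\right)$, wrapped to $(-\pi, \pi]$, and the PLV
at $f$ is the resultant length of the unit phasors over valid times:
$\mathrm{PLV} = |\langle e^{i\Delta\phi}\rangle_\tau| \in [0, 1]$. PLV is 1
for a constant phase difference and decays to a finite-sample floor for
scattered phases; it is symmetric in its inputs and deliberately blind to
amplitude correlation. PLVs are computed within each epoch and averaged
arithmetically across epochs (so connectivity over epochs $1..k$ is the
running mean of per-epoch matrices — a tested invariant).

Two estimator properties matter when interpreting values:

* **Finite-sample floor.** For independent phases the expected PLV is not
  0 but roughly $\sqrt{\pi/(4 N_\mathrm{eff})}$, where $N_\mathrm{eff}
  \approx T_\mathrm{valid} / (2\sigma_t)$ counts kernel-decorrelated
  samples. The floor therefore *rises* toward low frequencies (longer
  kernels, fewer independent samples): roughly 0.13 at 11 Hz for a 10-s
  epoch and 0.07 at 48 Hz.
* **Windows matter.** The relative phase of weakly coupled oscillators
  wanders slowly, so PLVs computed over different time windows of the same
  record legitimately differ; the test suite compares the wavelet
  estimator against an analytic-signal (quadrature) oracle over a common
  core window, where they agree within 0.05.

### Grid, bands and pairs

The default analysis grid has 30 points equally spaced on a log scale from
1 to 75 Hz (consecutive ratio $75^{1/29} \approx 1.1605$). Canonical bands
partition the grid as δ 1–4, θ 4–8, α 8–14, β 14–28, lower γ 28–75 Hz;
band intervals are half-open $[l, h)$ except the last, so a boundary
frequency such as exactly 8 Hz belongs to the higher band. Band-central
wavelets are the grid points nearest 2, 6, 11, 23 and 48 Hz (ties resolve
to the lower frequency, out-of-range targets clamp to the endpoints).
Unordered region pairs are indexed row-major over the strict upper
triangle; with 90 regions there are 4005 pairs per frequency. The packaged
AAL-90 region table (names, MNI seed coordinates, lobes) is labelling
metadata only and never enters computation.

## Classification

Subjects are points in a feature space of PLVs; a linear soft-margin SVM
(cost `c`, default 1) learns the boundary, and accuracy is estimated by
leave-one-out cross-validation. Three feature-selection schemes mirror the
typical workflow: per wavelet frequency, per canonical band, and best-k
features within a band ranked by ROC area.

Design decisions, each tested:

* **No leakage.** Ranking and column standardisation use the training fold
  only. A constructed "outlier canary" test verifies that full-data and
  training-fold rankings genuinely differ when the held-out subject is
  extreme.
* **Folded AUC.** A feature discriminating in either direction is equally
  useful to a linear model, so ranking uses $\max(\mathrm{AUC},
  1-\mathrm{AUC})$, computed by exhaustive Mann–Whitney pair counting with
  ties contributing 1/2; a constant column scores exactly 0.5. Ties in the
  ranking break deterministically by (frequency, pair, column) order.
* **Standardisation.** Columns are z-scored with training-fold statistics;
  PLV variances differ systematically across frequencies and would
  otherwise dominate the margin.
* **Confidence.** The signed Euclidean distance $(\omega^T x + b) /
  \lVert\omega\rVert$ (positive side = patient) is comparable across folds
  with different $\lVert\omega\rVert$; misclassified patients carry
  negative distances. Correlating patient distances with clinical scores
  per k yields the confidence–symptom curves.
* **Permutation null.** Every label shuffle re-runs the entire nested
  pipeline including per-fold ranking — the only unbiased reading of
  "repeat the same procedure" — with the add-one estimator $p = (1 +
  \#\{\mathrm{null} \ge \mathrm{obs}\}) / (n_\mathrm{perm} + 1)$, which
  cannot return 0.
* **Robustness map.** For each wavelet in a band and each fold, a
  connection selected into the top-k is scored −1 (else 0); averaging over
  (fold, wavelet) cells gives weights in $[-1, 0]$ where −1 means
  "selected always".

The SVM itself is standard machinery and is delegated to libsvm
(`e1071::svm`, linear kernel); weights and bias are extracted and
sign-normalised so the positive side is always the patient class.

## Partial least squares

The data matrix is subjects-within-groups × elements, one column per
(frequency, pair) combination — 120,150 columns at full scale, ordered
frequency-major with an exactly invertible element ↔ tensor-cell mapping.

* **Contrast PLS** centres the per-group element means on their
  (unweighted) grand mean and decomposes the groups × elements matrix by
  SVD. With two groups the centred matrix has rank 1: exactly one nonzero
  singular value, an antisymmetric group contrast on the left, element
  saliences on the right. $\sum s^2$ equals the squared Frobenius norm of
  the cross-block matrix (tested to 1e−10).
* **Behavioural PLS** correlates each element with a continuous covariate
  (days since injury in the motivating design, patients only by default);
  the 1 × elements matrix of Pearson correlations has a single latent
  variable whose saliences are proportional to the per-element
  correlations, and the reported left value is the correlation between the
  latent brain score and the behaviour. Correlations rather than
  covariances are used so elements with larger variance do not dominate.
* **Permutation tests** shuffle group membership (contrast) or the
  behaviour vector (behavioural) and compare permuted singular values to
  the observed ones with the add-one estimator.
* **Bootstrap ratios** resample subjects with replacement within groups
  (degenerate resamples with fewer than two distinct subjects are redrawn,
  with a capped retry count), align each resample's saliences to the
  original by the sign of their dot product — sufficient for a single
  latent variable — and report salience / bootstrap SE, read like a
  z-score with |3| as the conventional stability threshold.
* **Tail profiling** thresholds the pooled ratio distribution at its
  empirical `tail_q` and `1 − tail_q` quantiles (linear interpolation;
  ties at the threshold fall inside the tail) and counts elements per grid
  frequency in each tail. Differences between frequencies are tested with
  the pooled-variance two-sample proportion z-test (no continuity
  correction), each frequency contributing counts out of its 4005
  connections at full scale.
* **Band maps** average each connection's ratio across a band's wavelets
  and zero entries failing a one-sided threshold, returning the symmetric
  region × region matrix.

## The synthetic cohort generator

The generator exists so that every downstream stage can be exercised, at
desk scale, against data whose ground truth is known. It emulates: two
groups (20 patients vs 21 controls by default), frequency-specific
inter-regional phase coupling with group-specific strength (by default
alpha hyperconnectivity with delta/gamma hypoconnectivity in patients),
clinical severity and symptom scores positively coupled to each subject's
realized alpha coupling, and a days-since-injury covariate negatively
rank-correlated with it.

### Coupling model

Each planted effect lists region pairs and a band-centre frequency. Within
an effect, the connected components of the pair graph share a common slow
Wiener phase drift $C(t)$ (rate 1 rad/√s, keeping signals narrowband);
region $r$'s oscillator at the effect frequency carries phase

$$\phi_r(t) = \theta_r + 2\pi f t + C(t) + (1 - \kappa)\, D_r(t),$$

with independent fast diffusions $D_r$ (rate 8 rad/√s) and the subject's
coupling weight $\kappa$. The common drift cancels in any within-component
phase difference, which therefore diffuses with variance $2(1-\kappa)^2
\cdot 64\, t$: PLV is exactly 1 at $\kappa = 1$ (constant lag), decays
monotonically, and reaches the estimator floor at $\kappa = 0$. The
closed-form RMS of the epoch-mean phasor, `expected_plv()`, follows from
the double integral of the phase autocovariance and doubles as the Beta
mean of the tensor fast path. Unplanted regions receive their own slow
drift plus full-rate diffusion, so planted and unplanted pairs differ only
in coupling. If a listed component is not a clique, unlisted pairs inside
it inherit coupling — phase synchrony is transitive within a shared driver
— so disjoint pairs or cliques are the faithful configurations.

Every region also receives $1/f$ pink noise (SD 1.0 relative to the unit
oscillators, exponent 1), a realistic spectral backdrop with no extra
parameters.

### Calibration (fixed once)

The diffusion rate 8 rad/√s was chosen so the measured independent-pair
wavelet PLV floor over 10-s epochs sits near 0.1 (closed form 0.056 plus
the kernel-limited estimator floor), comfortably below the 0.15 the design
targets, while $\kappa = 0.8$ yields a clearly elevated PLV. Subject-level
coupling variability (`kappa_subject_sd = 0.05`) propagates through the
convex $\kappa \mapsto$ PLV map; with the resulting deviation scale, the
score couplings (70 and 31 with truncated Gaussian noise of SD 17 and 5)
target severity $\approx 20 \pm 19$ and symptoms $\approx 9 \pm 6$, and
days since injury is drawn uniformly on 3–90 days then rank-remapped to a
target correlation of −0.5 with the subject's alpha coupling. Only summary
moments are targeted — the empirical score distributions of any real
cohort are unknown — so tests assert signs and moments, not shapes.

### What the generator does not emulate

No sensor physics, volume conduction or beamformer leakage; no amplitude
correlation between regions; no artefacts or head motion; no spatial
structure beyond the planted pairs (the AAL table is labelling only).
Passing tests therefore demonstrate that the estimators and statistics
recover known coupling structure at realistic sample sizes — not that any
particular real-data effect will replicate.

## Problem sizes and numerical choices

The test fixtures use a 12-point 2–48 Hz grid (every canonical band
populated while a 7-cycle kernel fits short epochs; the pair-level
primitives are checked at the 48 Hz grid point, where the estimator floor
is lowest), cohorts of 12–41 subjects over 5–12 regions, epochs of 5–10 s
at 150–600 Hz, and reduced resampling counts (permutations 19–199,
bootstraps 50–199). Behavioural-PLS recovery uses 60 patients: a
behavioural design needs more subjects than a group contrast for the same
power, and at desk scale a 5 % tail keeps the per-frequency profile
informative where a 1 % tail of a few hundred elements holds only ~3
elements. The full study scale (90 regions, 30 frequencies, 27 × 10-s
epochs at 600 Hz, 500 permutations and bootstraps) is reachable through
the same configuration objects.

Other numerical decisions: CSV payloads are written in shortest
round-trip double representation and read back with base R's exactly
rounded parser, so write-then-read is bit-identical; all stochastic
functions take explicit seeds and restore the RNG state (`withr`), with
pipeline stage seeds derived from the global seed by fixed offsets; ties
are broken deterministically everywhere (documented orderings), so equal
seeds give byte-identical outputs.

## Known limitations

* PLV captures zero-lag-inclusive phase coupling and is susceptible to
  volume conduction in real source-reconstructed data; leakage-robust
  variants (imaginary coherence, weighted phase-lag index) are out of
  scope.
* Absolute classification accuracies and salience magnitudes depend on the
  SVM cost, standardisation and centering conventions; cross-study
  comparisons should rely on the permutation and bootstrap statistics, not
  raw magnitudes.
* The permutation null re-runs the full nested pipeline per shuffle, which
  is the unbiased but expensive choice; budget accordingly
  (`n_perm` × subjects × SVM fits).
* One latent variable is the interpretable regime here (two groups or one
  behaviour); multi-behaviour designs and rotated PLS variants are not
  implemented.
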