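# eegmvpa

Time-resolved multivariate decoding of epoched EEG, with group-level
permutation inference — as used to ask *when* the brain distinguishes
visual object categories (e.g. hands vs. tools vs. animals) from the
pattern of activity across the scalp at each millisecond after stimulus
onset.

The package is aimed at cognitive-neuroscience researchers who want a
reproducible, fully testable R implementation of this analysis stack:

- **Signal conditioning** — spectral downsampling, zero-phase 0.5–40 Hz
  band-pass, re-referencing to the average of the two mastoids, epoch
  cropping and pre-stimulus baseline correction.
- **Automatic artifact rejection** — a data-driven peak-to-peak threshold
  applied *across trials per electrode* and then *across electrodes per
  trial*, with inverse-distance interpolation of bad electrodes or
  exclusion of trials with too many of them.
- **Per-timepoint decoding** — shrinkage-regularised linear discriminant
  analysis (LDA) on z-scored scalp patterns under balanced k-fold
  cross-validation; cross-classification (train on one category contrast,
  test on a held-out category) and temporal generalization (train at time
  *t*, test at every *t'*).
- **Group inference** — threshold-free cluster enhancement (TFCE) of the
  group-mean accuracy map plus a maximal-statistic permutation null,
  converted to rank-based z maps, averaged over cross-validation
  repetitions and thresholded at |z| > 1.96.
- **Synthetic EEG** — a generator that plants known rank-one
  spatiotemporal category effects (topography × envelope) and artifacts
  into AR(1) noise, so every stage above can be validated against ground
  truth.

## The model in brief

At each timepoint *t*, the scalp pattern **x** ∈ ℝᵖ (p = 63 electrodes) is
classified between two conditions by LDA: **w** = S⁻¹(μ₁ − μ₀) with the
pooled within-class covariance S̃ shrunk toward a scaled identity,
S = (1 − λ) S̃ + λ (tr S̃ / p) I, λ estimated analytically (Ledoit–Wolf).
Accuracy(t) is the mean over k = 10 balanced held-out folds, repeated 20
times with fresh fold assignments. Group significance uses
TFCE(v)(s) = Σ_h e(s,h)^E · h^H · dh (E = 0.5, H = 2) on the
chance-subtracted group mean, compared against the distribution of the
maximal TFCE statistic under N = 100 within-subject label permutations;
rank p-values map to z via Φ⁻¹(1 − p), so with N = 100 the attainable
ceiling is z = Φ⁻¹(100/101) ≈ 2.33.

## Worked example

```r
library(eegmvpa)

# a small synthetic study: a shared hands/tools pattern at 250-350 ms
cfg <- sim_config(
  n_subjects = 6, n_trials_per_condition = 48,
  conditions = c("hands", "tools", "animals"),
  n_scalp_channels = 16, sfreq = 100, epoch_window = c(-100, 500),
  effects = list(effect_spec(c("hands", "tools"), c(250, 350),
                             amplitude = 2.5, topography_seed = 3)),
  seed = 21)
study <- lapply(simulate_study(cfg), `[[`, "epochs")

res <- group_decode_test(study, condition_pair("hands", "animals"),
                         k = 5, n_repetitions = 2, n_perm = 50, seed = 5)
res
#> <zmap> group decode: hands vs animals: 60 timepoints, 10 significant point(s) (|z| > 1.96), 1 cluster(s)
res$clusters
#> # A tibble: 1 × 8
#>   cluster  sign onset offset peak_time peak_z peak_accuracy n_points
#>     <int> <dbl> <dbl>  <dbl>     <dbl>  <dbl>         <dbl>    <int>
#> 1       1     1   250    340       250   2.06         0.925       10
```

The z-map says decoding of hands vs. animals beats chance only between
250 and 340 ms — exactly where the generator planted the shared pattern —
with a peak cross-validated accuracy of 0.93 and a z near the
50-permutation ceiling. `tidy()`, `glance()` and `autoplot()` work on
every result object; `run_pipeline()` executes the whole chain
(simulate → preprocess → reject → decode → infer → report) from a single
YAML/JSON config and writes CSV/JSON artifacts plus a checksummed
manifest.

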