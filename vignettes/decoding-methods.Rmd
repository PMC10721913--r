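---
title: "Time-resolved EEG decoding with eegmvpa: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved EEG decoding with eegmvpa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmvpa)
```

## What the pipeline estimates

Multivariate decoding asks, at every timepoint of an epoched EEG recording,
whether the joint pattern of voltages across scalp electrodes carries
information about the experimental condition. The pipeline implemented here
covers the full chain for a visual-category design (hands, tools, feet,
animals; two-class contrasts such as hands vs. animals):

1. signal conditioning (resample, band-pass, re-reference, crop, baseline);
2. automatic artifact rejection;
3. per-timepoint linear decoding with cross-validation, plus
   cross-classification and temporal generalization;
4. group-level inference with threshold-free cluster enhancement (TFCE)
   and maximal-statistic permutation testing.

A synthetic-data generator with known ground truth sits beside the
pipeline so that every stage can be validated quantitatively; it is
first-class, tested code, not a fixture.

## The decoding model

At timepoint $t$ the feature vector is the scalp pattern
$\mathbf{x} \in \mathbb{R}^p$ (mastoid and EOG channels are never
features). Features are z-scored per channel using training-set statistics
only, and a two-class linear discriminant is fit from the class means
$\mu_0, \mu_1$ and the pooled within-class covariance $\tilde S$
(maximum-likelihood normalisation), shrunk toward a scaled identity:

$$ S = (1-\lambda)\,\tilde S + \lambda\,\frac{\operatorname{tr}\tilde S}{p} I,
\qquad \mathbf{w} = S^{-1}(\mu_1 - \mu_0), \qquad
b = -\tfrac12\,\mathbf{w}\cdot(\mu_1 + \mu_0). $$

A sample is assigned the target class iff $\mathbf{w}\cdot\mathbf{x} + b >
0$; an exact tie goes to the control class, so predictions are
deterministic. By default $\lambda$ is the analytic Ledoit–Wolf estimate
computed from the class-centred training rows: with 63 channels against
roughly two hundred training trials the raw covariance is poorly
conditioned, and an analytic intensity avoids a nested cross-validation
loop. `lambda = 0` is supported (and used in the oracle tests, where the
discriminant has a closed form).

Accuracy at $t$ is the mean over $k = 10$ balanced held-out folds. Fold
balancing truncates both classes to a common size divisible by $k$
(seeded random subsample) and deals each class evenly across folds, so
equal priors hold by construction and 0.5 is the exact chance level. The
whole procedure is repeated (default 20 times) with fresh fold
assignments; both the fold assignment and the balancing subsample are
redrawn per repetition, since the two sources of sampling variability are
not separable in practice.

Cross-classification trains on *all* balanced trials of one contrast
(e.g. tools vs. animals) and scores the fraction of held-out-category
trials (e.g. hands) assigned to the target; no cross-validation is needed
because the test category is disjoint from training. Temporal
generalization applies the classifier fit at train-time $t$ to test
features at every $t'$; test features at $t'$ are standardised with the
*training-pair* statistics computed at $t'$, so only the classifier —
never the scaler — crosses time. Under a shared seed the matrix diagonal
reproduces the matched-time cross-classification exactly, and this
identity is asserted in the test suite.

## Group inference

Per repetition, subject accuracy maps are averaged, chance (0.5) is
subtracted and the map is TFCE-transformed:

$$ \mathrm{TFCE}(s) = \sum_{h = dh,\,2dh,\dots}^{v(s)} e(s,h)^{E}\, h^{H}\, dh $$

with the method's standard exponents $E = 0.5$, $H = 2$, step
$dh = \max|v|/100$ (adaptive per map; the sum is a Riemann approximation
of the same integral on every map, so the observed and null statistics
remain comparable), 2-neighbour connectivity on timecourses and
4-neighbour on train × test grids. Negative excursions are handled by
transforming $+v$ and $-v$ separately and recombining with sign.

The null is maximal-statistic: condition labels are permuted across
trials independently within each subject, the whole group map is
recomputed, and the maximum (and minimum) TFCE value over all points is
recorded; with $N$ permutations the per-point one-tailed rank p-value is
$p^{+} = (1 + \#\{\max_\text{null} \ge v\})/(N+1)$ and symmetrically
$p^{-}$ against the minima. The z-map is $\Phi^{-1}(1-p)$ for the
dominant tail, signed accordingly, and floored at zero evidence: a point
extreme in neither tail gets $z = 0$ rather than a spuriously negative
value (the naive transform would assign $z \approx -2.33$ to every
unremarkable point and break the two-tailed mask). With $N = 100$ the
attainable ceiling is $\Phi^{-1}(100/101) = 2.33$ (2 d.p.). Repetition
z-maps (default 20) are averaged and the significance mask is recomputed
on the average at $|z| > 1.96$; each repetition draws its own null, as a
repetition is a complete analysis.

For comparing two decoding analyses on the same subjects (e.g. tools vs.
animals against hands vs. animals), the paired test uses the per-subject
accuracy difference per timepoint and a sign-flip null — swapping the
pair assignment within a random subset of subjects — because the subject
is the natural exchangeable unit there, while trial-label permutation
remains the default for tests against chance.

## Preprocessing: numerical choices

* **Time windows are half-open** `[start, end)` everywhere, so the
  analysis window \[-100, 500) ms at 250 Hz contains exactly 150
  samples, and a baseline of \[-200, 0) never includes the onset sample.
* **Resampling** is spectral (Fourier-domain truncation at the new
  Nyquist), the method used by mainstream M/EEG software; only integer
  output lengths are accepted (1000 → 250 Hz in the reference chain). It
  is exact for band-limited periodic content; for aperiodic epochs the
  implicit circularity can touch the outermost samples, which the
  subsequent filtering padding and the analysis crop both discard.
* **Band-pass filtering** uses a symmetric FIR kernel built by frequency
  sampling of a raised-cosine target response (transition width 0.5 Hz at
  the low edge, 10 Hz at the high edge), Hann-tapered to half-length
  0.4 s and re-centred so the DC gain is exactly zero. A symmetric kernel
  has zero phase by construction, satisfying the bidirectional-filtering
  contract (no net phase shift) in a single pass. It is applied by exact
  FFT-based linear convolution over odd-reflection padding. Two caveats
  are inherent to epoch-length data and documented rather than hidden:
  the effective low-edge transition is widened by the kernel's finite
  support, and padding transients contaminate roughly the outermost
  kernel half-length of the epoch for signals with strong edge
  mismatch. A windowed-FIR design applied forward–backward was evaluated
  first; at epoch-feasible orders its DC gain was 0.83, and forcing the
  DC null distorted the 10 Hz passband by 7%, so the frequency-sampled
  design above was adopted instead.
* **Re-referencing** subtracts the mean of the named mastoid channels
  from every channel; afterwards the mastoid average is identically zero.
* The chain order is fixed: resample, filter, re-reference, crop,
  baseline. Resampling before filtering mirrors the reference pipeline;
  the anti-aliasing burden is negligible because the 40 Hz band edge sits
  far below the 125 Hz post-resampling Nyquist.

## Artifact rejection

The data-driven threshold works on a group of equal-length signals: the
candidate set is the observed unique peak-to-peak values (the objective
only changes there); for a candidate $\theta$, the objective is the sum
of squared differences between the mean of the signals with
$\mathrm{p2p} \le \theta$ (ties kept at $\le$) and the pointwise median
of *all* signals — the median read as a waveform, the only reading that
makes the comparison well-defined. Ties in the objective resolve to the
largest threshold, i.e. reject least. The two passes run across trials
per electrode, then across electrodes per trial, with repair after each
pass: a trial is repaired by inverse-distance interpolation
(weights $1/d$ on unit-sphere electrode positions) when fewer than half
its scalp electrodes are flagged, excluded otherwise.

One refinement proved necessary: electrodes repaired in pass 1 are
excluded from the pass-2 threshold estimation (while still counting as
rejected for the half-electrode rule). An interpolated electrode tracks
the mean of its neighbours almost exactly, so including it lets the
under-threshold-mean-vs-median objective "prefer" keeping only that
electrode and flag all the raw ones — excluding clean trials. With the
refinement, clean simulated data pass with zero exclusions and under 5%
interpolated cells across 20 seeds, while implanted artifacts (5% of
trials, peak-to-peak 10× the clean 99th percentile) are recovered with
recall 1.0.

The threshold objective is scale-sensitive: on very short segments (a few
dozen samples) or very small montages its minimum becomes noisy. The
defaults assume epochs of a few hundred samples and a few dozen
electrodes, the regime of the emulated study.

## The synthetic-data generator

Defaults mirror the emulated study design: 14 subjects, four conditions
(hands, tools, feet, animals) × 128 trials (512 per subject), 63 scalp
electrodes (Fibonacci lattice on the upper unit hemisphere) plus two
mastoids, 1000 Hz sampling, epochs \[-500, 500) ms. Noise is AR(1) with
lag-one coefficient 0.5 and stationary SD 1 µV — enough temporal
autocorrelation to be EEG-like while staying analytically tractable;
white noise is available for closed-form checks. Category effects are
rank-one: a unit-norm random topography times a boxcar or half-cosine
envelope, scaled in microvolts, optionally jittered across subjects
(SD 20% of amplitude) so group statistics see realistic between-subject
variance. A single effect assigned to several conditions is the synthetic
analogue of a shared neural code, and is what makes cross-classification
and temporal generalization succeed inside — and only inside — its
window. Artifacts are implanted by rescaling chosen trial × electrode
segments to a peak-to-peak of `multiplier` × the 99th percentile of the
clean distribution; since the rejection algorithm only sees peak-to-peak,
amplitude scaling suffices and no blink/EMG realism is attempted.

Because the study's published accuracies come from real EEG, the
generator's signal-to-noise defaults are calibrated qualitatively: the
high-SNR validation settings produce near-ceiling within-window decoding,
and no attempt is made to match printed accuracy values, which depend on
unmodelled properties of real recordings (channel covariance structure,
non-stationarity, inter-subject topography variability). Passing tests
therefore demonstrate correctness of the machinery and calibration of the
inference, not that real data would yield any particular accuracy.

## Validation scales

The test suite validates the inference at reduced problem sizes chosen as
the package's own trade-off between statistical resolution and runtime:

* chance-level calibration and family-wise error: 200 simulated no-effect
  studies of 8 subjects × 64 trials/condition, 5 repetitions × 50
  permutations each, on a 10-channel, 12-timepoint grid;
* onset-latency recovery: 20 studies of 6 subjects with a boxcar effect
  at \[136, 156) ms on a 250 Hz grid (16 channels), onsets required
  within ±8 ms (two samples);
* cross-classification/temporal generalization: 6 subjects, a shared
  hands/tools pattern at \[250, 350) ms on a 100 Hz grid.

With 50 permutations the attainable $|z|$ is $\Phi^{-1}(50/51) = 2.06$,
still above the 1.96 cutoff, so significance is attainable and the
max-statistic construction bounds the family-wise error near
$2/51 \approx 0.04$ per tail direction pair.

## Known limitations

* No biophysical forward model: topographies are random unit vectors, not
  dipolar fields; spatial covariance between channels is absent from the
  noise model.
* The band-pass low edge is honest only down to ~2–3 Hz on 1 s epochs;
  true 0.5 Hz filtering requires continuous recordings.
* Interpolation is inverse-distance, not spherical-spline; adequate for
  repair bookkeeping, coarser than a production re-referencing tool.
* The rank-based z saturates at the permutation ceiling, so peak z values
  are censored at $\Phi^{-1}(N/(N+1))$ — a property of the method, not a
  bug, and the reason peak z values cluster at 2.33 when $N = 100$.
* Cross-classification's 0.5 reference is a no-bias point, not a
  cross-validated chance level; its significance is always assessed
  against the permutation null, never against 0.5 parametrically.
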