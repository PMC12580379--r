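---
title: "Methods: EEG microstate dynamics and bilateral actigraphy in a synthetic stroke cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG microstate dynamics and bilateral actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdyn)
```

## Scope

`microdyn` implements the analysis chain used to relate resting-state
EEG microstate temporal dynamics and spontaneous bilateral arm activity
to clinical status after middle-cerebral-artery stroke: EEG
preprocessing, polarity-invariant microstate segmentation with its four
temporal parameter families, wrist-actigraphy asymmetry metrics, and a
covariate-adjusted group-comparison layer with FDR control. Because no
patient recordings are distributed, the package ships a first-class
synthetic-data module that generates EEG with planted microstate
structure and paired activity-count series with controlled statistical
structure; every downstream stage is validated against that ground
truth. The `analysis/` scripts run the stages over a simulated cohort.

## The microstate model

At each time sample the scalp potential vector `v(t)` (19 channels,
average reference) is modelled as one of `K = 4` fixed unit-norm
template topographies scaled by a positive amplitude, with polarity
carrying no class information. Global field power,

```
GFP(t) = sqrt( sum_i (v_i(t) - vbar(t))^2 / n ),
```

is the spatial standard deviation across the `n` electrodes
(population convention, divide by `n`). Topographies at local GFP
maxima have the highest signal-to-noise ratio and are the clustering
input.

**Clustering.** `modified_kmeans()` is the standard polarity-invariant
microstate algorithm: assignment maximizes squared spatial correlation
`|corr(v, map)|^2`, and each centroid update takes the first principal
component of its assigned maps (GFP^2-weighted), which is the
maximum-likelihood orientation-free prototype. Because maps are
average-referenced, spatial correlation equals cosine similarity; that
convention fixes every formula in the package. The objective reported
and used for restart selection is the global explained variance

```
GEV = sum_t (GFP(t) * corr(v(t), map_label(t)))^2 / sum_t GFP(t)^2.
```

Empty clusters are re-seeded from the worst-explained map. The fit is
deterministic given its seed; 50 random restarts is the default.

**Group maps and labels.** Individual-subject maps are aggregated by
aligning each model to a reference with the best row permutation under
total absolute correlation (exhaustive over the `k!` permutations,
exact for `k = 4`), flipping signs to positive correlation, averaging
and renormalizing. Canonical labels A-D are assigned against built-in
19-channel templates constructed from the montage geometry: A and B are
the two diagonal frontal-posterior gradients, C the symmetric
anterior-posterior topography, D the fronto-central versus peripheral
pattern. Ties break deterministically toward the smaller label index.

**Back-fitting and parameters.** Every sample is assigned to the map
with the highest absolute spatial correlation; no temporal smoothing is
applied by default, and runs never cross epoch boundaries. Coverage,
mean duration (ms), occurrence (runs/s) and the distinct-state
transition matrix follow the standard definitions; transitions are
conditional on leaving a state (zero diagonal, rows normalized over
states with at least one outgoing event; a state with none has an `NA`
row rather than fabricated zeros). Epoch-final runs contribute no
transition. These definitions give the identity
`coverage = occurrence x duration / 1000` exactly when no run touches
an epoch edge; edge truncation keeps deviations within 2% at the
default epoch layout.

**Flicker and the minimum-duration option.** With per-sample
assignment, additive noise produces brief spurious label switches at
amplitude troughs, which biases mean durations downward (at the
package's default synthetic conditions, snr 4 and 60 ms mean dwell,
unsmoothed mean run lengths sit near 20 ms) while leaving coverage and
the conditional transition structure close to truth. `backfit()`
therefore exposes `min_duration_ms`: segments shorter than the minimum
are absorbed into the neighbouring state with the better correlation,
cascading until none remain. With a 15 ms minimum the recovered
durations land within roughly a third of the generative dwell
(typically overshooting by 10-25%, because genuinely short dwells of a
geometric dwell distribution are merged away too). The option is off by
default; analyses that interpret durations should state the setting.

## Preprocessing chain

`preprocess_recording()` applies, in order: a zero-phase 2nd-order IIR
notch (default 50 Hz, quality factor 30); an artifact-removal hook that
defaults to a no-op (real recordings can insert an ocular/EMG cleaner
here; the synthetic data contains no such artifacts); a zero-phase
order-4 Butterworth band-pass (1-45 Hz per pass, effective order 8
forward-backward); robust bad-channel detection; the dataset exclusion
rule; spherical-spline reconstruction; average referencing; and
selection of five 10-s epochs.

Numerical choices worth stating:

* **Zero-phase filtering** uses odd reflect padding of three filter
  lengths plus steady-state initial conditions per pass (the
  Matlab/SciPy `filtfilt` edge treatment); the implementation is
  numerically equivalent to the reference one to ~1e-15 given the same
  coefficients. Edge-transient energy is fixed per record end, so
  empirical attenuation ratios on short records are dominated by the
  edges, not the stopband.
* **Bad channels**: a channel is bad when its temporal SD, as a robust
  z-score across channels (median/MAD), exceeds 4. A raw
  microvolt-SD threshold of 4 would flag essentially every channel, so
  the standardized reading is the only self-consistent one. The
  criterion is computed after filtering (the chain's order above); the
  functions can be called in any order if a different convention is
  wanted. Recordings with more than two bad channels are excluded, not
  repaired.
* **Spherical spline**: Perrin-style order `m = 4`, Legendre series
  truncated at 50 terms, ridge regularization 1e-5 on the kernel
  diagonal. The interpolator reproduces constant fields exactly and is
  solved once per geometry, then applied to all samples.
* **Epoch selection** takes the `n` lowest total-channel-variance
  non-overlapping windows, in temporal order — a deterministic stand-in
  for the manual "clean epoch" selection of clinical practice. It
  guarantees reproducibility, not optimality.

## Synthetic data

The generator is the package's substitute for patient recordings, and
its defaults are the validation conditions used throughout the tests:
19 channels, 500 Hz, `K = 4`, 60 ms mean dwell, snr 4, five 10-s
epochs.

* **Templates** are potentials of randomly placed and oriented dipoles
  evaluated at the montage, average-referenced and normalized; draws
  repeat until all pairwise absolute correlations are below 0.8, so
  templates are distinguishable but realistically non-orthogonal.
* **State sequence**: an alternating-renewal process with geometric
  dwell (memoryless per sample; chosen for analytic tractability) and a
  distinct-state transition matrix (uniform off-diagonal by default).
  `stationary_occupancy()` gives the implied long-run coverage.
* **Amplitude envelope**: a rectified 10 Hz low-pass-filtered Gaussian
  process with mean 1, so GFP fluctuates and has genuine peaks. Its
  troughs are moments of near-zero signal, which is what drives the
  back-fit flicker discussed above.
* **Noise** is spatially smoothed channel noise (Gaussian kernel on
  unit-sphere chord distance, width 0.5) band-limited to 1-45 Hz:
  scalp background activity is spatially and temporally correlated, and
  white noise in either domain would make the recovery problem
  unrealistically easy or unrealistically hard. snr is the ratio of
  state-signal RMS to noise RMS over the record.
* **Actigraphy**: per-minute counts are log-normal (right-skewed,
  nonnegative; the field reports no distribution) with a lower activity
  level at night (06:00-22:00 day window by default; the day/night
  boundary is a configurable convention, not a measured quantity). The
  location parameter is calibrated by root-finding so the expected
  fraction of minutes above the 500 counts/min moderate threshold
  matches its target; the affected arm is a Gaussian-copula copy whose
  latent correlation is tuned on the realized sample so the empirical
  Pearson r matches `target_r`, then scaled so the count-sum ratio
  matches the ULAR target. Infeasible targets warn and clamp.

What the generator does **not** emulate: ocular/EMG artifacts, lesioned
hemisphere asymmetries, realistic EEG spectra (the synthetic spectrum
is the envelope's and the noise band's, a free choice), non-wear gaps
and sleep structure in actigraphy. Passing tests therefore demonstrate
correctness of the algorithms under the stated generative model, not
clinical validity on real recordings.

## Statistical layer

Group and subgroup comparisons follow the study design: outcomes are
adjusted for age and sex by OLS residualization (an explicit option of
interpreting "GLM with covariates"; testing the group coefficient
inside the linear model gives the same t when the group indicator is
orthogonalized), compared with a pooled two-sample t-test, described by
Cohen's d (pooled SD; reported for both adjusted and raw values, the
adjusted one primary), and corrected by Benjamini-Hochberg FDR within
one subgroup comparison's outcome family. The pooled (not Welch)
variant and the Yates-corrected 2x2 chi-square are the defaults because
they are the conventions that reproduce published demographic-table
statistics from summary data (`t_from_summary()`, `chi_square_2x2()`).
Correlations are Pearson on raw values or Spearman on mid-ranks, with
two-tailed p from the t-approximation at `n - 2` df.

`run_subgroup_analysis()` refuses splits leaving fewer than two
subjects per group; undefined quantities (zero variance, zero
marginals, no unaffected-arm activity) are reported as `NA` with a
warning, never as 0 or infinity.

## Validation summary

The test-suite conditions and problem sizes are the package's own
choices: template/parameter recovery uses ten independently seeded
50-s runs at snr 4 (about 25,000 transitions pooled); dwell and
transition laws of the sequence generator are checked at 1e5 samples;
BH-FDR control under the null uses 1e4 simulated families of 20;
the planted-effect power check uses 100 seeded cohorts of 17 + 17 with
the effect planted at an exact Cohen's d of 1.2 within a three-outcome
activity family. Published-table statistics (sex ratio chi-square, age
t-test) are recomputed from printed summaries and matched to three
decimals. `scripts/acceptance.R` re-runs all of this from scratch and
writes the measured numbers as JSON.

## Known limitations

* Durations from unsmoothed back-fitting are systematically short at
  realistic snr; use `min_duration_ms` consciously (see above).
* The canonical A-D templates are geometric idealizations; relabelling
  quality on real group maps should be checked via the reported
  `canonical_corr` values.
* The EDF writer/reader covers continuous 16-bit recordings with one
  sampling rate (what this pipeline needs), not the full EDF+ feature
  set.
* Transition probabilities are conditional on leaving a state; if
  per-second transition rates are wanted, combine the matrix with
  occurrence.
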