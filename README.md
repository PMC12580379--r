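# microdyn

EEG microstate temporal dynamics and bilateral wrist actigraphy for
stroke cohorts.

After a middle-cerebral-artery stroke, the balance of large-scale
resting-state brain networks shifts, and so does the use of the two
arms. Two cheap, bedside-compatible measurements capture both sides:
resting-state EEG summarized as **microstates** — brief (tens of ms)
periods of quasi-stable scalp topography, canonically labelled A–D —
and wrist **actigraphy** summarized as per-minute movement counts of
each arm. `microdyn` implements the full analysis chain that links
them to clinical status, for researchers who want to reproduce or
extend this kind of study:

* **Microstate core.** Global field power
  `GFP(t) = sqrt(Σᵢ (vᵢ(t) − v̄(t))² / n)`; GFP-peak topographies;
  polarity-invariant modified k-means (assignment by `|corr|²`,
  centroid update by the GFP²-weighted first principal component,
  model selection by global explained variance, GEV); group-map
  aggregation with permutation/polarity alignment; canonical A–D
  labelling; back-fitting; and the four temporal parameter families —
  coverage, mean duration, occurrence, and conditional transition
  probabilities between distinct states.
* **EEG preprocessing.** EDF and delimited I/O, zero-phase 50 Hz notch
  and 1–45 Hz Butterworth band-pass, robust (median/MAD z > 4)
  bad-channel detection with a more-than-two-bad exclusion rule,
  spherical-spline interpolation, average reference, and selection of
  five 10-s epochs.
* **Actigraphy metrics.** The upper-limb activity ratio
  `ULAR = Σ affected / Σ unaffected × 100%`, the bimanual coordination
  index *r* (per-minute Pearson correlation), and minutes above the
  500 counts/min moderate-activity threshold, each overall and split
  into day/night windows.
* **Statistics.** Age/sex covariate adjustment by OLS residualization,
  pooled and Welch two-sample t (from raw data or published
  mean ± SD summaries), Yates-corrected 2×2 chi-square, Cohen's d,
  Pearson/Spearman correlations, Benjamini–Hochberg FDR, and a
  subgroup-analysis driver.
* **Synthetic data.** A generator of EEG with planted microstate
  structure (semi-Markov state sequence, dipolar template maps,
  spatially and temporally correlated noise at controlled SNR) and of
  paired activity-count series with controlled inter-arm correlation,
  count ratio, and moderate-activity fraction — so the entire pipeline
  is testable against ground truth without any patient data.

The repository is organised as an analysis workflow: the package in
`R/` holds every computation; the numbered scripts in `analysis/`
(simulate → preprocess → microstates → actigraphy → group statistics)
run them over a synthetic cohort and write tables under `results/`
(bulky intermediate data goes to `scratch/`).

## Worked example

Generate a synthetic recording with known microstate structure, fit
the model, and read off the temporal parameters:

```r
library(microdyn)

tpl    <- generate_templates(n_channels = 19, k = 4, seed = 1)
spec   <- state_sequence_spec(uniform_transitions(4), mean_dwell_ms = 60,
                              sampling_rate_hz = 500,
                              total_duration_s = 50, seed = 1)
truth  <- simulate_state_sequence(spec)
eeg    <- synthesize_eeg(tpl, truth, sampling_rate_hz = 500,
                         snr = 4, seed = 2)
epochs <- epochs_from_matrix(eeg$data, 500, n = 5, length_s = 10)

fit <- microstate_pipeline(epochs, k = 4, seed = 3)
fit$model
#> <microstate_model> k = 4, GEV = 0.961, labels: A B C D
parameters_to_df(fit$parameters)
#>   state coverage duration_ms occurrence_per_s
#> 1     A    0.258        19.6             13.2
#> 2     B    0.284        20.9             13.6
#> 3     C    0.227        17.2             13.2
#> 4     D    0.231        21.2             10.9
```

The fitted maps explain 96% of the GFP²-weighted topographic variance
and recover all four planted templates (their absolute correlations to
the generating maps are ≥ 0.99; `fit$model$canonical_corr` shows the
match to the canonical A–D shapes). Coverage is near the generative
stationary occupancy of 0.25 per state. Note the short mean durations:
per-sample back-fitting flickers at amplitude troughs, biasing
durations downward — `backfit(..., min_duration_ms = 15)` merges
sub-threshold segments if durations are the quantity of interest (see
the methods vignette).

Actigraphy with controlled targets, recovered by the metrics module:

```r
pair <- synthesize_actigraphy(actigraphy_spec(n_minutes = 1440,
                                              target_r = 0.62,
                                              target_ular_pct = 30,
                                              seed = 7))
activity_metrics(pair)
#>   ular_all ular_day ular_night r_all r_day r_night ...
#> 1       30       30         30  0.62 0.553   0.536 ...
```

Published demographic comparisons can be reproduced from printed
summaries alone:

```r
t_from_summary(62.44, 9.76, 34, 59.58, 9.15, 50, variable = "age")
#>   variable t_statistic df p_value cohens_d n1 n2
#> 1      age       1.369 82  0.1748   0.3042 34 50
chi_square_2x2(21, 13, 25, 25)   # sex ratio, Yates-corrected
#> chi-square = 0.706, p = 0.401
```

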