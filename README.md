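# stmdrift

Analysis of delay-period drift in trial-structured two-photon calcium
imaging.

## The problem

In a delayed match-to-sample task, an animal sees a moving grating (left or
right), holds the direction in short-term memory across a delay, and reports
it by licking the matching port. Imaging association cortex during the task
yields a ΔF/F matrix (frames × neurons) plus a trial table, and raises the
question this package is built to answer: **do memory errors come from
mis-encoding the stimulus during the sample phase, or from a drift of the
population representation toward the opposite stimulus during the delay?**

`stmdrift` implements the full analysis chain for that question, aimed at
researchers analyzing trial-aligned calcium sessions:

- **Synthetic sessions** (`generate_session`, `generate_movie`) — balanced
  left/right trials at 30 Hz (sample frames 1–120, delay 121–170, reward
  171–200), phase- and direction-selective neurons with sequential peak
  times, configurable error rate, noise, and a planted delay-period drift
  toward the opposite representation on error trials. Ground truth is
  recorded, so every downstream stage is testable.
- **Event-related neuron detection** (`fit_betas`, `test_event_relevance`,
  `detect_rois`, `classify_neurons`) — per-pixel/per-trace regression
  against calcium-kernel templates anchored at task events, one-sample
  t-gating of the per-event amplitudes `t = β̄/(s/√k)`, Moore-neighbor
  (8-connected) clustering of significant pixels into ROIs, and GLM-based
  phase/direction labels.
- **Selectivity indices** (`preference_index`, `reliability_index`,
  `phase_selectivity_index`, `permutation_validation`) — ROC indices
  `2·(auROC − 0.5)` in [−1, +1] on trial means, single-trial frames, and
  phase contrasts, with a 1,000-shuffle permutation Z-score.
- **Trajectory analysis** (`fit_trajectory_space`, `trajectory_distances`,
  `tsi`) — split-trial PCA (fit on 50% of correct trials, top 5
  components), per-frame Euclidean distances d0/d1/same-stimulation/
  same-response, and the trajectory similarity index
  `TSI = (dOO − dPP)/(dOO + dPP)`.
- **Coding directions** (`compute_mode`, `orthogonalize`, `project_trials`,
  `residual_separation`, `rt_cd_correlation`) — unit-norm activity modes
  for sample/delay/reward windows plus a nonselective ramping mode,
  Gram-Schmidt orthogonalization, normalized condition projections, and the
  error/correct separation ratio.
- **Population decoding** (`fit_lda`, `snr_timecourse`, `svm_decode`,
  `population_correlation`) — sliding-window LDA signal-to-noise ratios,
  linear SVM decoding with 70/30 correct-trial splits, and native-space
  Pearson correlations in 25-frame bins.
- **Pipeline** (`run_pipeline`, `validate_config`) — all stages end-to-end
  with seeded, byte-reproducible CSV/JSON outputs and a checksum manifest.

## Worked example

```r
library(stmdrift)

session <- generate_session(n_neurons = 60, n_trials = 60,
                            drift_rate = 0.5, noise_sd = 0.2, seed = 7)
session
#> stm_session: 60 neurons, 60 trials (42 correct, 18 error), 15600 frames

# GLM classification recovers the planted population structure
labels <- classify_neurons(session)
table(labels$primary_phase, labels$primary_direction)
#>          left none right
#>   delay     8    0     7
#>   none      0   22     0
#>   reward    4    0     6
#>   sample    6    0     7

# Trajectory similarity of error trials: near the correct representation
# during the sample phase, near the opposite one by the end of the delay
tr <- trajectory_distances(session, n_iter = 30, seed = 2)
mean(tr$mean$tsi[1:120])    # sample phase
#> 0.697
mean(tr$mean$tsi[161:170])  # last 10 delay frames
#> -0.463

# Coding-direction separation on error trials survives in the sample
# window but collapses in the delay window
cd <- coding_direction_analysis(session)
cd$residual_separation
#> $CD_sample 1.006   $CD_delay 0.178

# SVM trained on correct trials: error trials decode as their stimulus in
# the sample phase, but as the *opposite* direction by late delay
svm_decode(session, window_starts = c(60, 160), seed = 4)
#>   window_start acc_correct acc_err_stim acc_err_resp acc_shuffled
#> 1           60           1            1            0        0.492
#> 2          160           1            0            1        0.300
```

Read together: error trials start out encoding the presented stimulus
(TSI > 0, residual separation ≈ 1, same-stimulus decoding at 1.0) and end
the delay encoding the opposite direction (TSI < 0, residual separation
≪ 1, same-stimulus decoding below chance) — the drift signature the
package is designed to quantify. With `drift_rate = 0` none of these
reversals occur.

## Layout

```
R/                    implementation (generator, detection, selectivity,
                      trajectory, coding direction, decoding, pipeline, I/O)
tests/testthat/       unit, property and acceptance tests with independent
                      brute-force oracles
vignettes/            methods vignette: models, assumptions, parameter
                      defaults, numerical choices, limitations
scripts/acceptance.R  reference-quantity script (see above)
```
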