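---
title: "Quantifying delay-period drift in trial-structured calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying delay-period drift in trial-structured calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmdrift)
```

## The scientific problem

In a delayed match-to-sample task an animal sees a moving grating (left or
right), holds that direction in short-term memory across a delay, and then
reports it by licking a left or right port. Two-photon calcium imaging of
association cortex during such a task yields, per session, a ΔF/F matrix
(frames × neurons) and a trial table. The central question this package
serves is *where errors come from*: is the stimulus mis-encoded during the
sample phase, or does an initially correct representation drift toward the
opposite one during the delay? `stmdrift` implements the full chain of
analyses needed to ask that question — event-related neuron detection,
ROC-based selectivity indices, state-space trajectory distances, coding
direction projections, and population decoding — together with a synthetic
session generator that plants known ground truth, so that every stage is
testable without any recorded data.

## Trial layout and the calcium kernel

All analyses are defined on a fixed 30 Hz frame grid: sample phase frames
1–120 (4 s), delay frames 121–170, reward frames 171–200, followed by a
configurable inter-trial interval (default 60 frames) that lets calcium
transients decay between trials. The delay window is fixed in frames even
though behavioral delays vary between 1.5 and 2 s; the frame windows are the
primitive all downstream analyses reference, so sessions with longer delays
are analyzed over the same frames (the generator still records the nominal
delay duration per trial).

The indicator impulse response is a double exponential
$c(t) = e^{-t/\tau_d} - e^{-t/\tau_r}$, with $\tau_d$ = 1.0 s for cytosolic
indicators and 3.0 s for nuclear ones. Only the decay constant is pinned
down by the indicator; the rise constant defaults to $\tau_r$ = 0.1 s, a
typical fast-indicator onset, and is configurable. `calcium_kernel()` can
return the raw or the unit-peak-normalized kernel; all regression templates
use the normalized form so that a fitted amplitude of 1 corresponds to a
unit-peak transient.

## The synthetic session generator

`generate_session()` is a first-class module, not a test fixture. It
emulates the structure of a real session:

* **Design.** Pseudo-random balanced left/right stimuli (counts differ by at
  most one), a configurable error rate (default 0.3, matching a ~70%
  behavioral plateau), per-trial delay durations drawn from {1.5, 2} s, and
  small independent reaction-time jitter.
* **Population.** A fraction of neurons is selective for one phase and one
  direction (defaults: 25% sample, 20% delay, 15% reward, split evenly
  between directions; the remainder carries no event-locked signal). These
  proportions reflect a population in which roughly 60% of neurons are
  task-selective with sample selectivity more common than delay, and delay
  more common than reward. Each selective neuron emits one unit-amplitude
  kernel event per preferred-direction trial; peak times tile the early-to-
  middle portion of the phase (5%–60%), producing the characteristic
  sequential activation without extra parameters. Reward neurons respond
  only on rewarded (correct) trials.
* **Noise.** I.i.d. Gaussian ΔF/F noise, default sd 0.2 against unit-peak
  events (single-event SNR 5).
* **Drift.** On error trials the activity of delay-selective neurons is a
  convex combination of the response to the presented stimulus and the
  response to the opposite stimulus, with mixing weight
  $w(t) = \min(1,\ \text{drift\_rate} \times s)$ where $s$ is seconds since
  delay onset. The slope is expressed per second of delay, so at the default
  drift_rate = 0.5 the weight reaches ≈ 0.83 by the delay end — the
  representation crosses the midpoint and ends nearer the opposite pattern,
  which is the qualitative signature the analyses are designed to detect. A
  saturating parameterization (weight capped at drift_rate) would leave the
  two representations exactly ambiguous at 0.5 and no decoder could fall
  below chance, so the per-second slope is the reading used throughout.

What the generator deliberately does **not** emulate: licking kinematics,
arousal fluctuations, motion artifacts, baseline (F₀) dynamics, correlated
noise, or graded single-trial response amplitudes. Passing tests therefore
certify the *analysis chain* — that each statistic recovers what was
planted under clean, known conditions — not that real data will be as
well behaved.

## Event-related neuron detection

Detection follows the template-regression scheme: the expected event-related
trace is an amplitude-weighted spike train at the task event onsets
convolved with the kernel. For each of six task events (right/left ×
sample/delay/reward, defined on correct trials), one unit-peak kernel copy
is anchored at the phase onset of every matching trial; all columns enter a
single joint least-squares fit so that overlapping transients are
disentangled by multiple regression. A trace (or pixel) is event-related
when the one-sample t statistic of its per-event amplitudes,
$t = \bar\beta / (s/\sqrt{k})$ with $k-1$ degrees of freedom, is significant
— one-tailed by default, because calcium transients are positive-going
(a two-tailed variant sits behind a flag). The pixel-level default is
$\alpha = 0.05$ and the neuron-level default $\alpha = 0.01$; no multiple-
testing correction is applied across pixels, matching the method as
specified, though `p.adjust`-style correction can be applied downstream by
the caller.

Three numerical decisions matter here:

* **Zero-variance amplitudes.** If all fitted amplitudes are equal, the t
  statistic is degenerate. The contract is: $s = 0$ with $\bar\beta > 0$ is
  maximally significant ($p = 0$); $s = 0$ with $\bar\beta = 0$ carries no
  evidence ($p = 1$).
* **Floating-point residue.** When a trace is fitted *exactly* (zero
  residual), the off-event amplitudes are ~1e-18 noise and a t test on such
  dust is arbitrary. Amplitudes below 1e-8 of the trace's largest fitted
  amplitude are snapped to zero before testing. Without this guard, exact
  recovery in the noiseless limit is unattainable for any finite-precision
  implementation.
* **Baseline offsets.** The template regression has no intercept, matching
  the plain least-squares form and keeping the null calibration of the t
  test exact for zero-baseline ΔF/F traces (the type-I error on pure-noise
  pixels is 0.05 at the 0.05 threshold, verified on 10,000 simulated
  pixels). An optional baseline-offset column (`intercept = TRUE`) exists
  because a template placed at *random* times still overlaps a
  positive-going signal on average; absorbing that DC component is what
  makes a label-shuffled null land at the nominal α.

Significant pixels are clustered into ROIs under the Moore (8-connected)
neighborhood. Components smaller than `min_roi_size = 3` pixels are
discarded as speckle: with expected somata of 3×3–4×4 pixels, no real ROI is
smaller, while uncorrected per-pixel testing at α = 0.05 necessarily leaves
~5% isolated background rejections, of which almost none survive the size
filter.

### Known limitation: secondary phase labels

A neuron whose transient peaks mid-phase has a kernel tail that genuinely
loads on the next phase's regressor (the anchored template cannot absorb
response latency). With realistic noise this appears as a *secondary* phase
label on a minority of neurons — which is also a real biological category
(conjunctive sample+delay neurons). In the strict zero-noise limit any
nonzero positive loading is infinitely significant, so exact single-phase
recovery is only guaranteed when planted events coincide with the template
anchors (`generate_session(sequence = FALSE)`), and that is the regime in
which the exact-recovery tests run. `classify_neurons()` reports both the
full label set and `primary_phase`/`primary_direction` (the strongest
regressor), and downstream stages consume the primary labels.

A separate exclusion pass (`exclude_drifting_neurons()`) removes directional
neurons whose mean activity in their selective phase is *strictly* higher
for the nonpreferred stimulus on correct trials — the signature of a slow
baseline drift masquerading as tuning. Equality retains the neuron.

## Selectivity indices

All three indices are ROC constructions, `index = 2 × (auROC − 0.5)`,
bounded in [−1, +1], computed by the rank (Mann–Whitney) formula with 0.5
credit per tie — which equals exhaustive pairwise counting, as the test
suite verifies against a brute-force oracle. The positive class is the
rightward direction by convention, so +1 means perfect right preference.
Because the index depends only on ranks, it is invariant under any strictly
increasing transform of the inputs, and antisymmetric under swapping the
classes.

* **PI** uses per-trial *mean* ΔF/F in the phase of interest.
* **RI** uses pooled single-trial per-frame values, normalized to the
  neuron's maximum ΔF/F across the whole trial, measuring trial-to-trial
  consistency rather than average separation.
* **PSI** compares trial-averaged activity in the neuron's phase against
  the pooled values of the two other phases (pooled, not pairwise, because
  the nonpreferred phases form a single comparison class).

Permutation validation builds the null by pooling all trial-by-phase mean
values and reassigning them randomly to phase slots 1,000 times. The
observed session-mean selectivity index (preferred-phase mean minus mean of
the other phases) is expressed as a Z-score against the null means; the
neuron is significant when it exceeds the null's 95th percentile, and the
per-trial pass fraction counts trials whose individual index clears that
same one-tailed threshold. For directional neurons the validation runs on
preferred-direction trials, since a direction×phase-selective neuron is
silent on opposite-direction trials by construction. The threshold is taken
from the null of *session means* (not pooled trial-level nulls): for a
strongly selective neuron one third of trial-level null values reproduce
the observed arrangement, which would cap the pass fraction near 33% no
matter how reliable the neuron — inconsistent with the intended reading
that a perfectly reliable neuron passes on every trial.

## Trajectory space, distances, and the similarity index

Direction-selective neurons are aligned to a common preferred axis (left-
preferring neurons have their trial labels flipped), so "PP" denotes
preferred stimulus + preferred (correct) response, "OO" the opposite-correct
condition, and "PO" an error trial: preferred stimulus, opposite response.

On each of `n_iter = 100` iterations, a random half of the correct trials
(drawn within each direction — the same 50% convention as the original
split-trial analysis) provides the per-neuron PP trial averages; each
neuron's column is Z-scored (σ floored at 1e-12 for flat neurons, which are
flagged), the neuron×neuron covariance is eigendecomposed, and the top 5
loadings define the trajectory space. The held-out correct trials and all
error trials are then projected with the *stored* means and SDs — error
trials never touch the fit, which is asserted by construction and by test.
Per frame the analysis records d0 (fitting-half vs held-out-half PP
distance: the trial-by-trial variability floor), d1 (PP–OO), the
same-stimulation distance (PP–PO), and the same-response distance (OO–PO),
each a Euclidean distance in the 5-D space, retained per iteration.

The trajectory similarity index
$\mathrm{TSI} = (d_{OO} - d_{PP})/(d_{OO} + d_{PP})$ is bounded in [−1, +1]
whenever the distances are not both zero (in which case it is undefined and
returned as missing); +1 is attained exactly when $d_{PP} = 0$. For PO
trials the TSI is positive while the population sits near the correct
representation of the presented stimulus and turns negative as drift pulls
it toward the opposite one; with the generator's defaults the sign flips
midway through the delay, reproducing the qualitative error-trial
signature. A per-frame ROC comparison of two distance distributions across
iterations (`distance_roc()`) quantifies when two distance series separate.

## Coding directions

A coding direction is the unit vector along the per-neuron difference of
window-averaged, trial-averaged activity between correct-right and
correct-left trials: sample window frames 66–115, delay 121–170, reward
171–200. The nonselective ramping mode contrasts the last delay second
(141–170) with the reward second (171–200), pooling both directions. The l2
normalization makes projections independent of how many neurons were
recorded; neurons absent in a trial can be zeroed out before normalization.
Gram–Schmidt orthogonalization runs in the two declared orders (reward
mode, ramping mode, then sample; and reward mode, ramping mode, then delay)
so that the sample/delay projections are free of reward-locked and ramping
components. Projections are normalized by the mean correct-right projection
inside the mode's window (that mean is 1 by construction); residual
separation is then
$(\bar P^{err}_R - \bar P^{err}_L)/(\bar P^{cor}_R - \bar P^{cor}_L)$
of window means — the parenthesization that reads as "how much of the
correct-trial separation survives on error trials". Under planted delay
drift it falls well below 1 in the delay window while remaining ≈ 1 in the
sample window.

The reaction-time check projects every trial onto the delay coding
direction averaged over the last delay second, measures the absolute
distance to the decision boundary (the midpoint of the mean correct-right
and correct-left projections — no refit classifier), and correlates it with
the trial's deviation from the session median RT. The generator draws RT
jitter independently of the drift, so the expected correlation is ≈ 0.

## Population decoding

**LDA-SNR.** Within each 50-frame sliding window the discriminant is fit on
correct right vs correct left population vectors (scatter matrices with
class means taken within the window; a ridge of 1e-6·trace/dim is added
only if the within-class scatter is singular, with a warning). The SNR
numerator is the window-mean absolute separation of the projected per-frame
group means of the compared pair (same-stimulation: RR vs RL and LL vs LR;
same-response: RR vs LR and LL vs RL; averaged over the two pairings); the
denominator — the printed formula being typographically garbled — is the
root mean squared projected within-group deviation over *all* task frames,
with time-resolved group means so that temporal signal structure does not
count as noise. The ratio is invariant under any common invertible linear
map of the population (verified by test). Normalized series divide by the
session maximum, which therefore equals exactly 1. The discriminant is
refit per window by default (a fit-once option is a trivial caller-side
variant: fix `window_starts` to one window and project the rest).

**SVM.** A linear-kernel, C = 1 support vector machine is trained per
8-frame window on a random 70% of correct trials (features: per-neuron
window means; labels: stimulus direction) and evaluated on held-out correct
trials, on error trials labeled by stimulus, by response, and on a
label-shuffled control, averaged over 10 random splits. Under planted drift
the same-stimulus accuracy falls below chance in late delay windows — the
decoder reads out the opposite direction — while without drift it stays
high; the shuffled control sits at 0.5 within binomial error.

**Native-space correlations.** Pearson correlations between trial-averaged
population vectors (neuron × frames-in-bin, flattened) in six consecutive
25-frame bins starting at frame 21, or in a sliding 15-frame window. The
within-correct baseline uses repeated random 50/50 splits of the correct
trials; the correct-vs-error series compares the correct mean with the
same-stimulus error mean. Under drift the correct-vs-error correlation
declines across the two delay bins while the within-correct baseline stays
high.

## Pipeline and reproducibility

`run_pipeline()` chains generation (or a supplied session) → classification
with drift exclusion → selectivity metrics → trajectory distances → coding
directions → decoding, writing every stage's output as CSV/JSON plus a
manifest with the configuration hash and per-file checksums. Every
stochastic stage derives its own seed from the top-level seed, so two runs
of one configuration are byte-identical — tested by comparing manifests.
`validate_config()` names each violation (missing seed, out-of-range rates,
overlapping phase windows) rather than failing opaquely.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to keep every statistical
margin wide: type-I calibration on 10,000 noise pixels × 20 events; null
preference indices over 1,000 neurons at 30 trials/side; 10⁶ random
distance pairs for the TSI bound; drift-signature sessions of 60 neurons ×
60 trials with 30 trajectory iterations, SNR probed in two 25-frame delay
windows and the SVM in two late-delay windows; ROI recovery on a 32×32
movie with eight planted 3×3 footprints at single-event SNR 10. Exhaustive
oracles (pairwise auROC counting, 1°-grid discriminant search, brute-force
coordinate subsets for the top-5 eigen variance) cross-check each fast
implementation on inputs small enough to enumerate.

## Known limitations

* The generator's noise is white; real two-photon noise is temporally and
  spatially correlated, and shared across neurons. Type-I calibration under
  correlated noise is not guaranteed by these tests.
* The anchored-template GLM cannot represent response latency, so secondary
  phase labels appear for mid-phase responders (see above).
* Sessions are analyzed one at a time; cross-session pooling (concatenating
  neurons after per-session trial-averaging) is left to the caller, as is
  any between-session hypothesis testing.
* The delay analysis window is fixed in frames; trials with a 2 s
  behavioral delay are windowed identically to 1.5 s trials.
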