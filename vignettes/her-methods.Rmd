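---
title: "Heartbeat-evoked response analysis: models, conventions and design choices"
author: "herpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heartbeat-evoked response analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herpipe)
```

## The problem

A heartbeat-evoked response (HER) is a transient neural signal change
time-locked to a cardiac event. `herpipe` implements a complete sensor-level
HER pipeline for paradigms that contrast two within-subject conditions
(labelled *Self* and *Other* throughout): ECG R- and T-peak detection,
heartbeat eligibility rules, T-peak-locked epoch averaging, a
spatio-temporal cluster-based permutation test of the condition contrast,
and the two controls that make such a contrast interpretable — a
surrogate-heartbeat test (is the effect really *locked* to heartbeats?) and
rating stratification (does the effect survive equating a behavioral
confound such as arousal?). Trial-level GLMs and Bayes factors complete the
inferential toolkit.

Because the kind of raw data this pipeline targets is rarely public, the
package ships a synthetic-session generator with planted ground truth. It
is first-class, tested code: every downstream stage is validated against
what the generator actually planted.

## The synthetic session generator

`simulateSession()` produces one subject's session:

* **Cardiac renewal process.** R-peak times form a renewal process with
  truncated-positive Gaussian interbeat intervals, mean 854 ms and SD 50 ms
  by default. Each beat contributes P/Q/R/S/T Gaussian bumps to the ECG;
  the T apex lags the R-peak by 280 ms. The renewal process runs
  continuously across the session — heartbeats are *not* phase-locked to
  trial onsets, matching physiology.
* **Trial structure.** 36 trials per condition by default: fixation
  (1–1.3 s), instruction (2.3 s), imagination (uniform 6.7–7.3 s; the
  variable duration is part of the study conditions and interacts with the
  eligibility rules), response period, inter-trial interval (4.5–5.4 s).
* **Ratings.** Perspective, valence and arousal are discretized truncated
  Gaussians. Arousal means are 3.4 (Self) vs 3.0 (Other) on the 1–5 scale
  with SD 1.0. Only means are constrained by the emulated study design;
  variances are calibration choices made once.
* **Sensors.** Channels sit on a spherical-cap Fibonacci lattice with a 2D
  azimuthal projection used for adjacency — a nontrivial neighbor graph
  without real sensor geometry. Sensor data are white Gaussian noise plus a
  cardiac-field artifact (the clean ECG waveform mixed in with a smooth,
  signed left–right topography) plus the planted HER effect: a half-sine
  bump at the effect sensors in a latency window after *every* T-peak
  inside each trial's imagination period, with per-condition amplitude
  (defaults: Self −1.5, Other −0.5; window 307–326 ms; 8 posterior
  sensors).
* **Slow drift (optional).** `driftAmplitude` adds a condition-dependent
  *constant* offset spanning the whole imagination period (raised-cosine
  ramps outside it). This emulates a slow condition difference that is not
  heartbeat-locked, the exact alternative hypothesis the surrogate control
  must reject. An earlier design used a half-sine ramp over the trial; that
  shape interacts with the surrogate's eligibility-window truncation, so
  identity and permuted timing assignments sample systematically different
  ramp coverage — a simulation artifact rather than the phenomenon under
  test — and was replaced by the plateau.

What the generator does **not** emulate: realistic head geometry or forward
fields, gradiometer physics, respiratory or movement artifacts, 1/f sensor
noise, or rating distributions beyond their first moment. Passing tests
therefore demonstrate the *rules and statistics* of the pipeline, not its
robustness to every property of real recordings.

## Cardiac event detection

Detection is by sliding normalized (Pearson) correlation with a template —
amplitude-invariant by construction. One R-peak is placed at the local
signal maximum of each maximal contiguous episode of correlation above 0.7.
Templates are built per recording in two passes: a generic synthetic QRS
finds the first 20 confident beats, whose median waveform becomes the
subject template. The template spans ±200 ms so that it includes the P-wave
context; a narrow QRS-only template matches smooth P/T deflections
spuriously under amplitude-invariant correlation.

T-peaks are detected the same way inside `(R, R + 0.4 s]`; beats without a
qualifying episode are flagged `no_t_found`. The T correlation threshold is
per-recording tunable (default 0.6) because T-wave morphology varies across
subjects; there is no principled universal value.

Beats are excluded when they fall in user-supplied noisy intervals or flank
an abnormal interbeat interval — one deviating from the running median
(9-beat window) by more than 30%. The 30% extrasystole criterion is the
package's own convention, exposed as configuration.

`cardiacSummary()` computes the mean successive T-to-T distance (IBI) and
its sample (n−1) standard deviation (HRV) in a window; both are invariant
to uniform time translation.

## Artifact-component selection

The source separation itself (ICA or any decomposition satisfying the
components × time + mixing-matrix contract) is a pluggable input; the
package owns only the selection rules:

* **Cardiac:** mean pairwise phase consistency (PPC) between each component
  and the ECG over 0–25 Hz, estimated from single Hann-tapered transforms
  of −0.2…0.2 s R-locked epochs, averaged across frequency bins (whether to
  average bins or compute a broadband phase is an open choice; bin
  averaging is the default and the band is configurable). Components whose
  PPC exceeds the mean + 2 SD of the *current* set are removed iteratively,
  at most two.
* **Blink:** absolute Pearson correlation with the vertical EOG, 3 SD rule,
  at most three.

A caveat inherent to mean + k·SD rules: with very few components a single
strong outlier inflates the pooled SD enough to mask itself. The rules are
meant for decompositions of realistic rank (tens of components).

## Heartbeat eligibility and epoching

Eligible heartbeats per trial are valid T-peaks inside
`[imagination onset + 2 s, offset − 0.4 s]`, excluding T-peaks whose next
R-peak follows within 0.4 s — this guarantees that the 80–350 ms analysis
window never overlaps the next R-peak artifact. Trials missing any of the
three ratings contribute nothing. Under the default timing parameters these
rules retain ≈ 5.4 heartbeats per trial and ≈ 192 per 36-trial condition,
numbers the acceptance script recomputes from scratch.

Epochs span −100…+400 ms around the T-peak after a 30 Hz 4th-order
zero-phase low-pass. All filters in the package are zero-phase
(forward–backward Butterworth with reflection padding): a causal filter
would shift latencies in the narrow windows this analysis reads. No
baseline correction is applied by default — baselining heartbeat-locked
data is contentious because every candidate baseline is itself
heartbeat-locked; it exists as an option.

Visual artifact screening is replaced by an automatic rule: an epoch is
dropped when its peak-to-peak amplitude on any channel exceeds 3× that
channel's *median epoch peak-to-peak*. An absolute rule tied to the
channel's overall SD was rejected: for band-limited data it miscalibrates
badly (rejecting about half of clean epochs) and, worse, rejects
differentially by condition whenever a condition carries a larger planted
(or real) response. The adaptive median rule tracks the background level
and is condition-blind in the null case.

Condition labels live on trials and epochs inherit them; nothing downstream
may relabel an epoch except the permutation engines.

## The cluster permutation test

`clusterPermutationTest()` implements the paired two-condition
spatio-temporal cluster test on arbitrary sensor graphs:

1. Per-sample paired *t* map (zero-variance samples get t = 0 with a
   warning).
2. First-level threshold |t| > t_crit(df, 0.05 two-tailed), samples split
   by sign.
3. Optional pruning: a sample is retained only if at least `minNeighbors`
   (default 4) of its spatial neighbors are suprathreshold with the same
   sign at the same time bin. This is the *retained-sample* reading of the
   minimum-neighbor convention; the rule is applied before clustering, and
   identically in observed and permuted data. For sparse generic graphs
   (e.g. cortical meshes: first-level p 0.01, 1 neighboring vertex) set
   `minNeighbors = 0` and the appropriate `thresholdP`.
4. Connected components under spatial adjacency (same bin) ∪ temporal
   adjacency (same channel, consecutive bins), same sign only; cluster
   statistic = sum of t values. Ties between equal sums are broken by
   first-seen order under the fixed channel-fastest scan.
5. Label permutation: each of `nPermutations` (default 10 000) draws flips
   a random subset of subjects; the maximal positive and minimal negative
   cluster sums are recorded (0 when a tail is empty). Permutations are
   sampled with replacement — the 2^n sign-flip space is far larger than
   any feasible enumeration for realistic n, and for small n the
   granularity of achievable p values (1/2^n) is the binding constraint
   regardless.

**p-value conventions.** Each cluster's Monte-Carlo p is the plain
proportion of permutation extremes at least as extreme as its sum — no +1
correction (the `(k+1)/(N+1)` variant exists as an option). A statistic
more extreme than 4 of 1000 permutation extremes therefore reports
p = 0.004 exactly. The per-tail p values are reported raw, but the
`significant` flag tests each tail at α/2 (default α = 0.05): two
sign-specific tails each tested at the full α would double the family-wise
error to ≈ 0.10. The package's type-I simulation (200 null datasets, 12
subjects, 30 channels × 50 bins, 500 permutations — sizes chosen to make
the study precise yet runnable as an ordinary test) verifies that the
flag's family-wise error sits inside the exact binomial 95% interval
around 5%. Those simulation studies run with `minNeighbors = 0`; the
pruning path is verified separately against a brute-force graph oracle.

Effect sizes: per cluster, Cohen's d is the mean over member samples of the
per-sample paired d.

A note on small samples: with n subjects the permutation space has 2^n sign
patterns, so the smallest achievable per-tail p is about 2^−n; at least 6
subjects are needed before the α/2 = 0.025 criterion is reachable at all.

## The surrogate-heartbeat control

`surrogateHeartbeatTest()` asks whether a condition difference is genuinely
an evoked response to heartbeats. Within each subject, the per-trial *sets*
of heartbeat timings (taken relative to imagination onset; beat validity
and the next-R rule travel with the set, as they are properties of the
original heartbeat sequence) are randomly reassigned across trials —
full random permutations, fixed points allowed, identity excluded, and
unconstrained across conditions (the within-condition variant is an
option). Reassigned timings falling outside the recipient trial's eligible
window are dropped by the ordinary selection rules; with variable trial
durations this loses a small fraction of epochs. Eligibility, artifact
screening (pooled across conditions, exactly as in the standard path — the
identity assignment reproduces the observed statistic to machine
precision), averaging and the cluster statistic are then recomputed, and
the minimal negative cluster sum recorded per surrogate. `p` is the
fraction of surrogate minima at or below the observed minimum; `pAbs`
compares absolute extremes for two-sided use.

The control is informative in the regime it was designed for: effects of
realistic size relative to sensor noise. If the planted (or real) condition
difference is many times the noise level, the group t statistic saturates
and the surrogate comparison degenerates into a contest of tiny variance
fluctuations, where the identity assignment's slight epoch-count advantage
dominates. The package's specificity simulations therefore plant per-sample
differences on the order of the per-sample noise SD (locked arm: Self −0.9
vs Other −0.5; drift arm: constant −0.15 offset), mirroring the effect
sizes this kind of experiment actually produces.

## Stratification

`stratify()` equates a rating between conditions by iterative removal: pick
a condition at random; if its mean is larger, drop one trial holding its
maximum rating (random tie-break), otherwise one holding its minimum; stop
when the difference falls below 2%. The 2% is interpreted as *relative* to
the mean of the two condition means — the natural dimensionless reading; an
absolute mode exists. The absolute mean difference is not guaranteed to
shrink at every step (the condition is drawn at random); termination is
guaranteed by a cap of 10× the total trial count, and a condition exhausted
before convergence yields `converged = FALSE`. The same routine serves
emotion intensity, defined as the absolute value of the valence rating.

## GLMs, group tests and Bayes factors

Per subject, `fitHERGlm()` predicts the per-trial HER cluster amplitude
from 8 regressors: the condition (coded +1 Self / −1 Other), the three
ratings, the condition × rating interactions, and the trial number.
Response, ratings and trial number are z-scored within subject; the
interactions are the ±1 code times the z-scored rating, not re-z-scored (a
product of two standardized variables is not itself standardized, and
re-scaling it would destroy the interpretability of the main effects).
`fitHeartbeatCountGlm()` uses 4 regressors for the z-scored per-trial
heartbeat count. Ordinary least squares throughout; rank-deficient designs
fail naming the collinear columns. Betas are tested against zero over
subjects with one-sample t tests; per-subject correlations are tested after
Fisher-z transformation.

Bayes factors use the BF > 1 = evidence for the null orientation:

* `bfBICPaired()` compares the zero-mean and free-mean Gaussian models of
  the per-subject differences by BIC:
  BF01 = exp((BIC_effect − BIC_null)/2) = √n·((n−1)/(n−1+t²))^(n/2).
  This is the unit-information-prior reading; a reference construction
  that scales a Gaussian effect prior to the p = 0.05 criterion cannot be
  pinned down to a unique formula, so the package implements the standard
  BIC form and verifies direction, strict monotonicity in |t| and the
  evidence labels rather than claiming numeric equality with any
  particular published BF value.
* `bfJZS()` computes default-prior (Jeffreys–Zellner–Siow) Bayes factors by
  numerical integration: the Cauchy-scale mixture form for one- and
  two-sample t tests (prior scale √2/2) and the Zellner–Siow integral for
  correlations.
* `bfLabel()` maps max(BF, 1/BF) to the Jeffreys categories (<3 anecdotal,
  3–10 substantial, 10–30 strong, 30–100 very strong, >100 decisive) with
  the direction H0/H1 given by the side of 1.

## Pupil preprocessing

Blink intervals are extended by 80 ms on both sides; noise intervals are
any 300 ms window whose signal range — read as max − min — exceeds 1
arbitrary unit; the union is linearly interpolated; a 10 Hz 4th-order
zero-phase low-pass follows; epochs cover 2–4 s after imagination onset;
epochs with more than 30% interpolated samples are dropped and survivors
are z-scored. Subjects whose retained-epoch count falls below the group
mean − 1.5 SD are flagged.

## Pipeline orchestration

`runPipeline()` chains the stages over simulated subjects under one nested
configuration (`pipelineConfig()`, JSON-loadable, unknown keys rejected).
All analysis constants — the 0.7 and 0.6 correlation thresholds, the 0.4 s
rules, the 2 s onset offset, the 80–350 ms window, the 30 Hz low-pass, the
permutation count, the 2% tolerance, the ±1 coding, the 2/3 component caps
— are configuration defaults, never hard-coded. The run manifest records a
configuration hash, all derived seeds and per-stage record counts (beats
detected → valid → eligible → epochs kept, non-increasing). The
orchestration defaults are desk-scale (8 subjects, 24 channels, 250 Hz);
`simulationConfig()` itself defaults to the full study conditions (102
channels, 1000 Hz).

Session I/O uses a plain-text directory container (JSON metadata, TSV
signal matrices, CSV trial table, JSON ground truth) so that sessions
remain language-neutral and inspectable.

## Numerical choices and degenerate inputs

* Sliding correlation via zero-padded FFT cross-correlation (padded to a
  highly composite length), exact to machine precision against direct
  `cor()`.
* Flat templates, empty traces, zero-variance z-scoring inputs, empty
  conditions and rank-deficient designs all fail with explicit errors;
  zero-variance t-map samples become t = 0 with a warning.
* All stochastic procedures (generator, permutation test, surrogate,
  stratification) are seeded and restore the caller's RNG state;
  identical seed + configuration reproduces bit-identical output.

## Problem sizes used by the simulation studies

Chosen once, as a balance between statistical resolution and the runtime of
an ordinary test suite: heartbeat bookkeeping over 20 subjects × 72 trials
(ECG sampled at 500 Hz — eligibility rules are specified in seconds and are
sampling-rate-invariant); type-I calibration over 200 null datasets of 12
subjects at 30 channels × 50 bins with 500 permutations; effect recovery
over 50 seeds; surrogate specificity over 10 seeds per arm with 200
surrogates (scaled down from 1000); oracle equivalence over 1000 random
maps.

## Known limitations

* The decomposition behind the component-selection rules is not bundled;
  users supply components from their toolchain of choice.
* The surrogate control's p is only approximately uniform under
  non-locked alternatives; with saturated effects it becomes
  anticonservative (see above).
* Sensor geometry, forward physics and non-Gaussian noise are outside the
  generator's scope; claims about robustness to real-data pathologies
  require real data.
* The BIC Bayes factor is one defensible reading of a loosely specified
  construction; only its qualitative properties are guaranteed.
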