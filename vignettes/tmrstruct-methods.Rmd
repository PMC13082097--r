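---
title: "Simulating and analysing sleep-cued structure transfer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing sleep-cued structure transfer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package models

`tmrstruct` is a simulation-plus-analysis toolkit for category
structure-transfer experiments with targeted memory reactivation (TMR)
during sleep. The experimental logic it implements: participants learn
novel categories whose features covary according to a hidden graph
(either two feature communities, "modular", or a ring "lattice"); later
they learn a *transfer* category built from entirely different features
but sharing (or not) the earlier structure. If structural knowledge is
abstracted away from surface features, a congruent earlier category
should help, and reactivating that category's memory during a nap (by
replaying its associated sound at slow-oscillation up-states) should
help more.

No human data ship with the package. A synthetic-data layer generates
every input — behavioral responses on three tasks, multichannel sleep
EEG with a hypnogram, and cue logs — so that every analysis stage is
exercised end to end under known ground truth. The analyses themselves
(permutation and bootstrap structure statistics, condition regressions,
closed-loop cue scheduling, Morlet/cluster EEG statistics) are the same
computations one would run on real data.

## Category graphs and the ground-truth RDM

Both graphs have 11 nodes: 3 *core* features present in every category
member and 8 *peripheral* features that carry the structure. The modular
graph splits the peripherals into two fully intra-connected communities
of four (no cross-community edges); the lattice connects them in a
single 8-cycle so every peripheral node has peripheral degree 2. Each
graph yields exactly 8 six-feature exemplars (all 3 cores plus 3
structure-consistent peripherals): the two communities contribute
`choose(4, 3) = 4` triples each in the modular case, and the 8 rotations
of a 3-node path do so on the ring. The lattice exemplar rule (three
*consecutive* ring nodes) is a design choice of this package: it is the
unique local rule on the ring that produces the required 8 unique
six-feature exemplars while keeping every peripheral feature equally
frequent.

The ground-truth dissimilarity matrix `true_rdm()` is binary over
peripheral pairs — 0 if two features ever co-occur in an exemplar, 1 if
they never do — with pairs involving a core feature set to an
intermediate 0.5 (core features co-occur with everything, so these
entries carry no structure signal; the value is exposed as
`core_value`, and a `mask_core` switch removes those entries from any
correlation or regression). The scale is irrelevant by construction:
every downstream use is a Pearson correlation or an OLS fit, both
invariant to affine rescaling, and the test suite asserts this
invariance exactly.

## The missing-feature task

Each category is trained over 102 trials: 48 core trials, 48 peripheral
trials, 6 catch trials, with catch trials confined to the second half
and a per-trial auditory-cue flag drawn with probability 1/3. Where the
trial-level rules needed interpretation, the conventions are:

* **Balancing.** Each of the 8 exemplars contributes 6 core and 6
  peripheral trials (each feature of the relevant type missing exactly
  twice). The allocation is not otherwise constrained, so exposure is
  uniform; the order is a seeded permutation.
* **Core-trial foil.** The "structure-consistent peripheral" offered
  as the incorrect option is a peripheral feature *outside* the
  exemplar that shares an edge with at least one shown peripheral —
  the unique fourth community member in the modular case, one of the
  two ring neighbours in the lattice case. Only core-ness then
  distinguishes the options.
* **Peripheral-trial options.** The correct option is any feature that
  completes the shown peripheral pair into a valid exemplar (sampled
  uniformly when two completions exist); the incorrect option is a
  peripheral for which the completion is invalid.
* **Feedback/repetition** is a property of task delivery, not of the
  trial list; accuracy is scored on the initial response, so the
  simulator emits one Bernoulli outcome per trial.

`validate_trial()` re-derives all of these constraints from the graph
and is used property-style in the tests: for every generated peripheral
trial, swapping in the correct option must produce a valid exemplar and
swapping in the foil must not.

## The behavioral knowledge model

The paper-style analyses need participants; the generative model behind
`generate_cohort()` is deliberately the simplest one whose parameters
map one-to-one onto the measured quantities:

* **Missing feature.** P(correct) = 0.5 + 0.5·k, with k = `p_core` on
  core trials and k = `k_struct` on peripheral trials; catch trials are
  correct with probability `p_catch` (0.95). k = 0 is exactly
  two-alternative chance; k = 1 is perfect knowledge.
* **Feature selection.** Three sequential picks without replacement;
  each pick is an unchosen core feature with probability `p_core`, else
  uniform over everything unchosen. At `p_core = 0` this is uniform
  3-of-11 choice with expected core hit rate exactly 3/11 (the "27%"
  chance level; the package reports the exact value and rounds only
  for display).
* **Feature arrangement.** A blended dissimilarity
  `k_struct·z(true) + visual_weight·z(visual) + noise` is embedded in
  the plane by classical metric MDS (`cmdscale`) and rescaled into the
  unit-circle arena. The shared `visual` matrix is a seeded random
  symmetric matrix standing in for normative visual-similarity data,
  which are not available; it is synthetic and labelled as such.
  `arrangement_noise` (sd 0.6 by default) sets how much of each
  participant's geometry is idiosyncratic.

Condition defaults (`default_condition_params()`) were calibrated once,
at design time, so the simulated cohorts emulate the qualitative
published pattern rather than any particular number: selection
`p_core` values of 0.47/0.44/0.47/0.72 across
awake-incongruent/awake-congruent/sleep-incongruent/sleep-congruent map
(through the selection model) onto group accuracies near 60/57/60/78%,
and `k_struct` values of 0.02/0.04/0.03/0.25 make the sleep-congruent
group the only one whose group-mean arrangement passes the permutation
threshold at the design's sample sizes (N = 26/23/20/23). These are
generator conditions, fixed before analysis; nothing in the test suite
tunes them.

What the generator does *not* emulate: within-session learning curves
(accuracy is exchangeable across trials), response times, demographic
structure, and real arrangement-response distributions (the MDS-plus-
noise model is a documented convention). Passing tests therefore
validate the analysis machinery and its calibration under this model,
not claims about human data.

## Structure-match statistics

Arrangement coordinates become an 11 × 11 dissimilarity matrix by
pairwise Euclidean distance, z-scored within participant over the 55
upper-triangle entries (symmetric, zero-diagonal matrices carry all
information there; this is standard RDM practice). Participants whose
coordinates are degenerate (zero distance variance) are flagged and
excluded from aggregation.

The group-level test averages matrices element-wise and correlates the
mean with the truth (Pearson, upper triangle). The null permutes the
feature labels of the *true* matrix — the direction stated for the
original analysis; under Pearson correlation it is equivalent to
permuting the participant side — with the significance threshold at the
null's 95th percentile. `exact = TRUE` enumerates all label
permutations for small matrices and is verified against an independent
oracle in the tests. The bootstrap resamples participants with
replacement (group size preserved) and reports percentile quantiles.

One property of that bootstrap deserves a caveat: because a resampled
mean duplicates participants, it is noisier than the sample mean, so
its correlation with the truth is attenuated whenever the true
alignment is far from zero. The percentile interval therefore sits
below the point estimate and should be read as a significance device
(does the interval clear zero / the permutation threshold), not as a
calibrated confidence interval for the population correlation. The
test suite verifies calibration where the procedure is unbiased (null
cohorts, population r = 0).

Per-participant structure knowledge is the OLS coefficient of the
participant's upper-triangle entries on the z-scored true matrix,
controlling for the z-scored visual matrix; collinear predictors are
flagged rather than fitted. Condition comparisons use `condition_model()`:
OLS with the declared baseline condition as reference for continuous
outcomes, and a binomial logistic model for the selection score, which
is a count of 0–3 correct out of three picks (modelling the proportion
as binomial rather than Gaussian). The model-level test compares
against the same model without the condition factor (F or likelihood
ratio). Following the original analysis style, the package applies no
multiple-comparison correction across behavioral contrasts; they are
reported as a priori comparisons.

## Synthetic sleep EEG

`generate_hypnogram()` draws 30-s scoring epochs from a first-order
Markov chain over Wake/N1/N2/N3/REM. The default profile produces
nap-like records (sleep onset through N1, consolidated N2, N3 periods,
occasional late REM); total sleep time is the summed duration of the
four sleep stages. A `wake_bias` parameter shifts transition mass
toward Wake and is drawn per participant in the pipeline
(uniform on [0, 0.3]), because real nap cohorts vary widely in sleep
depth and that variability is what gives cue-dose regressions their
leverage.

`synthesize_eeg()` builds each channel from 1/f background noise
(spectral shaping; slope 1, RMS 12 µV by default) and injects:

* **Slow oscillations** in N3 (5/min) and N2 (half rate): one full
  0.8 Hz cosine cycle, down-state half-wave then up-state half-wave,
  positive peak +75 µV at Fz. This morphology is a package choice — it
  makes "the peak" and "slope changes from positive to negative"
  well defined for the online detector, and its band-passed amplitude
  comfortably exceeds the +35 µV detection threshold.
* **Spindles** in N2 (3/min) and N3 (half rate): Hann-windowed bursts,
  11–16 Hz, 0.5–1.5 s, 25 µV envelope.

Every injected event is logged with onset, peak time, and amplitude;
these ground-truth logs are the oracle for all detection benchmarks.
Cz carries a scaled copy of the event content plus independent noise;
M1/M2 are low-amplitude stand-ins so the linked-mastoid re-referencing
code path is exercised. The channels are reference-free by
construction — no hardware referencing is modelled.

## The closed-loop TMR engine

`run_tmr()` emulates the online system: causal filtering only, no
lookahead. An SO candidate arises when the causally band-passed Fz
signal crosses +35 µV upward; the cue fires at the first subsequent
sample where the filtered derivative turns negative (a 2-s guard
abandons detections with no peak). Cues are withheld within 2.5 s of
online spindle activity, detection is suspended for 8 s after every
sound, and cue kinds are consumed cyclically (default
target → control → sham).

Design choices that needed a decision:

* **Online SO band: 0.25–2.5 Hz** (configurable). A causal 0.5–4 Hz
  second-order Butterworth leads the true 0.8 Hz up-state peak by
  ~150 ms and passes enough 2–4 Hz noise to jitter the located peak,
  which would defeat the point of up-state-locked cueing; with
  0.25–2.5 Hz the worst-case delivery error on ground-truth SO peaks
  stays below ~80 ms across seeds, and the engine's ±100 ms delivery
  contract is met with margin.
* **Spindle refractory semantics.** The online detector reports
  rising-edge detection times, but the refractory clock runs from the
  most recent *above-threshold* sigma-RMS sample: a sustained spindle
  train keeps the refractory active indefinitely (and the tests assert
  that a continuous train yields zero cues).
* **Sham markers** record the timepoint without playing audio and, by
  default, without triggering the 8-s lockout (no sound was played);
  whether the original system locked out after shams is unknown, so
  the behaviour is a `sham_lockout` switch.
* **Epoch convention.** Scoring epochs are half-open `[start, end)`;
  an event exactly on a boundary belongs to the later epoch.

`tally_cues_by_stage()` assigns each cue the stage of its containing
epoch and conserves totals.

## Cue-locked analysis

Preprocessing downsamples to 256 Hz (FIR decimation), re-references to
the linked-mastoid average (skipped with a warning when mastoids are
absent), and band-passes 0.3–30 Hz with a zero-phase Butterworth.
Epochs span [−3, 3] s around cue onset. The manual artifact-rejection
stage of a real analysis is replaced by an automatic screen: per-trial
peak amplitude, variance, and kurtosis (max across channels) converted
to robust z-scores — median/MAD, because an ordinary z-score among n
trials is bounded by (n−1)/√n and could never flag a gross artifact in
a small epoch set — with rejection at z > 5.

Time-frequency decomposition uses complex Morlet wavelets, 4–30 Hz in
0.5 Hz steps, 5-ms output steps. The wavelet width is 5 cycles — the
width is a free parameter here; absolute power depends on it, but the
percent-change contrasts the statistics consume are robust to it.
Power is trial-averaged (and electrode-averaged, as the statistics
expect) before conversion to percent change against the pre-cue
baseline window **[−1.25, −0.25] s**. The source text prints this
window in "ms"; a millisecond reading is not computable at 5-ms
resolution, so seconds is the only consistent interpretation and is
what the package implements. One numerical caveat is asserted in the
tests: percent change is exactly zero for stationary signal content at
bins where that content has power, but at bins whose baseline power is
near zero the ratio is dominated by sampling noise — interpretation of
percent-change maps should stay within the signal band.

ERPs high-pass the trial average at 0.5 Hz (after demeaning, which
removes zero-phase edge transients for constant inputs) and baseline-
correct to [−200, 0] ms.

Cluster statistics: pointwise one-sample t-tests across participants at
α = 0.01 (two-sided by default; the sidedness of the original pointwise
test is unstated, so it is switchable) form candidate clusters under
4-connectivity (no diagonal adjacency), separately per sign. The
cluster statistic is size in grid points (cluster mass is available as
an alternative); the null is the maximum cluster size under random
participant sign flips (1000 by default; `exhaustive = TRUE` enumerates
all 2^n patterns and is checked against an independent oracle).
Corrected p is the null exceedance frequency with the add-one
convention for sampled nulls. Because cluster sizes are small integers
under the null, the max-size test is discrete and runs conservative at
small grids — the type-I property test sizes its grids (15 × 20 points,
16 participants) so the empirical rate sits inside [2%, 8%].

## The pipeline and its dose model

`run_experiment()` wires the stages together for the two designs. For
each sleep participant it simulates a nap, runs the TMR engine, and
tallies cues; the participant's transfer-structure knowledge is then
modulated by delivered dose on the log-odds scale:
`qlogis(p_core) + cue_boost · (n_transfer_cues − ref_cues)` with
`cue_boost = 0.017` per cue. The anchor `ref_cues` defaults to the
generator's typical dose (0.33 cues per nap minute) so the condition's
nominal parameters hold at a typical nap regardless of the configured
nap length. Incongruent-arm target cues reactivate the wrong structure
and contribute zero transfer dose.

Sound-evoked activity is injected post hoc (a 6 Hz, 8 µV burst
0.3–1.0 s after each played cue, absent after shams) so that
target-vs-sham TFR contrasts carry a detectable effect for the cluster
pipeline; the synthetic background itself has no auditory physiology.
With the default settings the significant cluster falls in the
delta/theta band shortly after cue onset, the qualitative analogue of
the published evoked response.

Every stage derives its RNG stream from the master seed via fixed
child-seed arithmetic, so a results bundle is bit-reproducible from
`master_seed` plus the config; `write_bundle()` records an MD5-hashed
manifest of every artifact.

## Problem sizes

The test suite and the acceptance script scale simulations to
desk-scale sizes as the package's own defaults for verification runs:
naps of 10–30 minutes (2 h remains the pipeline default), 5–20 seeds
per detection benchmark, 500–1000 replicates for type-I studies,
cluster grids of a few hundred points, and n = 500/group for logistic
recovery. The acceptance-scale cue-dose check uses a larger per-cue
boost at its reduced nap length so the dose spread in log-odds matches
the full-scale regime. The vignette-level claims above (latency
margins, calibration bands) are exactly the quantities those tests
compute.

## Known limitations

* The behavioral generative model has no trial-order learning dynamics
  and an invented arrangement noise model.
* The EEG is not biophysically realistic (no topography, no EOG/EMG,
  no SO-spindle coupling); mastoids are placeholders.
* The bootstrap for group alignment is a significance device, not a
  calibrated CI (attenuation at large true alignment; see above).
* The online spindle detector is an RMS stand-in for an unpublished
  original; its threshold was fixed once against the generator's
  ground truth (recall ≥ 0.8) and left alone.
* Phase-1 memory testing after the transfer tasks is summarized only
  through phase-1 learning accuracy; the interference dynamics the
  original design worried about are out of scope.
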