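---
title: "Methods: developmental olfactory electrophysiology analysis"
author: "olfOntogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developmental olfactory electrophysiology analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfOntogeny)
```

## Scope and data model

Hemimetabolous insects such as locusts hatch with a structurally complete
olfactory system and refine it quantitatively as they grow: the antenna
adds sensory-neuron-bearing segments, the brain roughly doubles in size,
and odor-evoked network dynamics change in measurable ways. This package
implements the three analysis chains needed to quantify that maturation
from electrophysiology — peripheral tuning (EAG), projection-neuron (PN)
response complexity (patch-clamp spike trains), and mushroom-body local
field potential (LFP) oscillations including antennal-trimming
manipulations — together with synthetic generators that emulate each
modality's statistical structure.

All analyses consume a single container, `EphysDataset`: a list of
`SpikeTrainTrial` (sorted spike times in seconds) and `AnalogTrial`
(uniform samples in millivolts with a sampling rate) objects, each
carrying its `OdorStimulus` (label, onset, duration — 1 s pulses by
convention) and `AnimalMeta` (id, age group, antennal segment count).
Units are fixed at seconds / millivolts / hertz at the API boundary; the
on-disk format (a versioned `manifest.json` plus one plain-text file per
trial) may declare milliseconds or microvolts and is converted on load.
Time zero is the trace start and the stimulus position is carried as an
onset rather than re-zeroed, because every analysis needs pre-stimulus
baseline windows. Trial indices are 1-based so that "trials 3–10" in an
averaging rule means exactly what it says. `validateDataset()` audits
every domain invariant (monotone spike times, stimulus inside the record,
Nyquist margin for the 50 Hz analysis band, uniqueness of trial indices
within a recording/odor/side group) and returns violations instead of
raising, so partially broken data can be triaged.

Sampling rates are never assumed: the format requires `fs_hz` per analog
file. The generators default to 1000 Hz (LFP) and 500 Hz (EAG).

## EAG analysis

The EAG peak is defined operationally as the maximum **absolute**
deviation from the pre-onset baseline (the mean of all pre-onset samples)
within a 2 s response window. Absolute deviation is polarity-agnostic; EAG
deflections are conventionally negative-going, but electrode conventions
vary and the magnitude is what the tuning comparison uses.

Within-animal normalization divides every odor's peak by the same
animal's hexanol peak. This makes hexanol exactly 1 per animal, removes
multiplicative gain differences between preparations (the property is
tested: scaling a whole panel leaves the normalized map unchanged), and
implies the reference odor cannot itself be compared across groups — it is
excluded from the pairwise tests.

Age groups are compared per odor with two-sample *t* tests at a
Bonferroni-corrected alpha `family_alpha / m`. Conventions that a figure
or table rarely pins down are explicit parameters:

* **t variant** — Welch (unequal variances) by default, since group sizes
  differ; the pooled-variance Student form is available via
  `variant = "pooled"`.
* **Bonferroni divisor** — defaults to the number of odors actually
  tested, overridable via `m_comparisons` (a printed alpha of 0.006 is
  consistent with dividing 0.05 by 9, not by the 7 odors a table may
  list; both conventions are reachable).

The panel-level model is a dummy-coded OLS, `amplitude ~ age_group +
odor`; the age coefficient with its SE and *p* is the quantity of
interest. The fit refuses rank-deficient designs by naming the aliased
terms instead of silently dropping them.

## PN response complexity

### Responsiveness gate

Spike rates are computed in 400 ms bins. The baseline is the pre-stimulus
bin rate averaged across the pair's trials; a trial is responsive in a bin
of the 4 s post-onset window if its rate deviates from that baseline by
more than one standard deviation, and a PN-odor pair enters the analysis
if some bin is responsive in at least half of the trials. Which population
the SD describes is genuinely open; the package defaults to the SD of the
pooled pre-stimulus bin rates across trials (the highest-powered reading)
and exposes a per-trial alternative (`sd_mode = "per_trial"`). With a
perfectly regular train the SD is zero and a bin is responsive only if it
deviates at all — strictly constant activity is never "responsive".

### Rate estimation and smoothing

The instantaneous rate is the inverse inter-spike interval: for
`t_i < t <= t_(i+1)` the rate is `1/(t_(i+1) - t_i)`; before the first and
after the last spike the rate is defined as 0 (the inverse interval does
not exist there, and zero matches the absence of observed activity).
Trains with fewer than two spikes give an all-zero series. The series
(1 ms steps) is smoothed with a truncated unit-sum Gaussian, σ = 33.33 ms
and 200 ms (6 σ) support. Two numerical choices matter:

* **Edges** are reflect-padded: zero padding would fabricate deep edge
  valleys that inflate transition counts.
* The convolution is a **direct sum** (`stats::filter`), not FFT-based:
  FFT round-off leaves ~1e-13 ripples on flat plateaus, which a
  zero-threshold peak detector happily reports as epoch structure. With
  exact sums, a noiseless piecewise-constant profile stays exactly flat
  between transitions.

### Peak detection

The detector is the classic lookahead/delta alternating-extrema scan: a
running candidate maximum (minimum) is confirmed as a peak (valley) when
the series drops below the candidate minus delta (rises above it plus
delta) and no sample within the lookahead horizon exceeds (undercuts) the
candidate; confirmed extrema strictly alternate. A candidate sitting on
the very first sample is discarded as an initialization artifact — the
scan has no information before it — so monotone series yield nothing
while an interior bump taller than delta yields exactly one peak.

The two parameters are not dictated by the procedure's description, so
they are explicit arguments with motivated defaults: `lookahead_s = 0.2`
(the smoothing support — structure finer than the kernel cannot be real)
and delta = one SD of the pooled pre-onset smoothed rate of the pair
(tying the prominence floor to the responsiveness criterion), overridable
with `delta_hz`.

### Transition counting

Peaks mark excitatory epochs; the valleys between them, inhibitory
epochs. Each valley lying strictly between two in-window peaks counts two
transitions (excitatory→inhibitory and back). Boundary transitions encode
whether the response emerged from and/or returned to baseline inside the
4 s window: a spontaneous→excitatory transition is counted when the first
in-window peak appears more than 200 ms after onset, and an
excitatory→baseline transition when the last in-window peak lies more
than 200 ms after onset and before the window's end. The 200 ms guard is
applied to both boundaries: a lone peak within 200 ms of onset is read as
excitation already in progress at stimulus time, contributing no
boundary transition — under a guard-free reading the same response would
absurdly score an "end" transition while being denied a "start". The
count therefore always equals `2·V + B` with `V` interior valleys and
`B ∈ {0, 1, 2}` (a tested invariant).

Ground truth for synthetic profiles comes from an independent
rule-enumeration oracle (`profileTransitions()`): merge equal adjacent
segments, take strict local maxima/minima of the level sequence, apply
the counting rules with each epoch's appearance time at its segment
start. `RateProfile` objects stamp this at construction; it is never
hand-entered.

At physiological firing rates the inverse-ISI estimate is noisy enough
(the smoothing kernel spans only a handful of intervals) that single-trial
counts scatter around the profile's truth; the statistic is therefore
used distributionally — per-trial counts pooled over pairs, compared
across ages by a two-sample KS test — exactly as the gate-then-pool
pipeline does. Trial-level recovery (modal count = truth in ≥ 90% of
trials) holds in the low-noise regime the tests use: epochs ≥ 0.5 s,
transient rates around 100 Hz, silenced inhibitory epochs, delta at 40%
of the peak rate (excursions exceed twice delta).

### Firing-rate ANOVA

Mean rates per trial — spontaneous (2 s before onset) or evoked (4 s from
onset; the windows are conventions, stated because figure-level summaries
leave them open) — are modeled as rate ~ age × odor. Type II sums of
squares are the default (the odor design is mildly unbalanced); Type I
and III are available, and the three provably coincide on balanced
designs (tested). Empty cells are an error naming the cells.

## LFP oscillation pipeline

* **Filter**: Butterworth bandpass 3–50 Hz, order 4 per direction,
  applied forward–backward (zero phase, so latency estimates are not
  shifted). The realization is a choice — "digitally bandpass filtered"
  names a family — and zero-phase is the member that preserves timing.
  The trace mean is removed and the ends odd-reflected before filtering
  to suppress start-up transients.
* **Spectrogram**: 0.5 s Hann windows, 50% overlap, one-sided squared
  DFT magnitudes; 2 Hz frequency resolution by construction. Time
  centers sit at window midpoints on the trial's own axis.
* **Averaging**: element-wise mean over trials 3–10; the first two
  presentations are excluded because oscillations typically only develop
  after a couple of stimulations.
* **Peak frequency**: the argmax over the 3–50 Hz rows of the columns
  within 1 s of odor onset. Descriptions that key this window to absolute
  record time (e.g. "2–3 s") agree with the onset-keyed default whenever
  the stimulus sits at 2 s; an absolute override (`window_abs_s`) exists
  for other layouts. A peak is flagged low-confidence unless it exceeds 3
  times the strongest pre-stimulus power in the band. (A guard against
  the in-window *median* was considered, but the maximum of a hundred-odd
  noise bins routinely sits 5–8× above their median, so a median-relative
  rule cannot actually separate noise from signal; referencing the
  pre-stimulus noise floor can.)
* **Burst properties**: the envelope is the analytic-signal magnitude
  (FFT Hilbert transform) of the band-passed trial-averaged trace.
  Amplitude = envelope maximum in the response window; duration = longest
  contiguous suprathreshold span (threshold: baseline mean + 2 baseline
  SD); latency = start of the first qualifying span after onset. Runs
  shorter than `min_span_s = 0.1` s are discarded — a 2 SD threshold is
  crossed by chance a few percent of the time, but only in brief bouts,
  while genuine bursts last hundreds of milliseconds. With no qualifying
  span, duration is 0 and latency is reported missing.
* **Trim regression**: one peak frequency per (antenna, stage) — from the
  trials 3–10 average at that stage — regressed on the cumulative number
  of cut segments by OLS, separately per side. One value per
  (antenna, stage) rather than per trial keeps the regression's n honest
  about its effective replication.

## Synthetic generators

Each generator is deterministic given (config, seed) and stores its
ground truth for recovery tests.

* **Spike trains** (`genPNTrials`): inhomogeneous Poisson by thinning
  against a piecewise-constant `RateProfile`, ≥ 2 s pre-onset baseline.
  Per-age default profiles (`ageRateProfile`) share a
  two-excitation/two-inhibition layout with epochs wider than the 400 ms
  bins; rates are ordered hatchling < 10 d < 20 d < adult (baselines
  1.5–4 Hz, transients 25–55 Hz). The ordering is the modeled claim; the
  numbers are plausible defaults, not measured values.
* **LFP** (`genLFPTrials`): AR(1) background (coefficient 0.97,
  stationary SD 0.02 mV, plus 0.005 mV white noise) approximating a 1/f-
  like spectrum without the band-edge artifacts synthetic 1/f filtering
  can introduce, plus a stimulus-locked sinusoidal burst under a
  raised-cosine envelope. The burst frequency comes from the `DriveMap`
  `f(n) = max(5, 20 − 0.52·(25 − n))` — a phenomenological map from
  intact-segment count (afferent drive) to oscillation frequency — and
  its amplitude scales with the fraction of intact segments. Per-age
  amplitude (0.05→0.20 mV), duration (0.5→1.2 s) and onset latency
  (0.10→0.30 s) increase from hatchling to adult; hatchlings default to
  12 segments (within the 11–13 range at hatching), giving ~13.2 Hz from
  the map rather than from any measured hatchling value.
* **EAG** (`genEAGTrials`): difference-of-exponentials deflections (rise
  50 ms, decay 400 ms), per-odor mean peaks with hexanol largest
  (2.0 mV), a log-normal per-animal gain (removed by normalization),
  15% between-trial peak variability and 0.02 mV trace noise. Age groups
  share identical means by default — the null the age comparison should
  not reject.
* **Trimming** (`genTrimExperiment`): per animal and stage, 10 ipsi
  trials at the trimmed count and 10 contra at the intact count. The
  per-animal reference frequency is jittered (SD 1 Hz) with a small
  per-stage drift (SD 0.3 Hz, independent per side): real animals differ
  by a few hertz and their state drifts between stages. This variability
  also matters methodologically — peak frequencies are quantized to the
  2 Hz bin grid, and without biological scatter a regression on the
  quantized staircase would be degenerate (zero residual variance).

What the generators deliberately do **not** emulate: antennal-lobe
network biophysics (no conductance-based model; the drive→frequency map
is phenomenological), non-Poisson spiking regularity or adaptation,
phase-varying or frequency-drifting oscillation bursts, correlated noise
across simultaneously recorded channels, and recording artifacts.
Passing the recovery tests therefore demonstrates that the analysis code
implements its stated rules and can invert its own generative
assumptions — not that those assumptions exhaust real recordings.

## Statistical core

`tTwoSample` and `olsCategorical`/`anovaTwoWay` are thin, tested adapters
over `stats::t.test`, `stats::lm` and `car::Anova`. The two-sample KS
test is implemented in-package: transition counts are small tied
integers, and the reference implementation downgrades its p-value under
ties, whereas the ECDF supremum is perfectly well defined. The p-value is
the asymptotic Kolmogorov series at `sqrt(nm/(n+m))·D` (the convention
appropriate at the trial counts the comparisons involve); for
`max(n, m) ≤ 10` an exact permutation enumeration over all
`choose(n+m, n)` assignments — exact under ties — is available. Tests
cross-check the statistic against a brute-force oracle, tie-free p-values
against `stats::ks.test`, and invariance under monotone transforms.

## Problem sizes and tolerances used by the test suite

The suite is sized to run in minutes on one core: 500 replicate EAG
datasets (9 vs 8 animals, 8 odors) for the type-I calibration, with
binomial Monte-Carlo bands (±2.5–3.5 SE) fixed in advance around the
nominal alpha and the family-wise bound; 100 Poisson trials for
transition recovery; 7 antennae × 6 stages × 2 sides × 10 trials for the
trim recovery (slope within 2 fitted SE, contralateral CI covering 0);
oracle equivalences at 1e-8–1e-12. Spectral recovery is asserted exactly
on the 2 Hz bin grid and within one bin off-grid.

## Known limitations

* The responsiveness SD population, detector delta, Bonferroni divisor
  and t variant are conventions with exposed switches; analyses of
  archival data should report which configuration they used.
* Burst amplitude/duration/latency depend on the envelope threshold
  convention; they are comparable within a configuration, not absolute.
* The KS p-value is asymptotic in the pipeline path; for very small
  count sets use `exact = "always"`.
* No mixed-effects machinery, no spike–LFP phase-locking analysis, and no
  acquisition-system readers (plain-text interchange only).
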