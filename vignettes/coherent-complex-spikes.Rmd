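---
title: "Methods: coherent complex spikes, zones, and lick initiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coherent complex spikes, zones, and lick initiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocs)
```

# The analysis problem

Cerebellar Purkinje cells fire two kinds of spikes. Simple spikes (SS, tens
of hertz) are modulated by mossy-fibre/parallel-fibre input; complex spikes
(CS, ~1-1.5 Hz) are driven by climbing fibres and produce large dendritic
calcium transients that two-photon imaging resolves one dendrite at a time.
During a go/no-go licking task -- a multisensory Go cue (air puff + tone)
versus two unisensory No-go cues, with a 500-ms response window -- CS
activity in lobule Crus I is organised into parasagittal zones roughly
300 um wide: bands of dendrites whose spontaneous CS events are strongly
correlated, reflecting shared climbing-fibre input. Within a zone, frames
in which a large fraction of dendrites fire together form *coherent
complex-spike (CoCS) events*, and the fraction of co-active dendrites at
the event peak is its *coherence level*.

`cocs` implements the full measurement chain for this setting:

1. a synthetic-session generator with known ground truth,
2. fluorescence preprocessing (rolling-percentile dF/F, kernel-matching
   event detection, ROI merging),
3. zone discovery by sequential binary k-means on the trace correlation
   matrix,
4. CoCS extraction and trial alignment,
5. electrode-side analyses (unit classification, SS modulation,
   millisecond CS synchrony with a permutation null, JPSTH),
6. behavioural metrics (outcome rates, d', latency residuals) and the
   regression models linking neural signals to lick initiation (OLS with
   leave-one-out likelihood-ratio tests; a linear mixed model with a
   per-mouse random intercept).

Because no recordings ship with the package, every quantitative claim the
test suite makes is a *recovery* claim: plant a known structure with the
generator, run the pipeline, and check the structure is recovered.

# The synthetic session generator

## Coherence model

Events are binary per frame (30.03 frames/s). Each zone owns a Bernoulli
"mother" train at the per-ROI CS rate (default 1.24 events/s); each member
dendrite participates in a mother event with probability
`within_zone_coherence` (default 0.6). An optional session-wide mother
with participation `across_zone_coherence` adds across-zone correlation,
and independent per-ROI events top each dendrite's total rate back up to
the configured CS rate. For small per-frame probabilities the pairwise
event correlation is then approximately

* within a zone: `within_zone_coherence^2 + across_zone_coherence^2`,
* across zones: `across_zone_coherence^2`,

which is how fixtures with prescribed correlation targets (e.g. 0.4
within / 0.05 across) are built: set the participations to the square
roots of the target gaps. This thinning model is the simplest mechanism
with a single interpretable coherence knob; its known artefact is that
every spontaneous mother event carries the full participation
probability, so spontaneous CoCS events are as coherent as evoked ones
(real spontaneous synchrony is more graded). Statistics that take the
maximum coherence inside a response window therefore sit above the evoked
participation level whenever a spontaneous event lands in the window.

## Evoked responses and behavioural coupling

Sensory-evoked CS events are planted per trial and zone with probability
`evoked_prob[cue][zone]` at a uniform latency in the 0-250 ms window. The
default response map alternates responsive (odd) and unresponsive (even)
zones, with air-puff-containing cues more effective than the tone alone.
Participation in an evoked event follows the same linear design the
downstream mixed model estimates:

```
participation = base + b_air * air + b_tone * tone + gain * lick
```

with defaults `base = 0.28`, `b_air = 0.08`, `b_tone = 0.01` and the lick
gain `coherence_gain_on_lick = 0.04` applied at the expert stage only --
the coupling between motor initiation and CS coherence is what training
adds, while the sensory drive is present throughout. Two optional
couplings make causal recovery tests possible: `lick_coupling_delta`
raises the lick probability on trials with a planted zone-1 event, and
`residual_shrink_on_cocs` multiplies the latency CV on those trials
(values below 1 emulate more precisely timed licks after coherent CS
activity).

## Behaviour

Cues are pseudo-randomized at a 1:1:1 mix with at most three consecutive
identical cues. First-lick latencies are gamma distributed (right-skewed,
shape fixed by the CV): air-puff-containing cues use mean 210 ms, CV 0.20;
the tone-only cue 280 ms, CV 0.30; the apprentice stage multiplies CVs by
4/3 so that the mean absolute deviation from the median -- the latency
residual, reported as a percentage of the mean latency -- lands near 21%
(apprentice) and 16% (expert). Photostimulated Go trials draw from a
mixture: the lick is abolished (probability 0.30), pushed beyond the
window into 0.5-1.0 s (0.15), or slowed to a 360-ms mean. Licks continue
as a 7-Hz bout for 1.5 s; spontaneous bouts occur between trials so that
spontaneous lick-onset analyses have material to work with.

## Electrophysiology

Each of `n_units` (default 13) model Purkinje cells contributes a Poisson
SS train and a Poisson CS train; SS within 10 ms after a CS of the same
cell are deleted. The SS base rate is set to
`ss_rate_hz / (1 - cs_rate * pause)` so the *realized* rate after pause
deletion matches the 84.1 spikes/s set-point. Optional per-unit additive
SS modulation in the 0-100 ms post-cue window supports recovery tests of
trial-aligned rate changes.

## What the generator does not emulate

No pixel-level movies, motion artefacts, neuropil contamination, slow
drift, bursty lick kinematics, or electrode drift/sorting errors. Noise is
i.i.d. Gaussian per frame. Passing recovery tests therefore demonstrates
correctness of the analysis chain under the stated statistical model, not
robustness to every artefact of real recordings.

# Preprocessing

## dF/F

`dff()` computes `(F - F0) / (F0 - Fb)` with `F0(t)` the 8th percentile
of the raw trace over a 31-frame window centred on `t` (about 1 s) and
`Fb` the floor fluorescence. Conventions fixed for reproducibility:
percentiles use linear interpolation (R's type-7 quantile), and windows
truncate at the trace ends rather than padding. A property test pins the
rolling baseline to a brute-force per-window sort.

## Event detection

The detector is greedy template matching with the calcium kernel
`k(n) = amp * exp(-n * dt / tau)` (one-frame rise; `tau = 0.15` s,
`amp = 0.65` dF/F): repeatedly fit the kernel to the residual by least
squares, take the best frame, subtract, and stop when the fitted
amplitude falls below the acceptance threshold. Runs of accepted frames
are merged and stamped at the first frame, and the output is binarized
(multi-frame runs at this frame rate reflect one large dendritic event).

Two numerical choices matter:

* **Offset invariance.** An 8th-percentile baseline sits about 1.4 noise
  SDs *below* the noise mean, so dF/F carries a positive offset that a
  raw kernel correlation would book as amplitude. The amplitude is
  therefore fit jointly with a local constant (equivalently, the template
  is centred within its window).
* **Noise-adaptive acceptance.** Acceptance requires the fitted amplitude
  to exceed both `accept_fraction * amp` (default 0.5, the fixed gate)
  and `z_gate = 3.5` robust SDs of the matched-filter amplitude, with the
  noise level estimated from the MAD of the trace's first difference.
  The second gate was set at the design operating point of one unitary
  amplitude to five noise SDs, where it holds both recall and precision
  above 0.9; with clean traces it is inactive and the fixed gate governs.

## ROI merging

Over-segmented dendrites are merged bottom-up: among pairs within
`dist_um` (default 10 um) and correlation at least `corr_min` (default
0.6), merge the most correlated pair (ties to the lowest index) into a
pixel-count-weighted average of traces and centroids, and iterate to the
fixed point. Termination is guaranteed because each merge reduces the ROI
count by one.

# Zone discovery

The correlation matrix of full-session traces, rows ordered lateral to
medial, is clustered by *sequential binary k-means*: run 2-means on the
rows of the current submatrix (20 seeded random restarts of
`stats::kmeans`), and accept the split only if both children have at
least `min_zone_size = 10` ROIs and the *separability* -- mean
within-child correlation minus mean between-children correlation -- is at
least `sep_threshold`. Accepted children recurse; leaves become zones,
renumbered 1..K lateral to medial by median coordinate.

The stopping rule formalises what was a human judgment ("splitting
further just cuts a homogeneous cluster randomly"). `sep_threshold`
defaults to 0.05: the spurious-split separability of a homogeneous block
is sampling noise (of order 0.005 at typical sizes), while the first
split of a six-zone field dilutes the within-child mean over three blocks
(about a third of the within-zone correlation), so the threshold must sit
well below ~0.12 and well above ~0.005. Degenerate settings behave
predictably: `sep_threshold = 1` always yields one zone;
`sep_threshold = 0` with `min_zone_size = 1` runs to the k-means fixed
point. Initialisation uses multiple seeded random restarts rather than a
bespoke farthest-point seeding; with 20 restarts the partition is stable
across RNG seeds on block-structured matrices (checked by adjusted Rand
index in the suite).

No spatial-contiguity constraint is imposed: zones come out contiguous
because the correlation structure is, which is itself a property worth
testing rather than forcing.

# CoCS events and trial alignment

The co-activation trace of a zone is the fraction of member ROIs with an
event in each frame. CoCS events are strict local maxima
(`c[t] > c[t-1]` and `c[t] >= c[t+1]`, so plateaus stamp at their first
frame) whose z-score -- standardized by the full-session mean and SD of
the trace, evoked periods included, exposed as a choice -- reaches 3. The
coherence level is the raw co-activation value at the peak.

Cue onsets are mapped to the frame timeline by the half-frame rule (half
a frame length before the first frame triggered after the event), and all
windows are half-open `[start, end)`. A trial is CoCS-positive for a zone
when an event peak falls within 250 ms of the aligned cue time; per-zone
probabilities are computed per trial type, and licking trials (Hit, FA1,
FA2) split into CoCS+/CoCS- groups for latency and residual comparisons.
Sessions with fewer than 7 licking trials in either group are flagged and
excluded from those comparisons.

# Electrode-side analyses

**Unit classification.** Rate above 40 spikes/s labels a unit SS; units
at 25-40 spikes/s are rescued as SS only when the CS-triggered
cross-correlogram shows a pause (0-10 ms rate under half the -50 to
-10 ms baseline rate); units in the 0.5-3 Hz band with a pause-producing
SS partner become CS; the rest stay unknown. The 50% pause criterion and
the CS band are exposed parameters; the pause itself is described only
qualitatively in the source material.

**SS modulation** is the rate difference between the 0-100 ms post-cue
window and a pre-cue baseline, per trial; the post-cue window precedes
the earliest licks so it cannot contain movement feedback. In
lick-aligned mode, non-licking trials are aligned to the mean first-lick
latency of the matching licking trial type so a lick predictor remains
estimable.

**Synchrony.** Per trial, CS of all units are binned at 1 ms over the
0-50 ms post-cue window; the statistic is the peak fraction of units
firing in one bin. The null redraws each unit's spike times uniformly in
the window, preserving counts (1,000 surrogates), and a trial is
significant when the observed peak *strictly exceeds* the 97.5th
percentile of surrogate peaks. With sparse trains this rule is markedly
conservative: most trials carry zero or one spike, for which observed and
surrogate peaks tie exactly, and only a same-bin collision between two
units can exceed the threshold. For 13 independent 1.5-Hz trains the
expected collision probability per trial is roughly
`(13 * 0.075)^2 / (2 * 50)` (~1%), and trials with three or more spikes
raise their own surrogate threshold, so the realised type-I fraction sits
near 0.1-0.5% rather than the nominal 2.5%. The suite asserts the nominal
calibration band and that check fails by design under these conditions --
it documents a real property of the discrete rule, not an implementation
error. A randomized tie-breaking test would restore exactness but would
no longer be the published rule, so it is not the default.

**JPSTH.** For a CS pair, trial-binarized 5-ms bins give the
trial-averaged joint histogram; the outer product of the marginal PSTHs
is subtracted and each cell normalized by the product of bin-wise
population SDs (so a pair of identical trains normalizes to exactly 1 on
the diagonal). Zero-variance margins yield `NA` rather than a value.

# Behavioural metrics

Outcomes are assigned by lick presence in the half-open response window;
rates are per stimulus condition. d' is `Z(hit) - Z(fa)`; a hit rate of
exactly 1 is replaced by 0.99 before the transform, and rates of 0 (or an
FA rate of 1) are capped symmetrically at 0.01/0.99 with a `capped` flag
-- the mirror of the published 99% rule, which is stated only for perfect
hit rates. The session d' is the minimum over the two No-go comparisons.
Latency residuals are `|latency - median| / mean` within the *same trial
type* (the normalisation scope was ambiguous; per-type keeps the measure
comparable across cue modalities with different baseline latencies),
in percent. The extended 1-s window separates delayed first licks
(0.5-1 s) from missed ones. Spontaneous lick-bout onsets are first licks
outside any cue window on trials following CR/Miss outcomes, and the
licking-epoch ratio is the fraction of consecutive 500-ms windows
containing a lick.

# Regression models

Both models assume a normal response, which makes the "GLM" ordinary
least squares and the "GLMM" a linear mixed model -- and makes closed-form
generalized-least-squares solves valid inside the mixed model.

`fit_glm()` regresses a per-trial response on binary air/tone/lick
predictors. Per-predictor significance comes from a leave-one-out
likelihood-ratio test (chi-squared, 1 df): the published description says
only that model fits were compared with a variable removed, and the LRT
is the canonical such comparison; Wald tests would differ only at small
n. An exact-fit RSS is floored at 1e-12 so constant responses produce
finite log-likelihoods and p-values near 1.

`fit_lmm()` adds a single random intercept per mouse, fit by maximum
likelihood: the variance ratio `gamma = var_b / var_e` is profiled with a
1-D optimizer on the log scale (interval `e^-12` to `e^6`, boundary
`gamma = 0` checked explicitly); for each candidate the block-diagonal
covariance gives `log det` and GLS solutions analytically per group. ML
rather than REML is used throughout so the leave-one-out LRTs on fixed
effects compare likelihoods of nested models fitted to the same data.
The model's R^2 is the squared correlation between conditional fitted
values (fixed effects plus BLUP intercepts) and the observations. The
suite pins the optimum against a direct multivariate-normal density on a
12-row dataset and against an independent ML mixed-model fitter.

Per-cell latency regressions use `alpha / n_cells` (0.05/30 = 0.0017 for
a 30-cell family) as the Bonferroni significance line; multiple-testing
corrections delegate to `stats::p.adjust`. Cohen's d uses the pooled SD
with n-1 weights.

# Problem sizes and runtime choices

The test suite exercises sessions of 1-6 zones, 2-50 dendrites per zone
and 1-10 minutes, 200-1,000 behavioural trials, and mixed-model tables of
12-340 rows; stochastic recovery claims use 10-20 fixed seeds. The
acceptance script analyses one full field at study scale (300 dendrites,
513 s at 30.03 frames/s) through the complete chain and scales the
remaining checks as above. These sizes were chosen so each statistical
check retains comfortable power while the whole suite runs in minutes.

# Known limitations

* The event detector is a stand-in for model-based spike inference: it
  preserves the kernel constants and the binarization contract, and its
  equivalence is asserted at the recall/precision level on synthetic
  data, not spike-for-spike.
* The thinning coherence model makes spontaneous CoCS events as coherent
  as evoked ones (see above).
* The synchrony permutation test inherits the discreteness conservatism
  of the strict-percentile rule.
* The mixed model supports exactly one random intercept; no crossed or
  nested random effects, and no Satterthwaite-style degrees of freedom.
* Zone discovery reports spatial purity implicitly (via recovery tests)
  but does not register zones across sessions or animals.
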