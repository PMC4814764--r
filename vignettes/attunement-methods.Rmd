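---
title: "Methods: anisotropic cross-recurrence analysis of coded gesture and speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anisotropic cross-recurrence analysis of coded gesture and speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model implemented by `attune`, the conventions
it fixes where the method leaves room, and what its synthetic-data tests do
and do not establish.

## From coded events to categorical series

The raw material is a table of coded events: per child and stream
(`gesture` or `speech`), a start and end time in seconds, a category label,
and — for events that express task understanding — a skill level on a 1–7
complexity scale. Levels group into three tiers: sensorimotor (1–3),
representational (4–6) and abstract (7). Events such as emblems or short
answers carry no level.

Events are rasterized at 1 Hz: second-bin *t* covers `[t, t+1)` and carries
the level of the event overlapping at least 0.5 s of the bin (the majority
rule); seconds without a leveled event are 0. Conventions fixed here,
because a 1 s sample rate alone does not determine them:

* **Majority rule.** An event claims a bin iff it overlaps it by ≥ 0.5 s.
  This is the least surprising discretization and is exactly reproducible;
  an event shorter than 0.5 s in every bin vanishes from the series.
* **Ties.** Two adjacent events can each cover exactly 0.5 s of one bin;
  the later-starting event wins. Touching boundaries (end of one = start of
  the next) are legal.
* **Unleveled events rasterize to 0** — only leveled behavior can recur.
* Both streams of a child are rasterized to one common duration (the
  smallest whole second covering both streams), so the plot is square.

## The cross-recurrence plot and anisotropic measures

Cell (i, j) compares gesture second *i* (rows) with speech second *j*
(columns) and is recurrent when both display the *same tier*; the cell
stores that tier. Matching is by tier, not by exact level, throughout.

From the plot we compute the recurrence rate `RR` (recurrent cells over all
`n_g × n_s` cells — no-event seconds stay in the denominator, as RR is a
property of the entire plot) and the line measures per orientation:

* a **vertical line** is a maximal run of recurrent cells down one column:
  successive gesture seconds matching one speech second — gestures trapped
  in a tier briefly expressed by speech. Horizontal lines are the mirror.
* `LAM_V`, `LAM_H`: share of recurrent points inside runs of length
  ≥ `min_line`; `TT_V`, `TT_H`: mean length of those runs (0 when none);
  `MaxL_V`, `MaxL_H`: longest run of *any* length ≥ 1 (0 only when the plot
  has no recurrence).

`min_line = 2` for LAM and TT: an isolated point is not a line structure.
MaxL deliberately counts single points — a child whose horizontal structures
are all isolated points reports `LAM_H = 0`, `TT_H = 0`, `MaxL_H = 1`,
which is the only convention consistent with the bundled reference tables.

**Tier restriction.** The sensorimotor and representational analyses zero
out all other tiers and recompute the line measures. Because every second
has exactly one tier, runs are tier-pure, and two normalization identities
hold *exactly* (they are asserted in the tests): tier `%RR` values sum to
100, and tier LAM values sum to the global LAM, because tier LAM keeps the
*full* plot's recurrent-point count as denominator. TT and MaxL within a
tier are computed over that tier's lines only.

**Asymmetry scores.** `V-H_LAM = LAM_V − LAM_H` (proportions compare
directly); `V-H_TT` and `V-H_MaxL` are relative differences
`(V − H)/(V + H)` in [−1, 1]. When both operands are 0 the relative
difference is undefined and reported missing; `x/x` contrasts with one side
0 give ±1.

## The LOS profile

The delay profile scans diagonals within ±`window_s` (default 60 s — leads
and lags up to one minute) of the line of synchrony:
`RR_τ = count(τ) / (n − |τ|)` with `τ = j − i`, so positive delays are
recurrences where the gesture came first. Measures: `%Sync = 100·RR_0`,
`RR_peak = max RR_τ`, `τ_peak = argmax` (ties resolve toward the smallest
|τ|, then the positive delay), and
`Q_LOS = Σ_{τ<0} count(τ) / Σ_{τ>0} count(τ)`.

Declared conventions, where the method's verbal description is ambiguous:

* **Per-diagonal normalization** of RR_τ (each diagonal divided by its own
  length), so a fully recurrent plot has RR_τ = 1 at every delay and the
  profile is not biased toward the LOS.
* **%Sync is 100·RR₀** — the share of LOS cells that are recurrent — chosen
  for consistency with the RR_τ envelope (the alternative reading, LOS
  cells over all recurrent points, is not used).
* **Q_LOS uses raw counts** within the window, excluding τ = 0. An empty
  gesture-leading side leaves Q_LOS undefined (missing); an empty
  speech-leading side gives 0.

**RR_peak screen.** A delay is only meaningful if the peak beats chance.
The null shuffles the order of whole coded episodes of the gesture stream —
a maximal run of one nonzero value together with its trailing zeros —
preserving episode durations, level composition and within-episode
autocorrelation, and recomputes RR_peak; `p = (1 + #{perm ≥ obs})/(1 + B)`.
A per-second shuffle (`second_shuffle`) is available for comparison; it
destroys autocorrelation and is anti-conservative for blocky categorical
series. In the pipeline, children failing the screen at α = 0.05 get
`τ_peak` reported missing.

## Permutation inference

All group-level tests use the *mean difference* as statistic (not a
t-ratio), with nulls matched to the design: label reshuffling for two
groups, within-pair sign flips for paired contrasts, sign flips of centered
deviations against a reference value. p-values use the add-one correction,
so they live in (0, 1] and are reproducible bit-exactly given a seed.
Sidedness is directional where a directional claim is at stake (e.g.
vertical measures expected to exceed horizontal ones) and two-sided for
exploratory contrasts and correlations. Cohen's *d* divides the observed
difference by the pooled (n−1) SD. Correlations are Pearson on complete
pairs (pairwise deletion) with a two-sided permutation p by shuffling one
variable; stars at 0.05/0.01. Rater-agreement checks shuffle one coder's
sequence and compare percentage agreement.

A deliberate consequence of random (rather than exhaustive) permutation with
the add-one correction: an effect whose exact enumeration p is exactly 0.05
(e.g. the most extreme of 20 possible splits) reports ≈ 0.051 at B = 1000.
The tests assert closeness to the enumerated value, not to a significance
verdict.

## The synthetic cohort: a stated world

The generator emulates the statistical structure of the observed sessions,
not the children themselves. One latent sequence of understanding states
drives both streams: geometric dwell times (memoryless, the simplest model
producing the blocky plot texture; a hook is left for other distributions),
each state sensorimotor or representational (`p_tier_R`). Each state is
expressed per stream with probability `p_express_*`, at onset + stream lag +
rounded Gaussian jitter, for a geometric duration with a stream-specific
mean, at a level drawn uniformly within the tier; with probability
`p_mismatch` the episode expresses the other tier. Episode durations are
drawn through a *shared* per-state quantile (comonotonic across streams), so
perfectly symmetric parameters produce literally identical streams — making
the symmetric-construction and lead-recovery properties exact rather than
approximate. Within-stream overlap after jitter is resolved by clipping an
episode's start to the furthest end seen so far.

Defaults are the stated world and are not tuned: 480 s sessions (observed
range 300–720 s), 20 s mean state dwell, gesture episodes 6 s vs speech
3.5 s (the dwell asymmetry that makes TT_V > TT_H), a 6 s gesture lead
(the cohort-level mean delay), 2 s jitter, expression probabilities 0.9/0.8,
10% mismatch. Cohort covariates (age, scores) are linear-plus-noise links to
each child's ground truth; they exist to exercise the correlation stage
only.

What a green synthetic test establishes: the chain recovers imposed leads
exactly without jitter, within ±3 s on average at 2 s jitter; dwell
asymmetry propagates to TT asymmetry; mismatch noise lowers RR; fixed seeds
give byte-identical outputs. What it does not establish: anything about
real coding reliability, about non-geometric dwell distributions, or about
drift of synchrony within a session (the profile is global, not windowed).

## Numerical and reporting choices

* Rasterization comparisons use a 1e−9 tolerance so that exact-0.5 overlaps
  computed in floating point are not lost.
* Report rounding follows the reference-table conventions: proportions 3 dp,
  TT and percentages 1 dp, MaxL whole seconds, Q_LOS and asymmetry scores
  2 dp; a parallel JSON keeps full precision, and the group-mean rows are
  recomputed from the per-child columns, never stored.
* Seeds: every stochastic routine takes an explicit seed; the pipeline
  derives per-child and per-test seeds from the base seed arithmetically
  (all below 2³¹).
* Scenario and configuration files are YAML; reports are CSV + JSON.

## Known limitations

* Diagonal-line CRQA measures (determinism, mean diagonal length) are out of
  scope: categorical skill-level series form block/line structures where
  vertical and horizontal lines carry the asymmetry of interest.
* The per-child values in the bundled reference tables derive from
  unavailable raw recordings; the package recomposes their arithmetic
  (asymmetry scores, means, correlations) but cannot re-derive them from
  video.
* Published Cohen's *d* values were computed from unrounded inputs; from the
  rounded tables they reproduce only qualitatively (same sign, same
  magnitude class), and are treated accordingly in the tests.
* The generator's covariate links are a test harness, not a developmental
  model.
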