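---
title: "Models and methods behind catrains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind catrains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrains)
```

`catrains` implements the downstream statistics applied to deconvolved
calcium event trains recorded with one-photon microendoscopy in motor
cortex: per-cell event descriptors with Wilcoxon/FDR comparisons,
trial-aligned modulation classification, Jaccard-index pairwise coactivation
standardized against a circular-shift null, and permutation-validated
detection of precisely timed multi-cell event sequences. This vignette
explains each model, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic-session
generator does and does not emulate.

## Data model

A *session* bundles four tabular artifacts on one clock (seconds from
recording start):

* **events** — one row per deconvolved calcium event: `cell_id`, `time_s`,
  `amplitude` (a.u.). Event times are continuous doubles; binning to the
  10 Hz frame grid happens only where an analysis demands it, to avoid
  premature rounding.
* **traces** — fluorescence sampled on the frame grid (10 Hz by default),
  wide format, one column per cell.
* **centroids** — spatial cell centroids (`x`, `y`, unit recorded).
* **trials** — behavioral events per trial: preceding inter-trial-interval
  start, target onset, direction, optional movement onset (two-target task),
  success flag.

All segments are half-open `[start, end)`, so splitting a 20-min recording
into two 10-min windows never double-counts a boundary event.

## Event descriptors

For each cell over a segment of duration $D$: the event rate $n/D$, the
coefficient of variation of the inter-event intervals
$\mathrm{CV} = s(\Delta t)/\overline{\Delta t}$ (sample sd, $n-1$
denominator; $\mathrm{CV}=1$ characterizes a homogeneous Poisson train), and
the mean deconvolved event amplitude. The IEI CV is undefined (NA) below
three events; amplitude is undefined for silent cells. Condition contrasts
on the same cells (spontaneous vs task) use the two-sided Wilcoxon
signed-rank test; region contrasts on disjoint cell sets use the Wilcoxon
rank-sum test; families of tests are corrected with Benjamini–Hochberg FDR
(`bh_fdr()`, a thin validated wrapper over the standard step-up
adjustment). Degenerate inputs (all paired differences zero; identical
singleton groups) return $p = 1$ by convention rather than erroring, and
comparisons with fewer than five valid pairs are flagged `underpowered`.

## Trial alignment and modulation classification

For every successful trial, a 3-s epoch of raw trace starting 1 s before
the alignment event (target onset, or movement onset in the two-target
task) is Z-scored per cell against that trial's own baseline: the first
second of the preceding inter-trial interval. With ITIs of 2–3 s this
window always exists; reading "the first second" as the *start* of the
preceding ITI is a choice this package makes explicit, since for ITIs
longer than 2 s the phrase is ambiguous — the alternative (the last second
before target onset) would sit closer to movement preparation.

Event times map to frames by nearest-frame rounding (the 100-ms grid is
coarse; nearest is unbiased). Cell-by-trial combinations with zero baseline
sd are dropped and counted. Note a deliberate property of per-trial
Z-scoring with a 10-frame baseline: under a stationary white-noise trace
the pooled Z-scores are $t$-like, with variance
$(1 + 1/10)\cdot 9/7 \approx 1.41$ (sd $\approx 1.19$), not 1. The
downstream tests are rank-based, so this heavier tail costs nothing, but
Z-score heat maps should be read with that scale in mind.

Modulation is tested per cell and condition by a signed-rank test across
trials contrasting the per-trial mean Z in the event window (0 to +1 s)
with the pre-window (−1 to 0 s), FDR-corrected across *all* cell × condition
tests of the session (the chamber-level family). The classification rule is
purely the significance pattern: zero significant conditions →
`not_modulated`; exactly one → `direction_related`; two or more →
`non_direction_related`. Magnitudes $|\Delta Z|$ (difference of
trial-averaged window means; the per-trial-then-average alternative was
rejected to keep the magnitude aligned with what the heat maps display) are
compared between increasing and decreasing responses by rank-sum and across
directions by Kruskal–Wallis.

## Coactivation: Jaccard and Z-Jaccard

Events are binned at 0.2 s (binary occupancy, not counts; a trailing
partial bin is discarded) and forward-smoothed: bin $t$ becomes 1 if an
event occurred in bins $t$ through $t+4$, so events within 1 s count as
coincident. For cells $c, c'$ with smoothed rows $y^*$,

$$\mathrm{Jaccard}_{c,c'} =
  \frac{\sum_t y^*_{c,t}\, y^*_{c',t}}
       {\sum_t y^*_{c,t} + \sum_t y^*_{c',t} - \sum_t y^*_{c,t}\, y^*_{c',t}}.$$

The null distribution per pair comes from circularly rotating the *second*
cell's smoothed row by a random offset and recomputing the index; rotation
preserves each train's autocorrelation and active-bin count while
destroying cross-train alignment. The observed index is standardized:
$Z = (\mathrm{Jaccard} - \mathrm{mean}_k)/\mathrm{sd}_k$, and a pair is
called synchronized when $|Z| > 1.96$.

Numerical choices:

* Offsets are drawn uniformly from $\{1, \dots, T-1\}$ — the identity
  rotation is excluded, removing a small conservative bias that including
  offset 0 would introduce.
* All $T$ rotated intersection counts are obtained exactly in one FFT
  circular cross-correlation per pair and the sampled offsets are looked
  up; this is bit-identical to rotating and recounting (verified against
  direct rotation in the tests) and makes 1,000 shuffles per pair cheap.
* Rotation is applied to the smoothed row; rotating the raw row and then
  smoothing would differ at the wrap-around boundary.
* Pairs with zero null sd (e.g. a silent cell) have undefined $Z$; they are
  marked invalid and excluded from the synchronized-pair denominator rather
  than assigned $Z = 0$, which is the conservative choice.

The distance–synchrony relation joins each valid pair's $Z$ with the
Euclidean centroid distance and fits a loess smoother (span 1, locally
weighted *linear* regression) over a distance grid; degenerate geometries
(all centroids identical, fewer than five pairs) skip the smoother but keep
the raw table.

## Precisely timed sequences

A sequence is an ordered tuple of distinct cells whose events recur in that
order, each consecutive step within $(0.05, 2]$ s. The strict 0.05-s lower
bound applies to consecutive *events within an occurrence* — its purpose is
to keep near-simultaneous bursts from masquerading as ordered sequences —
and the 2-s cap applies per step, not to the whole motif.

**Counting.** Occurrence counting is greedy, earliest-first, and
event-disjoint: anchor events are scanned in time order; each subsequent
cell contributes its earliest unused event inside the step window of the
previous matched event, backtracking within a chain when a deeper step
cannot complete; a completed occurrence consumes its events. On exhaustive
sweeps over tiny instances (2–3 cells, crowded windows) this greedy count
equals the maximum disjoint-matching count, which the test suite enforces
against a branch-and-bound oracle; the greedy value is nevertheless the
package's *definition* of the count, and the same counter is used for
observed and null data so the comparison is internally consistent.

**Enumeration.** All ordered pairs observed at least once are tabulated;
motifs reaching the minimum repetition count (4) are extended one cell at a
time up to order 5. This downward-closure pruning bounds a combinatorial
space that is intractable verbatim for 100+ cells, and is sound because an
extension's count cannot exceed its prefix's count under the shared
consumption policy.

**Null and significance.** Each motif's null is built from 1,000
replicates in which every member cell *except the anchor* is independently
circularly shifted by a uniform offset in $(0,\;\mathrm{window})$ — the
pairwise phrasing "shift one stream against the other" does not define the
multi-cell case, and shifting all non-anchor cells independently destroys
all cross-cell coupling while preserving each train's structure. A motif is
significant when its observed count is at least 4 *and* strictly exceeds
the empirical 95th-percentile order statistic of its null counts (the order
statistic at $\lceil 0.95 K \rceil$, no interpolation — "more commonly than
seen in 95% of the shuffles"). The repetition filter applies only to the
observed data; null counts are tabulated unfiltered. Significant motifs
that are ordered subsequences of a longer significant motif are flagged
`subsumed` but retained. Recordings longer than the 10-min analysis window
are split into consecutive windows and a trailing remainder is dropped.

Two open points were decided here and are surfaced in the API: motifs use
distinct cells (no A→A steps), and event reuse across occurrences of the
same motif is disallowed (the disjoint-greedy policy), both validated
against the package's own oracle rather than inherited from any reference
implementation.

## The synthetic-session generator

`simulate_session()` is first-class, tested code: it generates the inputs
every downstream stage is validated against, with known planted structure.

* **Background**: independent homogeneous Poisson trains, default
  0.2 events/s per cell — the middle of the sparse 0.01–1 events/s regime
  typical of deconvolved one-photon data. These rates are free parameters
  of the simulation, not values calibrated to any particular recording.
* **Planted synchrony**: a shared Poisson process copied to both members of
  a pair with independent uniform jitter on $[0, 0.2]$ s — one coactivation
  bin, matching the analysis' coincidence scale.
* **Planted sequences**: motif occurrences placed at uniformly drawn start
  times with rejection so occurrences never overlap within a cell, keeping
  ground-truth counts unambiguous; per-step lags must stay inside
  $(0.05, 2]$ s after jitter.
* **Task tuning**: extra Poisson events at rate
  $\mathrm{base} \times (\mathrm{gain} - 1)$ inside a 1-s response window
  after target onset on matching successful trials. The default gain is 10:
  a rest-to-burst transition (0.2 Hz → 2 Hz) typical of movement-related
  motor cortex cells. Much weaker tuning (e.g. gain 3–4 on a 0.2 Hz cell,
  well under one extra event per trial) produces raw signed-rank p-values
  around 0.01–0.03 that do not survive chamber-level FDR at 30 trials per
  condition — a power limit of the test at these rates, not a detection
  defect, and worth remembering when interpreting real sessions.
* **Amplitudes**: i.i.d. log-normal (meanlog 0, sdlog 0.5) — positive and
  right-skewed like deconvolved amplitudes; exact values are free
  parameters.
* **Traces**: each event contributes a single-exponential GCaMP6f-like
  transient ($\tau = 0.5$ s) on the 10 Hz grid plus Gaussian noise
  (sd 0.1 a.u.).
* **Trials**: uniform random direction (3 directions for the one-target
  task, 2 for two-target), ITIs uniform on 2–3 s, a 1-s hold before
  movement onset in the two-target task.

What the generator does **not** emulate: raw movies, optics, motion
artifacts, deconvolution errors (missed/split events), amplitude–rate
correlations, slow nonstationarities (drift, state changes), or correlated
background beyond the planted structure. Passing parameter-recovery tests
therefore demonstrates correctness of the statistics under their own
assumptions — not robustness to extraction artifacts in real data.

The planted-sequence recovery tests use a construction in which the three
motif cells carry only the planted occurrences while the remaining cells
provide background. With background on the motif cells themselves, chance
chains through the 1.95-s step windows add roughly 0.3 expected extra
occurrences per 10-min window, so a motif planted 3 times crosses the
4-repetition filter in about a quarter of runs — a genuine property of the
detector worth knowing, exercised separately in the unit suite.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed and is deterministic
given it; `run_pipeline()` derives per-stage seeds from one global seed and
records them in its JSON manifest alongside parameter echoes and every
exclusion count (dropped trials, flat baselines, invalid pairs, skipped
comparisons) — exclusions are counted and reported, never silent. The test
and acceptance workloads use sessions of 10–20 minutes with 20–42 cells,
1,000 shuffles per null, and 5–20 Monte-Carlo seeds per calibration
quantity; these sizes give Monte-Carlo error comfortably inside the
asserted bounds while keeping a full run to a few minutes.

## Known limitations

* The Z-Jaccard standardization assumes the null Jaccard distribution is
  summarized well by its first two moments; for very sparse cells the
  distribution is discrete and skewed, which is why pairs with degenerate
  nulls are excluded rather than standardized.
* Greedy counting is order-dependent by construction; its equality with
  maximum disjoint matching is verified on small instances, not proven for
  all inputs.
* The classification rule is winner-pattern-based, not a tuning-curve
  model: a cell significant in two directions is "non-directional" even if
  its responses differ greatly in magnitude.
* One-target tasks have no movement-onset event; alignment to movement
  onset is only available for the two-target task.
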