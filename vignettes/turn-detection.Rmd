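---
title: "Detecting alpine-ski turns from boot-mounted gyroscopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alpine-ski turns from boot-mounted gyroscopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skiturn)
```

## The problem and the signal model

In parallel alpine skiing every turn ends with a *turn switch*: the single
instant at which both skis change from the uphill to the downhill set of
edges, operationally the moment the ski surfaces lie flat on the snow.
Segmenting a recording into turns and runs is the prerequisite for any
per-turn analysis (edge angle, symmetry, turn phases), and boot-mounted
inertial sensors are the least intrusive way to obtain it in the field.

`skiturn` works from a single gyroscope axis per boot: the roll (anterior–
posterior) axis, about which edging rotations occur. The processing chain
is:

1. **Resampling.** Each boot stream is linearly interpolated onto a uniform
   grid (default 64 Hz, the nominal transport rate). Gaps longer than
   0.5 s split the recording; filtering across a dropout would fabricate
   signal.
2. **Bilateral mean.** The two boots' roll rates are averaged. Unilateral
   rotations (skating pushes, leg lifts) produce high rates on one boot
   only and are suppressed by the mean; parallel turning survives it.
3. **Decision signal.** The mean is negated (so that positive rotation
   points anterior and a local maximum marks a left-to-right switch) and
   low-passed with a fourth-order zero-lag Butterworth filter at 0.5 Hz.
   Its local extrema are the candidate switch points.
4. **Labeling.** Heuristic rules assign each extremum exactly one of three
   labels: `switch` (a real edge change), `noise` (an artifact *within* a
   turn — the saddle or counter-oscillation a long stable edging phase
   produces), or `eliminated` (an artifact *outside* turning — standing,
   gliding, straight running).
5. **Turns and sequences.** Maximal runs of switches uninterrupted by
   eliminated extrema become seamlessly tiling turns; each interruption
   starts a new numbered turn sequence. A run of `k` switches yields
   `k − 1` turns: the first switch is the entry into the sequence (the
   first edge change out of the fall line), not a counted turn.
6. **Fine tuning.** The 0.5 Hz signal is heavily smoothed, so each switch
   timestamp is re-located at the matching extremum of a 3.0 Hz-filtered
   version of the same signal, searched inside an asymmetric window
   spanning a fraction `p = 0.6` of the gaps to the neighboring switches.

## The labeling rules

Rules run in a fixed order; earlier labels are never overwritten.

* **Rule 1 (switch pairs).** Consecutive extrema with high absolute rate
  (`min_switch_rate`), opposite sign, and a time distance in (0.3 s, 5 s)
  are both switches. The time window brackets physiologically plausible
  turn durations.
* **Rule 2 (within-turn noise).** In a window of four consecutive extrema
  whose outer pair would satisfy rule 1 and whose inner pair is smaller in
  magnitude than both outer values (and not already switches), the inner
  two are noise — the saddle pattern of long turns.
* **Rule 3 (elimination).** Still-unlabeled extrema are eliminated if
  (a) their magnitude is below `low_rate_threshold`; else (b) they repeat
  the sign of the preceding extremum; else (c) the learned two-threshold
  rule fires: value change to the predecessor ≤ θ₁ **and** time gap ≤ θ₂.
* **Rule 4 (stranded extrema).** Iterated to a fixpoint: an unlabeled
  extremum whose existing neighbors are all eliminated-or-unlabeled, at
  least one of them eliminated, is eliminated. At the ends of a recording
  the single existing neighbor decides. The iteration matters: each pass
  can expose new candidates at the edge of an eliminated region.
* **Rule 5.** Whatever remains is a switch.

θ₁ and θ₂ ship as (0.05 rad/s, 1.0 s) and can be re-learned with
`train_elimination_thresholds()`, a cross-validated grid search over the
axis-aligned threshold pair — a depth-2 decision tree restricted to the two
features that discriminate within- from outside-sequence extrema.

### Tunables the method leaves open

Two rate thresholds have no published value and are exposed as
configuration with calibrated defaults:

| parameter | default | units | role |
|---|---|---|---|
| `min_switch_rate` | 0.2 | rad/s | rule-1 "high rotation rate" bound |
| `low_rate_threshold` | 0.1 | rad/s | rule-3a small-oscillation bound |

The defaults were calibrated on simulated corpora such that clean parallel
runs (edging amplitude ≥ 0.5 rad/s) are fully recovered while post-stop
oscillations (≤ 0.05 rad/s) are fully eliminated. They are tunables of this
implementation, not published constants.

Two further choices the source method does not specify, made here and
flagged as interpretation:

* Whether rule 1's rate bound equals rule 3a's. We keep them separate
  (0.2 vs 0.1 rad/s): a single constant either lets weak oscillations pair
  into switches or deletes legitimate low-rate switch candidates.
* Whether rule 4 runs once or to a fixpoint. We iterate to a fixpoint,
  treating not-yet-labeled neighbors as transparent; a single strict pass
  ("both immediate neighbors eliminated") can never clear a pair of
  adjacent unlabeled extrema stranded between eliminated regions.

## Numerical choices

* **"Fourth-order zero-lag"** is realized as a second-order Butterworth
  applied forward and backward — the standard biomechanics reading. Edge
  transients are controlled with odd (point-symmetric) reflection padding
  of at least `3/fc` seconds, which preserves level and slope at the
  boundary; the padding is stripped afterwards. Zero-phase behavior is
  verified in the tests as commutation with time reversal on interior
  samples (the outer quarters retain transients below 10⁻⁵ relative).
* **Plateaus** in the extremum search take their first sample, and runs of
  same-kind extrema are merged keeping the more extreme value, so the
  extremum list strictly alternates max/min — a deterministic tie-break
  the method description omits.
* **Timestamps** are reported at grid resolution (1/64 s ≈ 0.016 s), with
  no sub-sample interpolation: the reference methods this detector is
  validated against are themselves only precise to ±0.03 s.
* **Direction naming.** A decision-signal maximum is a left-to-right
  switch. Whether a turn is named after its opening or closing switch is
  convention; both are exposed (`direction_convention`) and they agree
  whenever signs alternate, which the labeling guarantees.
* **Alternation violations.** A rule-5 switch separated from a neighbor
  switch only by noise can, on noisy data, repeat its neighbor's sign —
  a case the rule set cannot express. `build_turns()` then starts a new
  sequence at the offending switch (exactly what an eliminated extremum
  would do); the strict behavior is available as `alternation = "error"`.
* **Boundary fine-tuning windows.** The first/last switch of a sequence
  has one neighbor only; its search window falls back to the symmetric
  `± p ·` (gap to the existing neighbor). If a refined timestamp would
  break the ordering inside a sequence (overlapping windows), the original
  timestamp is kept for that switch.

## Evaluation

Detected turns are compared to reference turns per run: a detection and a
reference match if their directions agree and their timestamps differ by
less than **half the mean duration of the run's actual turns**; each event
is used at most once. Three metrics follow: the detected/actual count
**ratio**, turn-count **precision** TP/(TP+FP), and **recall** TP/(TP+FN).
`actual` is always derived as TP + FN so the metrics remain mutually
consistent (published tables of this kind occasionally print an
actual-turn column off by a count or two).

Matching is greedy on the smallest time difference by default; a
maximum-cardinality matching (`mode = "optimal"`) is also implemented. The
two provably coincide when reference events are at least a full tolerance
window apart — which tiling turns with a half-mean-duration tolerance
guarantee — and the tests verify both against an exhaustive search.

## What the simulator emulates — and what it does not

`simulate_run()` generates seeded two-boot recordings with exact ground
truth, so the detector can be validated without field data. The roll-rate
model is **pendular edging**: across each switch the edge angle swings from
one extreme to the other, so the roll *rate* is a train of smooth unimodal
bursts of alternating sign peaking at the flat-ski instant — the true
switch time. Long turns hold a stable edge angle mid-turn, so each burst
extends at most `edge_change_halfwidth` (0.8 s) into the adjacent turns and
the remaining mid-turn time is a near-zero plateau.

Emulated phenomenology:

* per-turn duration and peak-rate draws — durations use a shifted
  lognormal (floor 0.4 s) matched to the observed field timing of
  2.97 ± 0.43 s for long carved and 1.04 ± 0.41 s for short carved turns;
  an unbounded normal would produce physically impossible sub-0.5 s turns
  that no filter could preserve;
* per-turn left/right amplitude imbalance (cancelled by the bilateral
  mean);
* mid-turn saddle/counter-oscillations on the stable-edge plateau of long
  turns (amplitude 0.25 rad/s, period 2 s — slow enough to survive the
  0.5 Hz filter, small enough to label as noise rather than switch);
* post-stop oscillations around zero (0.04 rad/s) and straight gliding;
* a bumpy-surface two-tone disturbance in drifted segments, reproducing
  the documented failure mode of slow low-dynamics turns: extra extrema
  between switches finalize sequences early and consecutive turns are
  lost;
* an unsynchronized-leg snowplow mode: independently jittered burst trains
  per leg with a random per-switch sign relation and a dominant yaw
  channel. The bilateral roll mean largely cancels, and roll-axis
  detection fails — deliberately, as it does in the field.

Not emulated: ski–snow interaction or terrain, accelerometer channels,
falls (which are known to produce spurious turns and are a documented
limitation of the detector, not handled here), and rater noise in the
reference timestamps. Passing the simulation tests therefore shows that
the implementation realizes the method faithfully on signals with the
documented morphology; it does not re-establish the field validation.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run simulations of 10–20 turns
per segment, pooling three seeds per style (≈ 45–90 turns per style) for
the recall-ordering check, and enumerate all rule-engine inputs of up to 8
extrema over a 4-value grid against a brute-force oracle. These sizes keep
the whole suite near ten seconds while leaving every decision path
exercised; the duration-distribution check draws 1000 turns.

## Known limitations

* Snowplow steering is outside the design envelope (yaw-dominated,
  unsynchronized legs); the simulator generates it to demonstrate the
  failure, not because the detector handles it.
* Very short turns (≲ 0.6 s) are strongly attenuated by the 0.5 Hz
  decision filter and can drop below the labeling thresholds — the
  documented trade-off of a fixed cut-off frequency.
* Left/right streams are assumed on a common clock; no cross-boot time
  alignment is estimated.
* The first switch of every sequence is a sequence entry, not a counted
  turn; a misdetected sequence start therefore costs one turn, and
  fragmented sequences (heavy noise) lose one turn per fragment.

## A worked example

```{r}
run <- simulate_run(sim_config(seed = 7, segments = list(
  sim_segment("carved_long", n_turns = 8),
  sim_segment("stop", duration = 12),
  sim_segment("carved_short", n_turns = 12)
)))
turns <- detect_turns(run$left, run$right)
sequence_summary(turns)
evaluate_runs(turns, truth_to_reference(run))$pooled
```
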