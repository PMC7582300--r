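---
title: "Quadrant-trajectory detection of ectopic beats in pulse-interval data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrant-trajectory detection of ectopic beats in pulse-interval data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgectopy)
```

## The model

A premature beat (PAC or PVC) produces a short coupling interval followed by
a compensatory pause. In heart-rate terms this is a large upward HR jump
immediately followed by a large downward jump, and in the common ectopy
rhythms (bigeminy, trigeminy, quadrigeminy) it repeats every 2nd, 3rd or 4th
beat. Atrial fibrillation also produces large HR jumps, but without
periodicity. Normal sinus rhythm produces only small jumps (beat-to-beat
variation of roughly 10 BPM or less).

The detector works on one 30-s window of beat-to-beat heart rate at a time.
Each beat triple contributes a point to a difference Poincaré plane,

$$x_n = \mathrm{HR}_{n+1} - \mathrm{HR}_n, \qquad
  y_n = \mathrm{HR}_n - \mathrm{HR}_{n-1},$$

so positive values mean the heart is speeding up. The plane is partitioned
into nine quadrants by the central square $|x| \le w, |y| \le w$ with
$w = 5$ BPM: quadrant 0 (centre), arms 1 ($x > w$), 5 ($y > w$), 6
($x < -w$), 3 ($y < -w$), and corners 7 ($x,y > w$), 2 ($x < -w, y > w$),
4 ($x > w, y < -w$), 8 ($x,y < -w$). The sequence of quadrant indices over
the window is its *trajectory*. Periodic ectopy traces repeating cycles —
`1-2-3` (upward kite, normal-rate ectopy), `6-4-5` (downward kite,
fast-rate), `2-4` (bigeminy) — while AF wanders and NSR stays at 0.

*Vector resemblance* turns "repeating" into a statistic: for every instance
of a pattern we record a vector angle in the Poincaré plane (the included
angle at the middle vertex for 3-point kites; the slope angle of the segment
for 2-point edges) and take the sample standard deviation per pattern kind.
Overlapping trajectories give SDs of a few degrees; AF gives tens of
degrees. Note the angles live on the difference plane, not on beat times:
that is the only reading under which repeated cycles literally overlay.

Two decision rules consume the features. Windows an upstream AF detector
flagged as AF use the first rule: three or more kites with both kite-angle
SDs at or below 10° is ectopy; dispersed kites keep the AF label only if the
zero-quadrant ratio is below 13%, else the window is reclassified NSR; with
fewer than three kites the 50% ratio arbitrates AF vs NSR. Non-AF windows
use the second rule, which adds the bigeminy test (at least 5 `2-4` and 5
`4-2` pairs, slope-angle SDs ≤ 10°) and an interrupted-kite test on the edge
families (`1-2`/`2-3` and `6-4`/`4-5`), and falls back to calling AF when
the ratio is below 50% *or* at least 5 points lie outside the "cross"
(quadrants 0, 1, 3, 5, 6).

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `half_range` | 80 | BPM | plotting field half-width; arm length is `80 − 5 = 75` |
| `zero_half_width` | 5 | BPM | "small change" boundary, closed (`|d| ≤ 5` is small) |
| `std_angle_max` | 10 | degrees | resemblance ceiling for every pattern kind |
| `rzero_af` | 0.13 | ratio | AF-vs-NSR arbiter when kites are present but dispersed |
| `rzero_nsr` | 0.5 | ratio | AF-vs-NSR arbiter when patterns are absent |
| `outside_min_af` | 5 | count | cross-outlier count that reclassifies a non-AF window as AF |
| `min_kites` | 3 | count | kite occurrences needed for the kite branch |
| `min_bigeminy_pairs` | 5 | count | `min(n24, n42)` needed for the bigeminy branch |
| `min_edge_pairs_exclusive` | 3 | count | an edge family participates only with *more than* 3 pairs |
| `min_beats` | 10 | count | windows with fewer beats are UNDETERMINED |

All live in `classifier_config()` and can be loaded from YAML. Threshold
comparisons follow the pseudocode operators (`≤ 10`, `< 0.13`, `< 0.5`,
`≥ 5`, `≥ 3`) even where prose phrasing differs; the pseudocode is taken as
normative. The `min_beats` gate is this package's own addition: a trajectory
with fewer than eight points cannot contain three kites, so the published
rules are vacuous there.

## Numerical choices

* **Orientation.** Which sign convention goes on which axis is
  underdetermined by prose alone; the package uses
  $x = \mathrm{HR}_{n+1}-\mathrm{HR}_n$, $y = \mathrm{HR}_n-\mathrm{HR}_{n-1}$,
  the unique choice (up to joint reflection) under which the slow–fast–ultra-fast
  triple lands in corner 7 and ultra-fast–fast–slow in corner 8, and all ten
  triple permutations land in their stated quadrants.
* **Boundary inclusivity.** The central square is closed: a difference of
  exactly ±5 BPM is "small". This is a documented decision, not an
  established fact; it only matters for data sitting exactly on the
  boundary (the synthetic bigeminy-fast preset is kept strictly inside).
* **Kite matching** is greedy, left-to-right, non-overlapping on exact
  3-symbol matches. Periodic trajectories yield one instance per cycle under
  any sensible overlap rule; for pathological inputs like `1-2-3-2-3` the
  greedy rule reports one instance.
* **Edges** are counted over adjacent point pairs only; the interruption
  patterns (`6-4-2-4-5`) motivating the edge families are adjacency-based.
* **Angle dispersion** is the ordinary linear sample SD (n − 1) on degrees
  in (−180, 180], not a circular SD. Within-pattern angles cluster tightly,
  so wrap-around is a theoretical risk only; a pattern whose angles straddle
  ±180° would be spuriously dispersed and the window would fail the
  resemblance test (a conservative failure mode). Fewer than two angles give
  SD 0 by the degenerate-count convention of the published rules.
* **Degenerate-edge amendment.** As printed, the non-AF rule zeroes the SDs
  of *scarce* edge families, which would label every pattern-free window —
  including pure NSR — as ectopy. The package instead requires at least one
  family with more than 3 pairs to participate; if none qualifies, control
  falls through to the ratio/outlier test. This follows the stated
  "more than 3 pairs" requirement and preserves NSR specificity.
* **Rounding.** Metrics are kept at full precision internally;
  `format_metrics()` rounds half-up to two decimals, the convention of
  printed clinical tables (base R's `round()` rounds half to even).

## The synthetic generator

`rhythm_spec()` states a rhythm at the interval level:

* **NSR**: intervals $60/(\mathrm{HR}_0 + \varepsilon)$,
  $\varepsilon \sim N(0, \sigma)$. The ≤ 10 BPM sinus variation bound is
  read as roughly $3\sigma$, so $\sigma = 3$ BPM is the package's
  "realistic NSR" reference; $\sigma = 1$ BPM models a clean, quiet
  recording.
* **AF**: i.i.d. intervals with HR uniform on
  $[\mathrm{HR}_0 - 30, \mathrm{HR}_0 + 40]$ BPM. AF is characterised here
  only as highly varying and patternless; any broad-dispersion i.i.d. model
  with median zero-quadrant ratio well below 0.5 serves, and no quantitative
  AF interval distribution is claimed.
* **Ectopy**: a periodic cycle of $k$ normal intervals at the base rate, one
  premature interval at $\mathrm{HR}_0 + c$ (coupling rise $c$), one pause
  interval at $\mathrm{HR}_0 - p$ (pause drop $p$), all plus jitter, with
  $k = 0, 1, 2$ for bigeminy, trigeminy, quadrigeminy (ectopic every
  2nd/3rd/4th beat). The deltas encode the quadrant signs: an upward kite
  needs $c > 5, p \le 5$; a downward kite $c \le 5, p > 5$; `2-4` both
  large; all-`0` both small.

The **fast-rate presets** shorten the cycle by one normal interval: at fast
rates the compensatory pause effectively absorbs the next sinus beat, which
is what makes the printed fast-HR trajectories one symbol shorter than their
normal-rate counterparts (`6-4-5` for fast quadrigeminy rather than
`0-6-4-5`). Preset deltas are fixed in the shipped preset table and were
derived by direct enumeration from the quadrant geometry, not fitted.

Because the trajectory is cyclic, the emitted phase depends on which
interval opens the record; preset fidelity is therefore asserted up to a
cyclic rotation of the canonical pattern (the quadrigeminy presets happen to
start exactly on the printed phase).

What the generator does **not** emulate: pulse-morphology changes of ectopic
beats, motion/noise artifacts (only additive Gaussian waveform noise is
available), respiratory sinus arrhythmia, drifting base rates, and the
atypical noise-induced trajectories (`4-2-3`, `5-0-6`) seen in corrupted
recordings. A green synthetic test therefore establishes that the decision
logic is faithful and that the signatures are separable at stated noise
levels — not clinical performance, which depends on peak-detection quality
and artifact screening upstream.

## Test-world choices

The end-to-end recovery test uses 200 windows per class at jitter 1 BPM over
NSR, AF and four ectopy presets (bigeminy normal, trigeminy normal,
quadrigeminy normal, quadrigeminy fast — together covering all three
signature patterns), with ground-truth routing bits standing in for the
out-of-scope upstream AF detector. Bigeminy at fast rates is excluded by
construction: its trajectory is all zeros, indistinguishable from NSR, and
the method cannot detect it — a documented limitation, not a test artifact.
Trigeminy fast duplicates the `2-4` signature already covered.

The threshold-sweep checks use two cohorts. The angle-threshold sweep runs
on the full ectopy cohort at jitter 3 BPM — PPG-derived HR estimation noise
at the upper bound of sinus variation — because that is the regime where the
angle ceiling is load-bearing (at jitter 1 BPM all pattern-angle SDs are
near 1° and any ceiling above 2° behaves identically). There, tightening the
ceiling below 10° costs ectopy accuracy sharply while loosening it to 15–20°
changes little. The ratio/outlier invariance sweep runs on an NSR+AF cohort
at jitter 1 BPM, where those thresholds are the active arbiters; per-class
accuracy moves by less than 5 percentage points across `rzero_nsr` in
[0.3, 0.7] and `outside_min_af` in [1, 15]. Both cohort noise levels were
fixed on these measurement-physiology grounds before the assertions were
written.

## Known limitations

* Fast-rate bigeminy is invisible to the method (trajectory all zeros).
* Sensitivity to sparse ectopy is limited by the three-kite requirement in a
  30-s window; longer windows would help.
* The bundled peak detector is a deterministic stand-in (local maxima above
  an adaptive threshold, 0.25 s refractory period); production use should
  substitute a validated PPG peak detector via the peak-list input path.
* The AF routing stub (`rzero < 0.5`) is non-normative; real deployments
  must supply `prior_labels` from a dedicated AF detector.
* Linear angle SD can overstate dispersion for patterns whose slope angles
  straddle ±180°; see Numerical choices.
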