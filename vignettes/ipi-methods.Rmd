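---
title: "The Integrated Pulmonary Index: model, calibration and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Integrated Pulmonary Index: model, calibration and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipindex)
```

## The problem and the model

Ward-level respiratory monitoring produces four concurrent channels:
end-tidal CO₂ (PetCO₂, mmHg), respiration rate (RR, breaths/min), oxygen
saturation (SpO₂, %) and pulse rate (PR, beats/min). The Integrated
Pulmonary Index condenses them into one 1–10 score so that a single number
(and a single alarm threshold) can stand in for four traces. The model is a
Mamdani fuzzy inference system: it encodes clinical judgment as *if–then*
rules over verbal categories ("RR is Normal", "PetCO₂ is Very High") rather
than as a regression on raw values, which makes every scored sample
explainable by the rules that fired.

The model is deliberately **stateless and non-adaptive**: the score at
second *t* depends only on the four values at second *t*, never on patient
baselines or trends. That keeps device behaviour predictable (no customized
setup, no drift), at the cost of ignoring genuinely informative temporal
structure; trend analysis is left to the consumer of the score.

### Fuzzification

Each channel has a partition of trapezoidal membership functions — {VL, L,
N, H, VH} for PetCO₂ and RR, {L, N, H} for SpO₂ and PR. Trapezoids realize
the intended semantics directly: a plateau where a category holds fully and
linear "gray areas" of partial membership between adjacent categories. The
partitions are **sum-to-one**: adjacent sets share their transition edges,
so at every point of the axis the grades add to exactly 1. This is a
stronger design choice than mere overlap and it matters twice: it makes the
fuzzifier an exact interpolator (no dead zones, no double counting), and it
underlies the monotonicity guarantees discussed below. Inputs outside the
declared axis are clamped to its ends and flagged, never rejected:
streaming computation must survive sensor artifacts such as SpO₂ = 105.

One geometric subtlety: the SpO₂ **High** set is placed with its rise
starting at 100 on an axis declared up to 110. Saturation is physically
bounded at 100 % and supra-normal oxygenation carries no penalty, so the H
set — required by the three-set structure of the partition — never attains
positive grade at measurable values. Placing its transition *inside* the
measurable range would create a zone where the Mamdani `min` cap deflates
rule activations unevenly and the score could tick *upward* as saturation
falls; placing it above 100 makes the score exactly constant on the normal
plateau.

### Rules and inference

The primary rule base is generated from a 5 × 5 matrix of consequent levels
over RR × PetCO₂ label pairs (assuming normal SpO₂), a per-label SpO₂
consequent drop, and two secondary PR rules. Operators are the classical
Mamdani choices: `min` for AND, `max` for OR and aggregation, `min`
(clipping) for implication, centroid of area for defuzzification. The
implication operator is a reconstruction — consistent with `min` for AND —
rather than a transcription, as is the triangular shape of the output sets.

The output universe is [0.5, 10.5] with a symmetric unit-base triangle
centred at each integer level, so the centroid of an unclipped consequent
is exactly its level. Because the supports do not overlap, the aggregate
(pointwise max) equals the sum almost everywhere and the centroid has the
exact closed form

$$\mathrm{IPI}_{raw} \;=\; \frac{\sum_k k\, g(a_k)}{\sum_k g(a_k)},
\qquad g(a) = a(2-a),$$

where $a_k$ is the activation of level $k$ and $g(a)/2$ the area of a unit
triangle clipped at height $a$. We compute this closed form rather than a
grid integration: it is exact, grid-free, and vectorises across millions of
samples (the acceptance grid search evaluates ~2.9 × 10⁷ points). The test
suite checks it against an independent dense trapezoidal integration of the
aggregated curve (step 2 × 10⁻⁵) to within 10⁻⁶ on random activation maps.

Rules whose consequent does not depend on the SpO₂ label are emitted with a
**"don't care"** SpO₂ antecedent rather than as three parallel rules. This
is not cosmetic: with sum-to-one partitions, a label clause on a parameter
that cannot change the outcome still caps the rule's activation at the
transition grade (which dips to 0.5 between labels), and that uneven
deflation can raise the centroid as the input worsens. Dropping the
irrelevant clause removes the artifact at its source.

### The secondary pulse-rate adjustment

PR acts only as a secondary parameter: if PR is **L** while PetCO₂ is
**H/VH** and RR is **H/VH**, one point is subtracted from the computed
score; likewise if PR is **H** while PetCO₂ is **L/VL** and RR is **L/VL**.
We implement the subtraction as a *graded* post-defuzzification step: the
amount subtracted is the fuzzy degree of the compound condition (each
clause the max over its admissible labels, the clauses combined by min, the
two rules by max), floored at scale bottom. At crisp grades this reduces
exactly to "subtract one"; a crisp step function would have introduced
discontinuities into an otherwise continuous pipeline. The two rules are
combined with max rather than sum because their crisp conditions are
mutually exclusive (PR cannot be fully Low and fully High); max keeps the
subtraction bounded by one point in transition zones.

The reported IPI is round-half-up of the adjusted score, clamped to
[1, 10]; the continuous pre-rounding value is exposed alongside it
(`ipi_raw`, plus the subtraction applied).

## Calibration

Published descriptions of this class of index fix the structure (sets,
operators, the secondary PR rules) and a handful of reference behaviours,
but not the numeric breakpoints or the full rule matrix. The shipped
calibration was therefore *fitted by construction* against four anchors —

1. RR 12, PetCO₂ 26, SpO₂ 98, PR 70 → IPI **8** (hypoventilation step);
2. the same sample at SpO₂ 90 → IPI **5** (desaturation step);
3. all-normal vitals → IPI **10**;
4. apneic/hypoxic extreme → IPI **1**;

— plus the structural requirements that all-normal is the unique optimum,
that the score never rises as any single parameter departs its normal
plateau, and that the score is non-increasing as SpO₂ falls with the other
channels held fixed. Normal plateaus follow standard adult and pediatric
vital-sign tables (adult: PetCO₂ 33–43 mmHg, RR 12–20, SpO₂ 93–100 %,
PR 55–100; the three pediatric modes shift RR and PR plateaus upward with
decreasing age, and share the PetCO₂/SpO₂ partitions and rule matrix).

Anchors 1 and 2 pin the geometry tightly. Anchor 1 requires PetCO₂ 26 to be
fully Low and RR 12 fully Normal so that the single rule (N, L) → 8 fires
crisply. Anchor 2 then constrains the SpO₂ L→N transition jointly with the
desaturated consequent: with the transition placed at (85, 93) — low
plateau up to 85 % (the severe-hypoxia boundary), normal from 93 % — SpO₂
90 has μ_N = 0.625, and mixing consequents 8 and 1 through the centroid
gives 5.096, which reports as 5. The SpO₂ drop of 7 levels also sends
all-normal-but-desaturated vitals to 3, i.e. a sustained severe hypoxia
alone reaches the "intervention required" band — which in turn is what
makes the IPI-event detector catch every severe event at thresholds 3–6 in
the end-to-end analysis. Cells already at or below level 3 keep their
consequent under desaturation (`spo2_preserve_max = 3`): ventilatory
collapse cannot be meaningfully worsened by the saturation channel, and
(again because of the min-cap mechanics) letting such cells fade toward a
saturated level-1 target was the one remaining way the centroid could tick
upward as SpO₂ fell.

The full matrix (rows RR, columns PetCO₂, SpO₂ normal):

```{r}
default_rulebase()
```

Every row and column is non-increasing away from the Normal label, which
the loader enforces, along with complete coverage of all label
combinations. The whole calibration (breakpoints, matrix, drop, PR rules)
is loadable from and writable to YAML (`read_calibration()`,
`write_calibration()`); the shipped defaults are also installed as
`extdata/adult-default-calibration.yaml` and the two representations are
tested for equality.

## Event detection and reliability analysis

Events are maximal runs of grid seconds satisfying a condition for at least
a minimum duration, on half-open intervals `[start, end)`:

| kind | condition | min duration |
|---|---|---|
| severe apnea | PetCO₂ = 0 and RR = 0 | 30 s |
| severe hypoxia | SpO₂ ≤ 85 % | 15 s |
| cs apnea | PetCO₂ = 0 and RR = 0 | 15 s |
| cs bradypneic hypoventilation + hypoxia | PetCO₂ > 50, RR < 8, SpO₂ < 90 % | 15 s |
| cs non-bradypneic hypoventilation + hypoxia | PetCO₂ < 30, RR 8–12, SpO₂ < 90 % | 15 s |
| cs hypoxia | SpO₂ < 90 % | 15 s |

Boundary comparisons are implemented exactly as written (≤ 85 inclusive;
< 90, < 8, > 50 strict; 8–12 inclusive both ends), except that zero-flow
readings are tested as `< 1` (mmHg, bpm) on both channels: CSV round-trips
and sensor quantization make exact floating-point zeros unreliable, and the
same argument applies to RR as to PetCO₂. Runs are maximal with **no gap
bridging** — a single interrupted or invalid second splits an event,
because the definitions say "for at least N s" and state no merging rule.
One physiological episode may yield several event kinds (a 40 s apnea is
both severe and clinically significant; hypoventilation with hypoxia also
counts as plain hypoxia) — the epoch analysis counts epochs, so overlap is
harmless. An IPI event at threshold k ∈ [1, 9] is integer IPI ≤ k sustained
≥ 15 s; IPI-event seconds nest across thresholds by construction.

Reliability is evaluated per epoch: 60 s windows overlapping by 15 s
(stride 45 s), starting at 0, trailing partial windows dropped. We read
"overlap of 15 s" literally as overlap (not stride); the alternative
convention is available via the `stride_s` argument. An epoch is clinically
positive if it has any overlap with an event of the chosen class
(containment would discard events clipped at epoch edges that still
represent patient state within the epoch), IPI-positive likewise, pooled
across streams before counting. Epochs overlapping invalid seconds are
excluded and reported. Sensitivity is TP/(TP+FN), specificity TN/(TN+FP); a
zero denominator raises a classed error rather than silently returning 0.
The ROC is the nine threshold points anchored at (0,0) and (1,1),
integrated by the trapezoidal rule; by event nesting, sensitivity is
non-decreasing and specificity non-increasing in the threshold. A
label-permutation null (`permutation_null_auc()`) serves as the negative
control: shuffling epoch labels must centre the AUC on 0.5.

## The synthetic generator

`generate_vitals()` emulates the threshold semantics of continuous ward
recordings, not their physiology. Channels are Gaussian noise around
baselines sitting inside the mode's normal plateaus (SDs: PetCO₂ 1.5 mmHg,
RR 0.8 /min, SpO₂ 0.6 %, PR 2.0 /min — small enough that baseline seconds
never cross an event threshold, so ground truth is unambiguous), clamped to
physical ranges. Scripted episodes override channels into bands that
satisfy their defining condition with margin (e.g. apnea sets PetCO₂ and RR
to exactly 0; non-bradypneic hypoventilation confines PetCO₂ to [21, 28],
RR to [9, 11], SpO₂ to [86.5, 88.5]). Episodes are flanked by linear ramps,
but the ramps interpolate from baseline only to a *condition-safe boundary
value* (e.g. SpO₂ 91 %) and the signal then steps into the episode band at
onset: this guarantees that each ground-truth interval equals the maximal
run the detector should report, second for second, which the tests exploit
by asserting set equality between detector output and ground truth. Ramp
seconds are excluded from ground truth. A single scenario seed drives one
RNG substream per channel, so changing one channel's script never perturbs
another's noise; identical seeds give bit-identical streams.

What the generator does **not** emulate — and hence what passing tests do
not show about clinical data: SpO₂ lag behind ventilation changes,
cardiorespiratory coupling, motion/cannula artifacts, gradual drifts, or
events that hover at condition boundaries. Detector correctness at the
boundaries is instead covered by constructed boundary streams (SpO₂ exactly
85 vs 90, 14 s vs 15 s durations) and by brute-force oracle equivalence on
randomized streams.

`standard_benchmark()` fixes the study conditions for end-to-end checks: 20
streams × 30 min (36,000 s), four event-free controls, sixteen streams with
three scripted episodes each cycling through all five kinds (apnea
durations alternating 40/20 s so both severity classes occur; other
episodes 30–40 s), 5 s ramps, census recorded in a manifest. On this
benchmark severe-event sensitivity is 1.0 at IPI thresholds 3–6 — the
desk-scale property standing in for the clinical finding that severe events
are essentially never missed — and the permutation-null AUC is 0.5 within
0.02. The clinical headline numbers (AUC ≈ 0.98–0.995, sensitivity 0.83,
specificity 0.96 at threshold 3 for clinically significant events) are
**not** reproducible here: they are properties of a 523-patient clinical
database that is not publicly available, and this package makes no claim
about them beyond implementing the same analysis machinery.

## Numerical choices and problem sizes

- Closed-form centroid (exact); test oracle: dense trapezoidal integration
  at step 2 × 10⁻⁵, agreement 10⁻⁶ over 100 random activation maps.
- Partition sum-to-one verified to 10⁻⁹ on 10⁴ random inputs per axis.
- Round-half-up (`floor(x + 0.5)`) for the reported integer; base R's
  banker's rounding would map 4.5 to 4.
- Continuity: perturbing any input by 10⁻⁶ moves the raw score by < 10⁻³
  (checked over random states).
- Resampling to the 1 Hz grid is nearest-neighbour with 1 s tolerance;
  grid seconds without a sample within tolerance become gaps. Ties pick
  the earlier sample.
- Monotonicity suites: SpO₂ sweeps 100 → 70 at step 0.5 on random fixed
  (PetCO₂, RR, PR) triples; single-parameter departures from all-normal at
  step 0.25–0.5; scale bounds verified on a unit-step grid of 28,839,641
  points (and on 10⁵ random inputs per age mode).
- Detector equivalence: brute-force window scanner (every (start,
  duration) window, cumulative-sum condition check, maximality by
  non-extendability) on 200 random 600 s streams plus 30 in the unit
  suite.
- The benchmark-based analyses use the 20 × 1800 s census above with 100
  label permutations for the null.

These sizes were chosen so the entire suite exercises every property at
full strength while remaining comfortably interactive on a single CPU.

## Known limitations

- The calibration reproduces anchor behaviours and monotone structure, not
  a device's exact breakpoints; different legible-cell choices could yield
  different but equally admissible matrices. The config file makes the
  calibration replaceable wholesale.
- Infant (< 1 y) scoring is intentionally undefined; parameter norms there
  depend on weight and gestational age.
- No artifact rejection: a dislodged sampling cannula is indistinguishable
  from true apnea at this layer, so detected events assume an intact,
  accurately sampled signal.
- No alarm-management layer (delays, re-triggering, auditory fatigue
  modelling) and no temporal smoothing of the score.
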