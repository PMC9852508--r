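---
title: "Width-profile morphometry: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Width-profile morphometry: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labiometry)
```

## The measurement model

A subject is represented by two ordered polylines — the digitized free
edges of the left and right labia minora — and two landmark points, the
anterior and posterior ends of the vaginal vestibule. The segment joining
those two points is the measurement axis. Its length is divided by ten to
give the subject's *unit*; all widths are reported as multiples of this
unit (axis-tenth units), which is what makes the method scale-free: two
photographs of the same vulva at different magnifications, rotations or
offsets produce identical profiles.

Measurement proceeds in three steps:

1. **Axis frame.** A rigid transform maps the anterior landmark to the
   origin and the posterior landmark to `(0, length)`, so the axis runs
   along +y. The anatomical left contour must have negative mean x and the
   right positive; if the labels and the signs disagree consistently (a
   mirrored photograph) the frame is reflected, and if both contours fall
   on the same side the subject is rejected loudly rather than guessed at.
2. **Plumb lines.** At each axial position `k·unit`, `k = 1..9`, the
   horizontal line is intersected with the contour polyline, interpolating
   linearly between digitized vertices. Where the line crosses the contour
   more than once (a lobulated edge), the outermost crossing is taken: the
   quantity of interest is the distance from the axis to the free edge.
   Where the contour does not span the plumb line at all — short labia
   need not reach the vestibule's ends — the width is recorded as a true 0
   and the segment is QC-flagged, so downstream consumers can filter but
   means are not biased by silent exclusion.
3. **Normalization.** Each distance is divided by the unit, giving
   `L1..L9` and `R1..R9` with `L1`/`R1` anterior-most. The anterior-first
   ordering is a convention this package fixes explicitly (the zones
   anterior = 1–3, middle = 4–6, posterior = 7–9 depend on it).

Coordinates are treated as continuous reals throughout — no pixel
rounding — and interpolation is piecewise-linear, matching how outlines
are actually digitized; no smoothness beyond the polyline is assumed.

## Derived features

*Adjacent ratios* `v_n / v_{n+1}` (n = 1..8, both sides) encode the width
trend. A zero denominator yields an `NA` marker that propagates through
averaging (with a reported skip count) instead of raising, because zero
widths are legitimate measurements. All eight ratios are computed per
side.

*Prominence* is the argmax of the 18 widths, mapped to its third of the
axis. Ties are resolved deterministically: lowest segment index first,
left before right at equal index. The rule is arbitrary but must be fixed
for reproducible tallies; it biases ties anteriorly, consistent with the
anterior-first presentation of the zones.

*Asymmetry* is the signed per-segment difference `L_k − R_k` with the
mean absolute difference as a scalar summary — the simplest summary that
is zero iff the profile is mirror-symmetric.

*Golden-ratio index* is the quotient posterior/anterior labial distance.
The two distances are accepted as explicit inputs rather than derived
from the profile: their definition is a separate linear measurement on
the subject, and no derivation from `L1..L9`/`R1..R9` reproduces the
reference values, so the package deliberately does not guess one.

## Cohort aggregation

Per-segment means are arithmetic means over subjects, QC-flagged zeros
included (they are measurements, not missing data; a filter flag lets the
analyst exclude them deliberately). Two ratio tables are kept side by
side: the ratio of means and the mean of per-subject ratios. They answer
different questions and differ whenever profiles vary across subjects
(Jensen's gap); conflating them is a common error the API makes hard.

The average shape is reconstructed by inverting the measurement: the
closed polygon `(0,0) → (−meanL1, 1) → … → (−meanL9, 9) → (0,10) →
(meanR9, 9) → … → (meanR1, 1) → (0,0)`, stored as 21 rows (20 distinct
vertices plus the closing repeat). Re-measuring this polygon with the
plumb-line operator returns the input means to 1e-9 — the package's
central round-trip invariant, tested together with its rendering
counterpart `profiles_to_contours()`.

## The comparison protocol

Strata are compared segment by segment with two-sample t-tests, preceded
by Levene's test for equality of variances. The gate rule is: Levene
p ≥ α ⇒ pooled-variance Student t; p < α ⇒ Welch t. The source workflow
states the gate but not its consequence; pooled-vs-Welch switching is the
standard reading and is what this package implements, with the decision
recorded per segment in the output (`test_variant`). Classic Levene
(mean-centred deviations) is the default because that is the test named;
the median-centred Brown–Forsythe variant is available via `center =
"median"`. Tests are two-sided (no directional hypothesis), α defaults
to 0.05, and **no multiple-testing correction** is applied across the 18
segments or group pairs — matching the protocol being emulated. Every
comparison CSV carries a header caveat to that effect; with 18 uncorrected
tests, roughly one spuriously significant segment per pair is expected
under the null, which the calibration test quantifies.

Grouping schemes are fixed by the protocol: age 18–30 / 31–40 / 41–50 /
≥51 (groups A–D, age 30 in A, 31 in B), parity 0 / 1 / ≥2 (1–3), and
labiaplasty planned yes/no (I/II). Subjects younger than 18 are outside
the protocol and are excluded with a warning rather than binned.

## The synthetic-data generator

`generate_cohort()` draws, per subject: age uniform over 18–70; births
from {0, 1, 2, 3} with probabilities 0.6075 / 0.2475 / 0.0725 / 0.0725
(so P(births ≥ 2) = 0.145); a labiaplasty flag with probability 0.5575 —
the demographic mix of the reference cohort. Each side's 9 widths are a
multivariate normal draw centred on the side's mean vector with
covariance `sd² · ρ^|i−j|`, truncated at zero. Defaults: the reference
means, `sd = 0.5`, `ρ = 0.5`.

Choices and what they mean:

- **AR(1) correlation** expresses that adjacent widths on a smooth edge
  co-vary; no published covariance exists, so a one-parameter structure
  that decays with segment distance is the most parsimonious choice.
  ρ = 0.5 gives visually plausible contours (neighbouring widths share
  half their variance) without degenerating into parallel offsets.
- **sd = 0.5 axis-tenth units** puts the coefficient of variation at
  15–50% across segments and keeps zero-truncation rare (the smallest
  reference mean, 0.941, sits ~1.9 sd above zero). Published data include
  only means, so this magnitude — like the left–right `asym_sd` and the
  covariate effect sizes, which default to 0 — is a placeholder the
  analyst should treat as configurable, not as an empirical estimate.
- **Truncation at zero** keeps widths physical. It biases means upward by
  less than 0.006 units at the default sd (largest for the smallest
  segments), which is an order of magnitude below the sampling error of a
  400-subject mean; tests use bounds that absorb it.
- **Covariate effects** enter additively on all 18 segments: an age slope
  in units per decade centred on the midpoint of the age range, three
  parity offsets, and a labiaplasty offset. With all defaults at 0 the
  generator is a null model — stratified comparisons on it calibrate the
  protocol's type-I error.

What the generator does *not* emulate: digitization noise along real
photographed edges (only optional tangential vertex jitter in the
renderer), lobulated multi-crossing contours, missing segments / short
labia, demographic correlation between age and parity, and any realistic
asymmetry structure. Passing tests therefore demonstrate the pipeline's
internal correctness and calibration under a plausible null — not that
real labial contours satisfy the AR(1)-normal model.

## Numerical choices and degenerate inputs

- Coincident axis endpoints, contours with fewer than 2 points, negative
  widths and non-positive golden-ratio distances raise immediate errors
  naming the subject where possible.
- An all-zero profile has no prominence zone (`NA`), and a zero
  denominator makes the affected ratio `NA`; both propagate rather than
  raise, and aggregation reports how many entries were skipped.
- `levene_test` returns W = 0, p = 1 when both samples have zero spread
  (the equal-variance limit of the F statistic's 0/0).
- Rounding is applied only at reporting boundaries (3 decimals by
  default, 2 for percentages); all internal computation is full
  precision.
- The generator restores the caller's RNG state, so simulation calls do
  not perturb surrounding stochastic code; determinism is per-seed.

## Test problem sizes

The suite validates round trips on 100 random profiles (1e-6), rigid and
scale invariance on randomized transforms (1e-9), the statistical
stack against textbook-formula oracles (1e-10), generator moment recovery
at n = 400 and correlation structure at n = 10⁴, and type-I calibration
of the Levene-gated protocol with 1000 replicate null comparisons of 100
vs 100 subjects, requiring every segment's rejection count to lie in the
exact binomial 99% interval around 0.05. These sizes make the full suite
run in about two minutes on one CPU while leaving the Monte-Carlo checks
sharp enough to catch calibration errors of a couple of percentage
points.

## Known limitations

- The method is deliberately unit-free, so it cannot express absolute
  criteria (e.g. millimetre-based hypertrophy thresholds); no aesthetic
  scoring or diagnosis is attempted.
- Inputs are digitized landmark coordinates; image segmentation is out of
  scope.
- The uncorrected 18-fold testing protocol is reproduced as specified;
  analysts wanting family-wise control should apply their own correction
  to the emitted p-values.
- Covariate modelling is limited to the stratified pairwise protocol; no
  regression of shape on age or parity is provided.
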