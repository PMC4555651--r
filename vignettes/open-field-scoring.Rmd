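---
title: "Scoring open-field behaviour of hemiparkinsonian rats and testing drug synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring open-field behaviour of hemiparkinsonian rats and testing drug synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratfield)
```

## The assay and the measurement model

Rats with a unilateral 6-OHDA lesion of the medial forebrain bundle are a
standard model of hemiparkinsonism: dopaminergic drugs drive them to rotate
away from the lesioned side (contraversive turns), while non-dopaminergic
treatments can restore locomotion without stereotyped circling.  The assay
implemented here places a treated animal in a 50 x 40 cm open field filmed
from below, tracks three body points (nose, centre, tail) at 25 Hz for a
55-minute session, and condenses each session into five scalar metrics:

* **Distance** (cm): total centre-point path length over gate-accepted
  steps.  A step is accepted when the centre has moved at least 1 cm since
  the last accepted sample (the "Minimal Distance Moved" gate), so
  stationary tracking jitter accumulates no distance.
* **Ipsi / Contra turns**: the number of full 360-degree rotations of the
  body axis (nose direction relative to the centre) toward and away from
  the lesioned side.  The unwrapped body-axis angle feeds a signed
  accumulator; each crossing of +/-360 degrees counts one turn, and the
  accumulator is zeroed after more than 45 degrees of opposite-direction
  accumulation so a meandering walk cannot slowly bank partial turns.
  With a right-side lesion viewed from below, counter-clockwise image
  rotation is ipsiversive; both the lesion side and the camera view are
  explicit parameters because each flips the label mapping.
* **Stretched time** (s): time spent with body elongation (nose-tail
  extent over a reference length, clipped to `[0, 1]`) at or above 0.70 —
  a quadrupedal, non-bent trunk posture.  Dyskinetic dopaminergic
  stimulation produces a bent trunk (low elongation) during rotation.
* **Space occupancy** (cm): the mean gyration radius.  The session is cut
  into 10-s bins (250 samples); in each bin the mean distance of the
  centre positions from their bin centroid is taken, and the bin radii are
  averaged over the observation window.  Tight stereotyped circling gives
  a small radius, roaming exploration a large one.

The statistical layer reproduces the factorial synergy analysis used with
this assay: each metric is analysed by a 2 x 4 between-group ANOVA
(Tozadenant 0/30 mg/kg by Radiprodil 0/1/2/3 mg/kg, n = 8 per cell).  A
significant interaction term at alpha = 0.05 classifies the two drugs'
joint action as *synergistic*, a non-significant one as *additive*.
Variance homogeneity is checked with Levene's test; when it fails, a
Box-Cox profile likelihood chooses between a square-root and a log
transformation.  Tukey's HSD compares all 28 pairs of the eight cell
means, and Student's pooled t-tests compare the L-Dopa comparator
regimens.

## Body-axis angle rather than movement heading

The turn counter works on the nose-relative-to-centre angle, not on the
movement heading.  At low speed the heading is dominated by tracking
noise, while the three-point body axis stays well defined; the angle is
simply skipped for the rare frames where nose and centre coincide.  The
same 1-cm gate that protects the distance metric decides which frames
enter the angle sequence, so both metrics share one definition of "the
animal actually moved".  Applying the gate to distance as well as turns is
an extension of the published 1-cm constant, documented here as the
package's choice: it suppresses jitter inflation of path length.

## Elongation reference

The tracker's normalisation for body elongation is not published.  By
default the reference length is the 95th percentile of the session's own
nose-tail distances, which is robust to outlier frames and adapts to each
animal's size; a fixed reference length can be supplied instead when
cross-animal comparability matters (the simulator tests use the known
synthetic body length, 20 cm).  The nose-tail chord is used; the
nose-centre-tail arc length is available as a configuration alternative.

## Quality control

Frames with missing coordinates or points outside the arena box (plus a
0.5 cm overshoot margin) are invalid.  Gaps of at most 12 frames (about
0.5 s) bracketed by valid frames are linearly interpolated and flagged;
longer gaps stay invalid and contribute to no metric: the gate re-anchors
after a gap, so no distance or rotation is accumulated across it.
Sessions with 10% or more invalid frames are refused; gyration bins with
fewer than 80% valid samples are excluded rather than renormalised, which
would bias the bin radius downward.  These thresholds are declared QC
policy, not a reconstruction of the commercial tracker's undocumented
filtering.

## The synthetic cohort generator

No tracking data from the original study are deposited, so the package
ships a generative stand-in.  Behaviour is a continuous-time Markov state
machine over five states — rest, straight walk, counter-clockwise circle,
clockwise circle, wall follow — with exponential dwell times: the
simplest structure that can realise every phenotype contrast of interest.
The centre follows the active state's kinematics (correlated random walk
when walking, constant-radius arc when circling) and is reflected off the
walls; nose and tail sit on the body axis at 9 and 11 cm scaled by the
bout's elongation draw, plus isotropic jitter (0.15 cm), and are clamped
into the arena box, as a tracker would report a nose pressed against the
wall.

The built-in phenotypes encode the treatment profiles qualitatively:
`vehicle` rests most of the session; `ldopa_ben_like` circles
contraversively almost continuously (60 deg/s, 4.5 cm radius) with a bent
trunk; `ldopa25_like` mixes circling and walking with a straighter trunk;
`mono_like` walks moderately with mild contraversive bias; `combo_like`
explores fast and straight with a stretched posture.  These parameter sets
were fixed once, from the qualitative descriptions of the phenotypes, and
are the package's study conditions.  The generator reproduces the
*directional* contrasts (circling asymmetry, space occupancy, posture,
distance orderings); it does not model within-session pharmacokinetics,
habituation, or any quantitative fit to real animals, so passing tests
demonstrate correctness of the measurement and statistics pipeline, not
biological realism of absolute values.

### Factorial effect injection

`simulate_cohort()` injects drug effects at the phenotype-parameter
level, never directly on metric values, so the whole scoring path is
exercised: a distance target sets the walking speed (distance is linear
in speed, preserving additive structure), turn targets set circling-state
occupancy and direction bias, and a stretched-time target sets a per-bout
Bernoulli stretched/bent posture mixture.  Space occupancy is emergent
from the kinematics and cannot be mean-targeted; asking for it is an
error.  The cohort generator uses a low-jitter tracking model (0.05 cm)
so that injected cell means stay identifiable in the scored metrics.

The `interaction` field of an `effect_model()` is defined as the
sum-to-zero interaction coefficient of the combination cell (Tozadenant
30 with the highest Radiprodil dose): the single-cell synergy bump is
projected onto the pure-interaction space and rescaled so the
combination-cell coefficient equals the stated value, leaving both
factors' marginal means untouched.  Under this definition a
one-residual-sd interaction with n = 8 per cell has a noncentrality of
about 21 for the F(3, 56) interaction test, i.e. power well above one
half, while the type-I rate under an additive model stays at alpha.

Reproducibility follows a single master seed: per-animal substreams are
drawn once from it, so cohorts are bit-for-bit reproducible and animals
are uncoupled.

## Numerical choices and problem sizes

* Turn accumulator reset tolerance: 45 degrees of opposite accumulation,
  a declared constant exposed in `turn_params()`.
* Box-Cox decision boundaries: lambda below 0.25 selects log (with a +1
  offset when zeros are present), 0.25-0.75 selects square root,
  otherwise no transform.  The named procedure's cutoffs are not
  published; these are the package's.
* Type II sums of squares, so unbalanced data (after QC exclusions)
  remain interpretable; identical to the classical decomposition when
  balanced.  Degrees of freedom are always whatever the supplied data
  imply.
* Tukey comparisons run on the transformed scale whenever a transform was
  selected; cell means are back-transformed for display only, so
  inference and multiplicity live on a single scale.
* Monte-Carlo calibration of the interaction test (type-I rate and power)
  uses 200 replicate cohorts of 64 sessions at 240 s per session; session
  length only rescales the distance metric, not the additivity structure
  under test.  Analytic-limit checks use 60-600 s sessions.

## Known limitations

* The five metrics are implemented as published; the original selection
  procedure (decorrelation screening over a larger candidate set) is not
  reproduced.
* The simulator's wall interactions clamp the nose into the arena, which
  shortens the apparent body chord during wall contact; posture-recovery
  checks therefore use either the realised chord or a short-bodied
  configuration.
* Comparator regimens are simulated only through their default
  phenotypes; no dose-response model links them to the factorial cells.
* Reported group means and F statistics from the original animal data are
  not reproducible from synthetic cohorts, and the package does not
  attempt to match them numerically; every quantitative claim in this
  vignette is recomputed by the test suite or the acceptance script.

## A short worked example

```{r example, eval = FALSE}
spec <- cohort_spec(
  effects = list(distance_cm = effect_model(2500, toz = 400,
                                            rad = c(150, 300, 450),
                                            interaction = 750, sd = 250)),
  n_per_cell = 8, duration = 240, seed = 1, include_comparators = TRUE)
sim <- simulate_cohort(spec)
summaries <- score_cohort(sim$trajectories, sim$cohort)
tab <- metric_table(summaries, sim$cohort)
report <- synergy_report(tab)
report
```
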