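---
title: "Joint-attention eye-tracking: models, measures and the calibrated simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-attention eye-tracking: models, measures and the calibrated simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jagaze)
library(dplyr)
```

## The problem

Joint attention — coordinating one's visual attention with a partner toward
an object — has two dimensions: *responding* (following the partner's gaze
cue) and *initiating* (directing the partner's attention by alternating gaze
between an object and the partner's face). Screen-based eye tracking turns
both into measurable gaze events: toddlers watch short videos of a model
seated between objects, and their 120 Hz binocular gaze stream is reduced to
fixations, area-of-interest (AOI) labels and AOI-to-AOI transitions.

`jagaze` implements that reduction end to end for a three-task design:

* **RJA** (responding): the model turns her head toward one of two objects;
  joint-attention (JA) segment of 4 s.
* **IJA-1** (initiating, predictable): one of two toy cars starts moving
  while the model keeps a neutral direct gaze; JA segment of 7 s.
* **IJA-2** (initiating, unexpected): a toy truck crosses the scene; JA
  segment of 7 s.

Every trial has three contiguous phases — looking-down (2 s), interaction
(2 s), joint attention (4 or 7 s) — preceded by an attention-getter that
re-centres gaze. Four trials per task run in fixed block order
(RJA, IJA-1, IJA-2), twelve trials in all.

## Event layer

**Fixation detection** is dispersion-based (I-DT): maximal windows of valid
samples whose bounding-box dispersion (width + height, in degrees of visual
angle) stays within 1.0° and whose duration reaches at least 60 ms. The
60 ms floor removes short "unconscious" looks before anything else is
computed; the 1.0° ceiling matches the nominal accuracy of remote infant
eye trackers. Invalid spans (blinks, tracking loss) up to 75 ms inside a
window are bridged — roughly a blink-artefact scale at 120 Hz — and longer
ones terminate it. Dispersion is monotone in the window end, so the greedy
maximal extension is well defined and cheap; the test suite holds the
implementation to an exhaustive maximal-window search on random streams.
The duration threshold is applied before AOI assignment.

**AOI labelling** assigns each fixation the rectangle containing its
centroid, with half-open bounds so shared edges are unambiguous. Per trial
the roles are `face`, `target` (the cued or moving object; the side varies
by trial) and `non_target`; IJA-2 has a single object region.

**Transitions** are consecutive pairs of AOI-labelled fixations with
differing labels. Fixations on empty screen (`none`) are transparent:
gaze travelling across background between two AOIs still yields one
transition. The alternative — breaking the chain at every off-AOI
fixation — would undercount all transition types, since scan paths
routinely traverse empty screen between regions. Consecutive same-AOI
fixations contribute nothing.

**First look** is the AOI of the first JA-phase fixation landing on either
object; face fixations before it are ignored (the face is the interaction
anchor, not an object). Trials with no object look are `neither` and drop
out of accuracy denominators.

## Trials and exclusions

Fixations are assigned to the trial and phase holding the majority of
their duration, ties to the earlier phase — a deterministic, order-free
rule for boundary-straddling fixations. Two exclusion criteria apply, the
first checked first:

1. *No face look during the interaction phase* — operationalised as no
   face-AOI fixation (i.e. no >= 60 ms dwell), since the fixation is the
   atomic unit of every other measure.
2. *Looking away from the screen for the whole JA phase* — no detected
   fixation with an on-screen centroid in that phase. Whether "away"
   means invalid tracking or off-screen gaze is not distinguishable
   downstream of event detection, so both count.

## Participant measures

With `a` and `b` the relevant counts, every normalized score is
`(a - b) / (a + b)`, in [-1, 1], undefined (missing) when `a + b = 0`:

* **Normalized accuracy**: first looks on target vs non-target, over
  trials with an object look.
* **Normalized transition score**, RJA form: face-to-target vs
  face-to-non-target transition totals. IJA-1 form: target-to-face vs
  non-target-to-face. Note the denominator: at a fixed absolute
  imbalance, more transitions mean a smaller score.

Transition counts are totalled over usable trials; per-trial means divide
by the participant's usable-trial count for that task. Between-object
transitions pool both directions. Fixation-duration percentages (FD%)
divide the JA-phase fixation time on one AOI by *all* JA-phase fixation
time, including fixations on empty screen — "on-trial fixation time"
reads most naturally as total fixation time, not AOI-restricted time
(the restricted variant would only rescale all AOI shares by a common
factor per participant). Conditional FD% recomputes the same share on
the subset of trials with a congruent (target) first look.

Undefined scores propagate as missing values into the statistics — the
participant drops out of that comparison. A zero is a meaningful score;
absence of evidence is not imputed as zero.

## Statistical layer

Group comparisons adjust for nonverbal developmental level (the groups
differ on it), fitting `dv ~ group + covariate` and testing the group term
with a drop-term (Type III) F — with one two-level factor and one
covariate this equals the SPSS default. Effect size is partial eta
squared, `SS_group / (SS_group + SS_residual)` (0.01/0.06/0.14 as the
conventional small/medium/large bands). A Shapiro-Wilk gate per group at
alpha = 0.05 decides between the parametric fit and the **rank ANCOVA**
(Conover-Iman style): dependent variable and covariate replaced by pooled
midranks, same linear model on the ranks. An all-tied variable has zero
rank variance and returns F = 0 by convention. Levene's test
(mean-centred) accompanies every comparison.

Multiplicity is handled by Benjamini-Hochberg FDR at q = 0.05. The family
is the set of variables tested within one task (a `global` option exists);
the per-task default reflects that each task asks a separate scientific
question. Correlations are Pearson when both variables pass the normality
gate, Spearman otherwise. Trial attrition is checked with a two-way
repeated-measures ANOVA (task within, group between) on usable-trial
counts.

## The synthetic-gaze generator

Because no recordings ship with the package, a generator produces 120 Hz
recordings with the statistical structure the analysis assumes, and the
whole pipeline is validated by recovery against the generator's ground
truth.

The JA segment follows a **semi-Markov process**: an embedded Markov chain
over AOI states (plus optional `elsewhere`/`offscreen`) with zero diagonal,
and log-normal dwell times truncated to the remaining segment time (the
final dwell is capped, so segment lengths are exact). Dwell-level control
is what makes calibration closed-form: fixation durations, not samples,
are the unit of analysis. Log-normal dwells are positive and right-skewed,
matching the fixation-duration literature; the coefficient of variation
defaults to 0.25 so that sub-threshold (< 60 ms) dwells are vanishingly
rare and every generated dwell maps to exactly one detected fixation.
Samples within a dwell are the AOI centroid plus isotropic Gaussian jitter
(default sd 2 px, about 0.06°, far inside the 1° dispersion ceiling).
The looking-down segment is a single off-AOI dwell; the interaction
segment is a short off-AOI lead-in, a face dwell, and a short off-AOI
tail that keeps the face dwell clear of the JA boundary (otherwise a
face-initial JA segment would merge across the phase edge). Attrition is
trial-level: with probability `p_skip_face_interactive` the interaction
contains no face look (criterion 1 fires), with `p_away_whole_ja` the JA
segment is entirely off-screen, emitted as invalid samples (criterion 2).

### Expected transition counts in closed form

For a chain over AOI states with common dwell distribution, the expected
number of a→b transitions in a segment of length `D` is

```
E[count(a -> b)] = sum_k P(S_k < D) * P(X_k = a) * P_ab
```

where `S_k` is the sum of `k` dwells and `X_k` the k-th chain state.
`P(S_k < D)` is computed by a discretised renewal convolution of the
log-normal dwell distribution (2 ms grid; the grid rounds dwell sums up
by at most one step, a bias well under 1%). When the chain starts from
its stationary distribution the occupancy term is constant and the sum
collapses to `E[pairs] * pi_a * P_ab`.

### Calibration to the published group rates

`calibrated_presets()` inverts this relation. For each group x task a
table of target per-trial expected counts is fixed (see below), the chain
is read off directly — `P_ab` as row-normalised targets, the stationary
start as the normalised outflows — and the common dwell mean is solved by
`uniroot` so the expected number of dwell pairs matches the target total.
Published transition tables are per-participant group means; here they are
interpreted as **per-trial** means (totals divided by usable trials), the
reading under which a four-trial task and the reported magnitudes are
mutually consistent.

Choices in the target tables, made once:

* **RJA**: the two groups use one identical preset (no group differences
  were reported there); each entry is the mean of the two published group
  values, and small between-object rates (0.3 each way) close the flow so
  the table embeds as a stationary chain.
* **IJA-1, ASD**: the published count rows and the published normalized
  transition score are mutually inconsistent (the counts imply a score
  near 0.74, not 0.36). The score is the derived, scale-free quantity, so
  the preset preserves the published target-to-face rate (3.31) and sets
  the non-target-to-face rate from the score ratio
  `(1 + 0.36) / (1 - 0.36) = 2.125`; face-to-object rates follow by flow
  balance, between-object stays at the published 1.40.
* **IJA-1, TD**: the published table is nearly flow-balanced; it is
  symmetrised preserving the published score (0.10) and between-object
  rate (5.1).
* **IJA-2**: a two-state face/target alternation. Total pairs set the
  dwell mean; the published directional asymmetry (ASD: face-to-target
  3.87 vs target-to-face 3.62; TD: 1.31 vs 1.71) is reproduced by the
  start-state weight, which enters the occupancy sum linearly and is
  solved exactly. The fitted start probabilities (ASD mostly at the face,
  TD mostly at the truck) are a byproduct of the published counts, and a
  plausible one: an unexpected moving object captures typical toddlers'
  gaze first.
* **Attrition**: per-trial exclusion probabilities 0.1 (ASD) and 0.075
  (TD) reproduce the published mean usable-trial counts (10.8 and 11.1 of
  12); they are split as `p_away = 0.03/0.025` with `p_skip` solved from
  `p_excl = p_skip + p_away - p_skip * p_away`.
* The covariate is drawn per group from the published distributions
  (ASD 85 +/- 24.2, TD 107.1 +/- 15.2).

```{r presets}
cfg <- load_task_config()
presets <- calibrated_presets(cfg)
expected_transition_counts(presets$ASD$IJA2, 7000)
```

### What the generator does and does not emulate

It reproduces the dwell/transition structure, group contrasts, measurement
jitter, blinks and off-screen gaps (as invalid spans), trial attrition and
the segment timeline. It does **not** emulate saccade kinematics, smooth
pursuit of the moving objects (object AOIs are static rectangles and
dwells sit on centroids), pupil measures, drift or calibration decay, or
systematic per-participant offsets. Passing recovery tests therefore shows
the pipeline is correct *given* the event model — stationary fixations
separated by instantaneous gaze shifts — not that the event model captures
every property of real infant data.

## Numerical choices and degenerate inputs

* Dispersion uses bounding-box width + height converted to degrees via the
  full subtended angle; translation invariance of the whole event layer is
  tested.
* Sample times sit on the exact 120 Hz grid (`k * 1000/120 ms`); the
  canonical CSV dialect fixes formats (t to 4 decimals, coordinates to 2)
  so write→read→write round trips are byte-identical.
* Ties: phase assignment ties go to the earlier phase; midranks handle
  tied values in the rank ANCOVA; a constant sample fails the normality
  gate (Shapiro-Wilk is undefined there, and a constant is certainly not
  evidence of normality).
* Degenerate fits: zero rank variance gives F = 0, p = 1; a perfectly
  constant usable-trial table reports null task effects rather than 0/0
  artefacts.
* Empty inputs: empty sample streams give empty fixation tables (not
  errors); zero usable trials make all per-trial means undefined.
* A dwell truncated by the segment end may fall under 60 ms and go
  undetected; at calibrated dwell means this loses well under 2% of
  expected transitions and is the main (small, conservative) gap between
  closed-form expectations and pipeline recovery.

## Problem sizes used in validation

The packaged validation runs use 17 ASD / 15 TD simulated participants
per study (the published design), 50 seeded study replications for the
direction-of-effect checks, 2000 null replications (16 per group) for the
rank-ANCOVA type-I rate, 400-trial batches for exclusion-rate and
closed-form/empirical agreement, and 500 random streams (up to 200
samples) for the event-layer oracle. These sizes put Monte-Carlo error
comfortably below the tolerances they are checked against while keeping
the default test run quick.

## Known limitations

* The rank ANCOVA tests location shift on midranks; it is not a test of
  stochastic dominance, and heavy ties reduce its resolution.
* FD% denominators include off-AOI fixation time; studies that normalise
  by AOI-restricted time will report systematically larger shares.
* The simulator's IJA-2 world has no non-target object, so between-object
  measures are undefined there by construction.
* Calibration matches first moments (expected counts); published
  between-participant variances are matched only approximately through
  the renewal/chain variability, not targeted explicitly.
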