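---
title: "Measuring configural spatial knowledge: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring configural spatial knowledge: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confignav)
```

## The measurement problem

Two tasks dominate the assessment of configural (survey) spatial knowledge
after route learning: judgments of relative direction, scored by absolute
pointing error, and route-based shortcutting, scored by travel efficiency.
Both are averages of noisy per-trial scores, so any correlation computed
between them is attenuated by each measure's internal consistency, and any
group comparison is limited by each measure's discriminating power. The
package treats these psychometric properties as first-class outputs:
reliabilities are estimated per measure (and per ability group), observed
correlations are reported next to their disattenuated counterparts, and the
synthetic-data generator reproduces the floor and ceiling phenomena that
destroy discriminating power, so that the whole chain can be validated
against known ground truth.

## Scoring model

**Pointing.** A trial is scored as the absolute angular disparity between
response and true bearing, `min(|d|, 360 - |d|)` with `d` the difference
mod 360, in [0°, 180°]. A uniformly random response yields an error that is
uniform on [0°, 180°], so its expectation is exactly 90° — the chance level
against which cohort means are tested. Bearings are clockwise-from-facing
degrees in [0°, 360°), matching an on-screen pointer circle.

**Shortcutting.** A trial's travel efficiency is traveled length divided by
the shortest traversable path length between start and goal, computed on a
metric corridor graph (Dijkstra via igraph). Efficiency 1 is optimal. The
*learned-route efficiency* is the mean, over the task's trial pairs, of the
along-route distance from start to goal divided by the shortest path; it is
both an interpretive anchor ("no better than retracing the tour") and the
imputation value for failed trials. Along-route distance walks the tour
forward from the start landmark to the first subsequent occurrence of the
goal, wrapping around if the tour is closed; the forward-only walk matches
a one-directional guided tour, and the wrap is our choice for tours whose
endpoints are joined (the alternative, reflecting at the ends, would make
some pairs unreachable). Published constants (2.54 for the desktop-style
maze, 2.19 for the immersive-style maze) are accepted as overrides when no
maze geometry is available.

**Exclusions.** Participants failing more than 30% of their shortcutting
trials are removed from both measures (strict inequality: "more than 30%");
afterwards, any shortcutting trial failed by at least 30% of the remaining
cohort is dropped (inclusive: a trial failed by exactly 30% of a cohort is
excluded). The asymmetry is deliberate — it reproduces the screening
behavior reported for these tasks, where a trial sitting exactly at the 30%
boundary was removed while the participant rule was phrased strictly.
Remaining failed trials are imputed at the learned-route efficiency, the
score of a participant who retreats to the learned route; since that
constant also censors the generator's efficiency distribution from above,
imputation can never lower a participant's mean.

## Reliability: permutation split-half

For a participants-by-trials matrix, one split-half replicate partitions the
trial columns into two halves (sizes differing by at most one; for odd
counts the larger half falls on either side with equal probability),
averages each participant's observed cells within each half, correlates the
half-means across participants, and steps the correlation up with
Spearman–Brown, `2r/(1 + r)`. The reported estimate is the arithmetic mean
over `n_permutations` random partitions (default 5000; the acceptance and
pipeline defaults use fewer — see *Problem sizes* below). Design choices the
method itself leaves open, made explicit here:

* **Aggregation** is the plain mean of corrected correlations, not a
  Fisher-z mean; this matches the common implementation of the permutation
  method and keeps the estimate interpretable as an average reliability.
* **No clamping.** Individual split correlations can be negative and the
  corrected value can fall outside [0, 1]; the mean is reported as-is and
  flagged when outside [0, 1]. Silent clamping would hide exactly the
  estimator pathology (near-zero true-score variance) that the analysis is
  meant to expose.
* **Missing cells** are handled pairwise within each half; a participant
  with no observed cell in a half is dropped for that split and counted.
  Splits yielding no valid correlation (e.g. a constant half) are dropped
  with a warning and counted in `n_invalid_splits`.

When the matrix is complete, all permutations are evaluated at once as two
matrix products (trials-by-permutations weight matrices), which keeps even
the 200-cohort recovery study inexpensive.

## Correlations, disattenuation and inference

Observed correlations are Pearson throughout (the inference format
`r(df) = .., t(df) = ..` presumes Pearson sampling theory). The correction
for attenuation divides the observed correlation by the geometric mean of
the two reliabilities. Values with magnitude above 1 are reported, flagged,
and only shrunk to ±0.999 inside Fisher-z machinery, where the transform is
undefined otherwise. A non-positive reliability estimate leaves no
admissible correction; the disattenuated cell is then reported absent
rather than fabricated.

Single-correlation inference uses `t = r sqrt((n-2)/(1-r^2))` on `n - 2`
degrees of freedom and a Fisher-z interval `tanh(atanh r ± z/sqrt(n-3))`.
Two independent correlations are compared with Fisher's z statistic and
Zou's interval for the difference, assembled from the two individual
intervals. One caveat is inherited from practice: when the comparison is
applied to *disattenuated* values, their sampling distribution is
approximated as if they were plain correlations. The package applies the
same approximation and documents it rather than refusing the computation.

Power for the two-sided Pearson test uses the Fisher-z normal
approximation, `Phi(m - z) + Phi(-m - z)` with `m = sqrt(n-3) atanh(rho)`;
at `rho = 0` it reduces to the test size, and the test suite corroborates
it against Monte-Carlo rejection rates.

## Ability clustering and group descriptives

Participants are clustered by k-means on their three scores (efficiency,
Phase I and Phase II pointing error), z-scored per measure because degrees
and ratios are incommensurate — whether to standardize is genuinely open in
the field, and we standardize by default for that reason. Each candidate k
(2–6) is fit with the best of 50 random initializations; the silhouette
method decides k, and the inertia curve is reported for elbow inspection
rather than automated (the two criteria come with no published arbitration
rule). Labels are "low" for clusters whose mean Phase I error exceeds the
grand mean of cluster centers, ties broken by efficiency. Group
descriptives report SD with the n−1 denominator, adjusted Fisher–Pearson
skewness and *excess* kurtosis (e1071, type 2) — conventions the published
tables are consistent with but do not state.

## The synthetic cohort generator

The generator encodes the statistical structure the analysis assumes, not a
cognitive process model:

* **Latent layer.** Two clusters ("high"/"low") with bivariate-normal
  pointing and shortcutting abilities. The within-cluster correlation may
  differ by cluster (`rho = c(high, low)`, defaults 0.95 and 0.15): a
  dissociation in which weak learners point at chance yet still shortcut
  implies the latent coupling itself is weak in that subpopulation, not
  merely attenuated — with a shared coupling the low cluster's observed
  correlation would stay visibly positive whenever its reliabilities do.
* **Pointing.** A guessing mixture: with probability
  `plogis(guess_intercept - guess_slope * ability)` the response is uniform
  (the 90° floor); otherwise the signed error is wrapped-normal with
  concentration `exp(conc_intercept + conc_gain * ability - b_j)`, where
  `b_j` is a per-trial difficulty offset. The wrapped-normal family is one
  of the standard circular unimodal choices; all that matters downstream is
  a concentration parameter with a uniform limit (guessing) and a
  degenerate limit (perfect pointing). Phase II adds a practice bonus to
  ability.
* **Shortcutting.** Success is Bernoulli in ability and trial difficulty;
  successful trials score exactly 1 with ability-dependent probability (the
  ceiling mass) and otherwise 1 plus an exponential excess, censored at the
  learned-route efficiency. Failures carry no traveled length and are later
  imputed.
* **Geometry.** The fixture maze is a 4×4 grid (11 m on a side — a
  single-floor, planar environment) with 12 landmarks on the perimeter and
  a closed perimeter loop as the learned route; shortcutting pairs are
  chosen so the along-route detour is at least 25% longer than the interior
  shortcut. Pointing true bearings are uniform and independent of the
  geometry, as the pointing model needs only the error distribution.
* **Reproducibility.** All randomness flows from one root seed through
  named substreams (cohort, difficulties, each pointing phase, shortcut,
  walks, trial-pair selection), so each stage can be regenerated alone.

**Calibration.** The preset parameters were set empirically — simulate,
measure, adjust — against the published group-level profile of the
desktop-style study: a low cluster pointing near chance (mean in the
80–95° band, around 86°) with weak internal consistency (< 0.5), a high
cluster around 40–50° with reliability near 0.75, group efficiencies near
1.4 and 2.0, an observed high-cluster pointing–efficiency correlation near
0.6 with the low cluster's near 0, and silhouette-selected k = 2. Closed
forms for the split-half reliability of mixture models are not available,
so calibration proceeds by simulation; the `generate_trial_matrix` helper
complements this with a linear-Gaussian trial model whose reliability is
exact by construction (`noise SD = between SD * sqrt(k (1-R)/R)`), used
wherever a test needs analytically engineered reliabilities. The
"immersive-like" preset shifts abilities up, enlarges the exact-1 ceiling
mass and uses 24 trials per task with a 2.19 learned-route ceiling.

**What the generator does not emulate.** Item-level difficulty structure is
random rather than tied to landmark salience or maze geometry; pointing and
walking are statistically, not mechanistically, linked (no path
integration); reaction times, trajectory shapes and learning dynamics
within a phase are out of scope. Passing tests therefore demonstrate that
the *estimators* behave correctly under the assumed statistical structure,
not that real cohorts satisfy that structure.

## Numerical choices and degenerate inputs

* Efficiency may undershoot 1 by at most 1e-9 relative (float summation);
  the validators allow exactly that slack.
* `spearman_brown` is undefined at r = −1 and errors there; permutation
  splits that land on it (or yield no valid correlation) are dropped and
  counted.
* Ties between equally short paths are irrelevant — only lengths are
  consumed. Greedy steps in `simulate_walk` minimize edge length plus
  remaining distance, so a fidelity-1 walk reproduces a shortest path
  exactly.
* Constant score vectors report absent skewness/kurtosis; groups smaller
  than 5 omit reliability with a warning; a one-sample test with zero SD is
  an error, as is a correlation with a zero-variance input.
* Participants missing Phase II are retained with an `NA` score rather than
  dropped.

## Problem sizes

Defaults were chosen so the full test suite and the acceptance script each
run in well under a minute on a single core: pipeline reliability estimates
default to 1000 permutations (5000 remains the standalone default of
`permutation_split_half`), the recovery study uses 200 cohorts of 60
participants with 200 permutations per reliability estimate, the
chance-level Monte-Carlo uses 2×10^5 trials, and the dissociation check
averages six "desktop-like" cohorts. Estimates stabilize well before these
sizes; they are comfortable, not minimal.

## Known limitations

* Zou's interval applied to disattenuated correlations is an approximation
  (see above); bootstrap intervals for disattenuated correlations are out
  of scope.
* The permutation split-half estimator is itself noisy for small groups;
  per-group reliabilities for groups near the minimum size of 5 carry wide
  uncertainty, which the permutation SD and percentiles quantify.
* k-means with silhouette selection assumes roughly convex, comparable
  clusters; it is the conventional choice here, not a claim of optimality.
  Gaussian mixtures and stability analysis are deliberately not included.
* The generator's two-cluster latent structure is an idealization; real
  cohorts are likelier to sit on an ability continuum, and the clustering
  step will then carve it at a data-driven boundary.
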