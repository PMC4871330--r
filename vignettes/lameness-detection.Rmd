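---
title: "Detecting lame dairy cows from accelerometer and noseband sensor behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lame dairy cows from accelerometer and noseband sensor behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Lameness is one of the costliest and most painful conditions in dairy herds,
and farmers detect it poorly by eye, especially in its mild forms.  Modern
leg-mounted 3D accelerometers classify a cow's posture (lying vs upright) and
individual strides with high accuracy, and halter-mounted noseband pressure
sensors record jaw activity (eating and ruminating chews, rumination
boluses).  `lamewatch` implements the full analysis chain that turns such
classified sensor events into a lameness detector for a cross-sectional
cohort: behavioral summaries per cow, group comparisons between lame and
non-lame cows, and logistic classification with ROC-based cutoffs.

The reference design it emulates is a cohort of 12 non-lame and 41 lame
multiparous Holstein cows, each recorded for 3 consecutive days with two
accelerometers (one per hind limb) and one noseband sensor.  Lameness ground
truth is a visual gait score on the 1--5 half-point numerical rating scale
(NRS): the mean of six observer scores, rounded to the nearest half point,
with NRS <= 2 non-lame (group C) and NRS >= 2.5 lame (group L; subdivided
into LI 2.5--3, LII 3.5, LIII >= 4).

# Bout segmentation

`segment_events()` converts one cow-day of classified events into bouts:

* **Walking bout** — a maximal run of at least 3 strides in which the time
  between consecutive strides never exceeds 4 s.  Strides outside such runs
  exist in the stream but are *not counted* in the `strides` variable.
* **Lying bout** — a maximal lying interval strictly longer than 50 s.
* **Standing bout** — an upright, non-walking period lasting more than 50 s
  when the cow was previously lying, or more than 4 s when it was previously
  walking ("standing" is upright-but-not-walking).

Numerical choices, where the rules alone do not pin behavior down:

* All thresholds are strict inequalities (a 50.0-s lying interval is not a
  bout), matching the "greater than" wording of the definitions.
* Sub-threshold periods contribute no bout but their time still counts
  toward the state's total, so lying + standing + walking time always sums
  to 1440 min/day.  Time conservation is treated as non-negotiable because
  the daily time budget is itself an analysis variable.
* A walking bout's extent runs from its first stride's start to its last
  stride's end (start + stride duration).  The definitions never state the
  extent; this is the minimal consistent choice.
* The first period of the day has no preceding state and is treated as
  following lying, i.e. with the stricter 50-s rule.
* A standing period between a walking bout and a lying bout is counted if
  the post-walking rule (> 4 s) holds; the definitions are silent on this
  transition.

`summarize_hourly()` splits state durations across hour boundaries,
attributes each bout to the hour containing its start, and computes stride
statistics over the counted strides in each hour.

# Aggregation

Daily summaries sum every variable over the 24 hours except four rate/shape
variables, which are weighted means, `sum(a*x)/sum(x)`: chews per minute
(weighted by ruminating time), chews per bolus (by boluses), stride duration
and stride distance (by strides).  Two derived variables are attached:

* calculated walking speed (m/s) = 10 x stride distance (cm) / stride
  duration (ms);
* lying bout duration (min/bout) = lying time / lying bouts.

Days on which a cow was in heat, inseminated or visibly ill are discarded;
a cow with fewer than two clean days is excluded.  From the clean days, two
are chosen at random (seeded per cow) along with one of the two
accelerometers, and the two days are averaged: sums arithmetically, weighted
means by *re-weighting* across the two days.  Re-weighting (rather than
averaging the two daily means) keeps the averaged statistic equal to the
same statistic computed from the pooled raw events; the package tests
enforce this equivalence to 1e-9.

NRS rounding ties (means ending in .25 or .75) round *up* to the next half
point, consistent with the upward rounding used for body condition scores on
a quarter-point scale.  Group assignment is a total function on the
half-point grid: every value maps to exactly one of C/LI/LII/LIII.

# Group statistics

`two_group_test()` routes each variable: Shapiro-Wilk normality on both
groups at alpha 0.05; if both pass, an F test at alpha 0.05 chooses between
the equal-variance t test and the Aspin-Welch (Welch) unequal-variance test;
otherwise the Wilcoxon rank sum test (exact when the smaller group has at
most 10 observations and the data are tie-free, otherwise the
normal approximation with continuity and tie correction).  The original
analysis names the three tests but not the routing mechanism; this gate is
the package's explicit, documented substitute and mirrors common commercial
statistics workflows.

`four_group_compare()` uses one-way ANOVA with Bonferroni-corrected pairwise
t tests on the normal route, and Kruskal-Wallis followed by Dunn's pairwise
Z tests (rank-sum construction with midrank tie correction, Bonferroni
applied to the critical Z across all pairs) otherwise.  Results include a
compact letter display built by insert-and-absorb, with the guarantee that
two groups share a letter exactly when their corrected pairwise comparison
is non-significant.  IQRs use linear-interpolation (type 7) quantiles
throughout.

# Logistic classification

`lameness_model()` fits maximum-likelihood logistic regression and reports
odds ratios at field-relevant increments (per 30 min of time, per 1000
chews, per 10 bouts/boluses, per 100 strides, per 0.1 s, per 10 cm, per
0.1 m/s) with Wald 95% CIs and p values, both McFadden and Nagelkerke
pseudo-R^2 (the study's "R-squared" variant is not identified by name, so
both are computed and labeled), and a ROC analysis of the linear predictor.

ROC conventions:

* AUC uses the rank (Mann-Whitney) construction with midranks, equal to the
  probability that a random lame cow outscores a random non-lame one, ties
  counting half.
* The selected cutoff maximizes sensitivity + specificity; ties prefer the
  higher-specificity cutoff, then the more conservative one.
* Cutoffs are strict: a score exactly on the cutoff is called non-lame.
* Multivariable cutoffs are read on the linear-predictor (logit) scale —
  published values like -0.06 or 1.77 are inconsistent with probabilities —
  while univariable cutoffs for single variables live on the variable's
  natural scale, with the lame side implied by the odds-ratio direction
  (OR < 1 means lame-if-below).

Two frozen, published model equations ship with the package
(`frozen_model("A")` and `"B"`): scoring them is pure arithmetic, no
fitting, so published operating points can be reproduced on any compatible
summary table.

`build_multivariable()` implements the selection procedure: candidates
(variables significant in the two-group tests) are ranked by univariable
AUC (ties by smaller Wald p); walking down the ranking, a variable enters
only if its Spearman correlation with every admitted variable stays strictly
inside (-0.5, 0.5); backward elimination then removes the largest-Wald-p
variable while it is at or above alpha, recording the model AUC before and
after each removal.  The pre-elimination model is kept alongside the final
one, since a near-significant variable's contribution is often of interest.

# The synthetic cohort generator

No raw sensor data ship with the package, so `simulate_cohort()` generates
cohorts with the statistical structure the analysis assumes; it is
first-class, tested code, and its defaults *are* the study conditions: 12
non-lame and 41 lame cows, 3 recording days, and the published per-variable
means and SDs of the averaged 24-hour summaries.

Design choices:

* **Marginals** are truncated normals at physical bounds (times in
  [0, 1440] min, counts >= 0, durations and distances positive).  Published
  medians sit close to the means, supporting near-symmetric marginals;
  counts are rounded truncated normals rather than Poisson because the
  published SDs are far from sqrt(mean).
* **Correlation**: standing and walking bouts are linked by a Gaussian
  copula calibrated to Spearman rho 0.98 (the only correlation the source
  reports — every post-walking standing phase follows a walking bout).  The
  same copula is applied to the day-level deviations so the correlation
  survives daily averaging.
* **Derived variables are derived, not drawn**: standing time is
  1440 - lying - walking (the published standing moments are reproduced to
  within a minute by this identity), walking speed is computed from the
  drawn stride distance and duration (reproducing the published speed SDs of
  0.09/0.10 m/s almost exactly), and lying bout duration from lying time
  and bouts.
* **A misprint correction**: the published non-lame stride-duration SD
  (0.84 s) is irreconcilable with the same row's IQR (0.14 s), with the lame
  group's 0.15 s, and with the walking-speed SD it would imply; the
  generator uses IQR/1.349 = 0.104 s.
* **Within-cow day-to-day variance** is not reported; it is exposed as
  `day_sd_frac` (default 0.20 of the between-cow SD), a value typical of
  repeated behavioral measurements over consecutive days in one housing
  environment.
* **Severity subgroups** (`cohort_params(split_lame = TRUE)`): only the
  pooled lame-group moments are published.  Bout-count means are graded
  across LI/LII/LIII (effect fractions 0.55/1.25/1.50 of the C-L
  difference, sized 19/11/11 so they average back to the pooled mean, with
  within-subgroup SDs shrunk to preserve the pooled SD), reflecting the
  reported pattern that mildly lame cows are not separated from controls in
  bout counts while moderately and severely lame cows are.  Other variables
  keep the pooled mean across subgroups.
* **Event streams**: `simulate_event_stream()` realizes a day's targets as
  posture intervals and stride events (lying bouts alternating with upright
  blocks; each walking bout a stride run with gaps <= 4 s followed by a
  standing phase).  Standing-bout counts are matched by making some
  post-walking pauses sub-threshold or by inserting sub-threshold 30-s lying
  breaks; infeasible targets (e.g. walking time smaller than strides x
  stride duration) raise errors naming the violated constraint.
  Segmentation of a synthesized stream reproduces the generating targets
  exactly for lying/walking bout counts and counted strides, and to within
  seconds for state times.

What the generator does **not** emulate: diurnal activity rhythms (hour
allocation is random, not circadian), heavy-tailed or skewed real-world
marginals, sensor misclassification noise, and any correlation structure
beyond the single published pair plus the derived-variable identities.
Consequently, passing tests demonstrate that the analysis chain is
implemented correctly and behaves as published *under the published
moments*, not that the detector would achieve the same operating point on a
new farm.  Where the published numbers are sample artifacts — for example a
univariable cutoff that happened to fall below the observed minimum of the
12 control cows, yielding 100% specificity — a moments-calibrated
simulation reproduces the procedure but not the artifact, and the package
reports the honestly lower value.  Similarly, on Gaussian data the refit
walking-speed model discriminates slightly better than in the real cohort,
so backward selection retains a bout-count variable less often than the
original analysis did.

# Problem sizes and runtime

The test suite checks moment and correlation recovery at 500--600 cows per
group, reproduces published operating points as means over 40 replicate
cohorts of 53 cows (12 control cows make per-cohort specificity move in
8.3-point steps, so single-cohort values are too granular to compare), and
runs the scaled selection/severity replication over 500 replicate cohorts.
`scripts/acceptance.R` recomputes the same quantities from scratch with 40
and 200 replicates respectively.  All sizes were chosen so the full suite
and the script each complete in a few minutes on one CPU while keeping
Monte-Carlo error well below the comparison tolerances.

# Known limitations

* All classification metrics are resubstitution estimates, as in the
  original analysis; there is no cross-validation or external validation,
  and reported sensitivities/specificities are optimistic for new data.
* Behavioral thresholds and cutoffs are management-dependent (milking
  frequency, walking distances, floor type); frozen models A and B should
  not be treated as universal constants.
* The pipeline starts from *classified* posture and stride events; raw
  acceleration signal classification and noseband signal processing are out
  of scope, as is longitudinal change-point detection within a cow.
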