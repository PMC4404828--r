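---
title: "Multivariate behavioral profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate behavioral profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcsfr)
```

## The measurement model

The multivariate concentric square field (MCSF) is a 100 × 100 cm arena
whose ten zones offer qualitatively different settings: an open center with
a 22-cm central circle, three 15-cm corridors framing the center, a dark
corner room (DCR) serving as shelter, an elevated hurdle with a hole board,
and a slope–bridge-entrance–bridge run ending on an intensely lit, elevated
bridge. Because the zones differ in risk and enrichment, a free 30-minute
exploration samples the full repertoire of general activity, exploration,
shelter seeking, risk assessment and risk taking, rather than forcing the
single either-or readout of classical tests.

`mcsfr` treats the zone-visit event as its atomic observation. Per zone
and animal the pipeline computes latency to first entry (LAT, s), visit
frequency (FRQ), total duration (DUR, s), mean visit length (DUR/FRQ),
distance moved (cm) and mean velocity (cm/s, distance over duration), with
aggregate rows for all corridors (`total_corr`) and the whole arena
(`arena`); TOTAL ACT is the visit count over all zones. Percent measures
divide by TOTAL ACT (frequency) and by either total in-zone time or trial
time (duration) — both denominators are supported because published
time-budget figures and parameter tables use them inconsistently;
`total_visits_time` is the package default for parameter tables and
`trial_time` the default for time-budget displays.

Four derived indexes compress zone preferences into interpretable scores:

* **shelter/corridor index** `(FRQ DCR − FRQ corrA) / (FRQ DCR + FRQ corrA)`
  — since corridor A is the only access to the shelter, values near zero
  mean the animal enters the DCR nearly every time it enters corridor A,
  i.e. uses the shelter as a home base;
* **slope/bridge interval** `(LAT slope − LAT bridge) / LAT slope` — the
  relative delay between reaching the slope and daring the bridge, an
  impulsivity-flavoured readout (≤ 0 whenever the slope is entered first);
* **risk/shelter duration and frequency indexes**
  `(bridge − DCR) / (bridge + DCR)` on DUR and FRQ — performance in the
  risk area relative to the shelter, an anxiety-flavoured readout.

A zero denominator or a missing input makes the index missing — an absent
value is treated as missing data, never coerced to 0 or ±1, because a rat
that visited neither zone carries no information about their ratio.

## Visit extraction from tracking logs

The reference tracking software counts a visit using multiple tracked body
points. From a single tracked point that rule cannot be reconstructed, so
the package defines a visit as a maximal run of constant zone assignment
of the tracked point, with an optional `min_visit_duration` smoothing
(default 0: no smoothing; runs shorter than the threshold are absorbed
into the surrounding visit of the previous zone). This single-point rule
is deliberately simple because it is *oracle-checkable*: an independent
frame-by-frame scan must reproduce it exactly, and the test suite enforces
that equivalence on randomized tracks.

Numerical conventions, chosen once and tested:

* every inter-frame interval and step length is credited to the zone of
  the interval's *first* sample, so total time and distance are conserved
  exactly (visit + unassigned + missing-frame time = tracked time);
* geometry is half-open (`xmin ≤ x < xmax`; circles open), so a point on a
  shared boundary belongs to the zone listed first in the configuration and
  no point is ever double-assigned; nested zones win by depth (a point in
  the central circle is CTRCI, never center, and center time excludes
  CTRCI time);
* missing frames break a visit only when the gap exceeds
  `min(2 s, 5 / frame rate)` — brief detection dropouts should not inflate
  visit counts — and gap time is never credited to the visit;
* a zone entered only at the final frame has no measurable duration and
  forms no visit.

The published arena dimensions cover only the outer square, inner square
and central-circle diameter. The bundled default configuration fills in
the rest (15-cm corridors; corner rectangles for DCR and slope; top-strip
rectangles for hurdle, bridge entrance and bridge) as documented package
assumptions, with elevation ignored since tracking is 2-D overhead video.

## Trend analysis

The trend analysis converts heterogeneous parameters into comparable
profile scores: animals are ranked across experimental groups and trials
for each parameter (ascending mid-ranks; `(inv)` parameters are reversed
first so that, e.g., a *short* mean corridor visit ranks as *high*
activity), and ranks are summed within five fixed functional categories —
general activity, exploratory activity, shelter seeking, risk assessment,
risk taking. The bundled category map follows the standard parameter
assignment; it is a configuration file, not code, so laboratories with
different conventions can swap it.

Design choices where the method description is silent:

* **ties** take mid-ranks, preserving the per-parameter rank sum
  `m(m+1)/2` under any tie pattern (a tested invariant);
* **missing values** are excluded from the ranking, then contribute the
  parameter's pooled mid-rank `(m+1)/2` to the category sum, keeping
  scores comparable across animals with different missingness; a listwise
  mode is available;
* **pooling**: by default a single ranking pools all groups and trials, as
  the procedure's description implies; per-trial ranking is available for
  single-trial analyses.

Because rank sums are approximately normal, category scores are tested
parametrically: within-trial unpaired t-tests, and for two trials a
two-way repeated-measures ANOVA (group × trial, animal as repeated unit)
with Bonferroni-adjusted within-group trial contrasts. Normality is not
re-tested by default; the scores are sums of ranks and their sampling
distribution is stable by construction.

## Ethogram scoring

Novel cage (5 min) and home cage change (10 min) sessions are scored as
bout logs. Relative frequency and duration of each behavior are fractions
of the *total categorized behavior* of that animal; category scores sum
member fractions, so frequency-variant scores over the coping-style
categories (proactive, reactive, exploratory, locomotor) or the social
categories (neutral, dominant, aggressive, submissive) always sum to 1 on
fully categorized logs — a tested normalization invariant. Burrowing is a
standalone defensive behavior reported raw (seconds and bouts) and is
excluded from the denominators, keeping the category fractions and the
raw burrowing scale consistent with how each is reported. Point events
(e.g. passing) may have zero duration and then contribute to frequency
scores only. Overlapping bouts are permitted — two behaviors can co-occur
in dyadic scoring — and flagged.

## Statistical battery

Group comparisons use the Mann-Whitney U-test, within-group trial
comparisons the Wilcoxon matched-pairs test, intra-trial time courses the
Friedman test with Dunn's post-hoc comparisons (Bonferroni over bin
pairs), occurrence the two-sided Fisher exact test, and monotonic
association Spearman's rank correlation with the conventional strength
bands (|r| < 0.40 weak/none, 0.40–0.59 moderate, 0.60–0.79 strong,
≥ 0.80 very strong). Significance is labelled at p ≤ 0.05 and trends at
0.05 < p ≤ 0.1, boundaries inclusive.

Conventions: exact Mann-Whitney/Wilcoxon distributions are used when both
samples have ≤ 12 observations and no ties (the cohort size of interest
fits exact computation), otherwise the tie-corrected normal approximation
with continuity correction; zero paired differences are dropped before
ranking, and an all-zero difference vector returns p = 1 by convention;
a zone unvisited by an animal makes that zone's dependent variables
missing for between-group tests, while paired trial comparisons instead
set DUR and FRQ to 0 and latency to the session duration (1800 s), so
"never entered" participates as a real, maximally late observation. The
Friedman statistic is reported in its χ² form; software that reports an
F-approximation will show slightly different values on the same data.
The suite verifies all three exact tests against full enumeration
(all rank assignments, all sign patterns, all 2×2 tables with N ≤ 40).

For multivariate profiling, parameters are unit-variance scaled and
mean-centered. PCA summarizes the systematic variation (scores, loadings,
per-component R²X). PLS-DA relates the parameter matrix to group
membership with a NIPALS fit: each X-weight vector maximizes the
covariance between the X-score and the group indicator, X is deflated
between components, and the X-weights *w* and Y-weights *c* are returned
for biplot-style interpretation. With separable groups the two groups
locate opposite to each other on component 1. Missing cells are imputed
at the column mean after scaling (i.e. zero) and counted in the output;
zero-variance columns are dropped with a warning. No cross-validated
predictive statistic (Q²) is computed: its value depends on a
segmentation scheme the package does not define, and reporting an
arbitrary one would invite over-interpretation. Note that per-component
R²X is guaranteed non-increasing for PCA but not for PLS-DA, whose
components are ordered by covariance with the response, not by explained
X-variance.

The Mann-Whitney battery skips structurally constant columns (for
example, latency to the release zone is 0 for every animal by design, and
arena-total duration equals the session length): a parameter without
between-animal variance cannot be rank-tested and would only report a
meaningless p = 1.

## The synthetic cohort generator

No raw animal data accompany the method, so validation uses a simulator
whose ground truth is known. Zone occupancy is a semi-Markov walk on the
arena adjacency graph: per-zone dwell times (exponential by default,
gamma optional), transitions to adjacent zones proportional to
configurable weights, and a within-zone path simulated as a persistent
random walk confined to the zone geometry at the profile's speed. A
multiplicative habituation factor (default 0.8 per 10-min bin) scales
dwell and behavior rates so within-session declines — the pattern
time-course analyses are designed to detect — are present in the
synthetic data. Ethogram sessions are alternating-renewal bout sequences:
behavior drawn proportional to its rate, bout length exponential,
exponential inter-bout gaps; the expected relative frequency of a
behavior therefore equals its normalized rate, which is the closed-form
oracle the tests use. Home-cage pairs are generated jointly, with a
configurable probability that a dominant or aggressive bout elicits the
partner's complementary submissive response.

Default study conditions mirror the design the pipeline targets: 2 groups
× 12 rats, two 30-min MCSF trials, one 5-min novel-cage and one 10-min
paired home-cage session per animal, 5 Hz tracks. Baseline dwell means
(5–30 s, shelter longest, bridge-approach zones shortest), speeds
(4–14 cm/s) and behavior rates (0.1–2 events/min) were chosen once as
realistic magnitudes for an actively exploring rat; they are test
fixtures, not estimates of any strain's parameters, and the simulator
makes no claim of behavioral realism beyond the structural features the
pipeline consumes. Dwell draws are floored at two frame intervals so
every generated visit is resolvable in the emitted track; with an odd
group size the last animal has no cage mate and gets no home-cage log.

Everything is a pure function of configuration and master seed:
per-session seeds are drawn deterministically from the master seed, so a
cohort is byte-reproducible. Effect multipliers (named paths such as
`point_rates.saps` or `attract.dcr`) perturb group 2's profile to plant
known effects.

`recovery_experiment()` closes the loop: it repeatedly simulates cohorts,
runs the full pipeline and reports per-parameter and per-category
rejection rates. With no planted effects these estimate type-I error
(the suite checks they sit near the nominal 5 % over 1000 cohorts); with
a planted effect the affected parameter and its functional category must
out-reject all others. What passing these tests shows is that the
*pipeline* is calibrated and sensitive under the generator's assumptions;
it does not show that real tracking data satisfy those assumptions —
real data carry detection noise, body-point ambiguity and
non-exponential dwell structure the generator does not emulate.

## Problem sizes and runtime

The test suite simulates 1000 null cohorts and 200 effect cohorts at
n = 12/group with visits-only sessions (no frame-level tracks), which
keeps the full suite around a quarter hour on one core; the acceptance
script uses 400 null and 100 effect replicates for the same quantities.
These sizes were chosen to keep Monte-Carlo standard errors near half a
percentage point on rejection rates while remaining comfortable to re-run.

## Known limitations

* The single-point visit rule is a documented deviation from
  multi-body-point tracking; absolute FRQ/DUR values from real
  EthoVision exports will differ, although within-experiment contrasts
  are expected to be insensitive.
* The default arena geometry beyond the published outer/inner squares and
  central circle is an assumption set; laboratories should encode their
  own apparatus in a config file.
* Dunn's post-hoc z-test is the standard rank-mean formulation with
  Bonferroni adjustment; software using other multiplicity schemes will
  report different adjusted p-values.
* PLS-DA is fitted without cross-validation; weights are descriptive, not
  predictive claims.
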