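---
title: "Analysing loop migration with looptrack: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing loop migration with looptrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(looptrack)
```

## The scientific setting

Small trans-Saharan migrants such as barn swallows (*Hirundo rustica*) can
only be tracked with light-level geolocators (GLS), which yield at most two
position fixes per day (one per twilight) with latitudinal errors well in
excess of longitudinal ones. From such twilight-resolution tracks a typical
analysis asks three families of questions:

1. **Where and for how long do birds reside in winter?** Tracks are reduced
   to *stationary periods* (SPs): residency intervals south of the Sahara,
   each located by the density mode of its daily position estimates.
   Individuals occupying two or more distinct areas are *itinerant*.
2. **What do the journeys look like?** Each migration episode
   (post-breeding, colony to first SP; pre-breeding, last SP back to the
   colony) is summarised by departure and arrival dates (DD, AD), length of
   the migration path (LMP, km), path straightness (PS, %), duration
   (DM = AD − DD, days) and migration speed (MS = LMP/DM, km/day).
3. **How consistent are routes, within and among individuals and between
   seasons?** Route similarity is measured with the One-Way-Distance (OWD)
   metric, and hypotheses about timing, carry-over effects and route spread
   are tested by permutation.

`looptrack` implements this pipeline together with a seeded synthetic
cohort generator, so every statistical procedure can be validated against
data whose generating truth is known. Reconstructing positions from raw
light data (particle-filter geolocation, twilight filtering, calibration)
is upstream of this package: the pipeline starts from position tracks,
candidate SP intervals, and colony departure/arrival dates, as those
upstream tools supply them.

## Geometry

All distances are haversine great circles on a sphere of mean radius
6371.0088 km. Tracks are ordered sequences of fixes with strictly
increasing continuous day offsets (day 1 = 1 January of the deployment
year; spring dates continue past 365 so that a winter stay is a single
interval).

Two operations deserve comment:

* **Latitude-band clipping** (`clip_to_lat_band()`, default 17°N–45°N)
  retains the track sections between the southern margin of the Sahara
  (≈17°N, the 200 mm/yr rainfall line) and the southernmost breeding
  latitude. Boundary crossings are interpolated *linearly in (lat, lon)* on
  the crossing segment rather than along the great circle: segments span at
  most half a day of flight, so the difference is far below GLS noise,
  and linear interpolation is exactly testable. Every in-band section of a
  track that leaves and re-enters the band is kept, in time order.
* **Equal-arc resampling** (`resample_equal_arc()`) places k points at
  cumulative arc distances iL/(k−1), endpoints included. Index-based
  subsampling would oversample stopovers, where fixes accumulate; equal
  arc spacing makes the resampled shape independent of fix density.

The antimeridian is not handled specially; the study domain
(≈20°W–50°E) is far from it. Longitudes are normalised to (−180, 180].

## Stationary periods

Candidate residency intervals (from upstream twilight-trend detection) are
processed with three rules:

* **Location**: the per-axis mode of a Gaussian kernel density (Silverman
  bandwidth) of the daily latitude and longitude estimates, maximised on a
  0.05° grid, with 5th–95th percentile intervals as spread. A mode is used
  rather than a mean because GLS daily estimates are heavy-tailed and
  occasionally multimodal; the 0.05° grid (≈5.5 km) is far below GLS
  accuracy. If all estimates coincide the mode is that value; if the
  bandwidth degenerates the median is used.
* **Merging**: consecutive SPs whose modal centres lie < 200 km apart are
  merged, pooling their daily positions and recomputing centre and
  quantiles on the pooled data. Merging proceeds left-to-right in time and
  iterates to a fixed point, so chains of nearby periods collapse fully.
  200 km is about the scale of GLS positional uncertainty, so closer
  "distinct" periods cannot be distinguished from noise.
* **Duration filter**: SPs shorter than 14 days are treated as migration
  stopovers and dropped (strict inequality: a 14-day SP is retained).

An individual with ≥2 retained SPs is itinerant; the longest SP is its
main one (ties resolved to the *earlier* period — a documented, arbitrary
tie-break), and the temporally first/last SPs anchor the post- and
pre-breeding episodes (AD_sp = start of the first SP, DD_sp = end of the
last).

## Episode features

LMP integrates step-by-step great-circle distances from the colony to the
first SP centre (post-breeding) or from the last SP centre to the colony
(pre-breeding); if the reconstructed track stops short of an endpoint, the
colony or SP centre is appended as a virtual endpoint so the path always
spans the full journey. PS is defined here as

PS = 100 · GC(endpoints) / LMP,

the percentage ratio of the endpoint great circle to the path length, so
PS ≤ 100 always, with equality only for a great-circle route. (Stated as a
ratio of LMP to the great circle this quantity would exceed 1; the
percentage form below 100 is the scale on which straightness values are
conventionally reported, and the one this package uses.) MS·DM = LMP holds
as an exact identity, which the test suite audits cohort-wide.

Cohort-level exclusions are parameters, not hard-coded counts: deployment
years can be dropped to keep the year factor two-level, and individuals
whose main SP lies strictly south of 10°S (long-distance outliers with
distinct migration patterns) are excluded from inferential analyses while
remaining in descriptive summaries.

## The One-Way-Distance metric

For tracks A and B, both clipped to the comparison band and resampled to
k = 20 equal-arc points:

d_AB = ( Σᵢ min over j of GC(aᵢ, bⱼ) ) / L_A,   OWD(A,B) = (d_AB + d_BA)/2,

where the "corresponding position" of aᵢ is the *resampled point* of B at
minimum great-circle distance (not an interpolated segment point), ties
resolved to the lowest index, and L_A is the length of A's clipped,
resampled 20-point polyline. Three deliberate choices:

* **Windowed denominator.** Each directed term is normalised by its own
  source track's clipped-resampled length. The clipping exists precisely to
  remove overall route-length effects, so the length of the object actually
  compared is the right normaliser.
* **Nearest among the k points only**, mirroring the definition of the
  metric at fixed k; with k = 20 on band-spanning routes the difference
  from segment-interpolated matching is small relative to GLS noise.
* **k is part of the metric.** The sum has one term per resampled point, so
  OWD is roughly proportional to k; values are only comparable at a common
  k. The per-point value OWD/k is stable (< 5% change when k doubles on
  smooth routes), which the test suite asserts. All cohort comparisons use
  k = 20.

OWD is symmetric by construction, zero iff the resampled point sets
coincide, invariant to reversing a track's fix order (endpoint-inclusive
resampling), and never decreases as one route is rigidly translated away
from another — all properties enforced by tests against a brute-force
oracle that builds the full k × k distance matrix with explicit loops.

`owd_matrix()` assembles cohort matrices: within-season (all ordered pairs
i ≠ j, so n individuals give n(n−1) comparisons — 2970 at n = 55) and
cross-season (each bird's post vs pre route, plus all ordered
among-individual post-of-i vs pre-of-j pairs).

## Permutation inference

**Linear models.** Covariate collinearity is reduced before fitting:
responses affected by a significant factor are *group-centred* (per-group
mean subtracted), and covariates entangled with earlier ones are
*residualized* (least-squares residuals on the conditioning terms).
`vif()` verifies the result (the designs used here stay below 1.8).
`permutation_lm()` computes sequential (type-I) F statistics in formula
order and builds each term's null by the Freedman–Lane scheme: residuals
of the model containing the *preceding* terms are permuted and added back
to that model's fitted values. Sequential sums of squares match the
convention of ordering covariates from design factors to adjusted
covariates; the Freedman–Lane scheme is the standard choice for
multi-term permutation ANOVA and is what general-purpose permutation
ANOVA software implements. P-values use the add-one convention
(1 + #{F* ≥ F})/(1 + B), so the smallest attainable p is 1/(B+1).

**Paired post/pre comparisons.** Each individual contributes one value per
migration period. With exactly two observations per individual, a random
intercept plus random season slope is not identifiable beyond a single
paired covariance, so the model is fitted as a compound-symmetry paired
LMM by maximum likelihood. The implementation uses the orthonormal
pair-difference/pair-sum transform, which turns the ML problem into a
two-block heteroscedastic regression solved by a small fixed-point
iteration — important because the permutation test refits the model
thousands of times (the ML fit is cross-checked against `nlme::lme` in the
test suite). Significance of each term is the likelihood-ratio statistic
against the model without that term, ranked in a null built by a two-step
shuffle that preserves the paired structure: (1) post/pre values are
randomly swapped within individuals; (2) each individual's (possibly
swapped) value pair is reassigned en bloc to another individual.
Likelihood-ratio differences below 1e−7 are treated as exact ties at zero
(fixed-point convergence noise).

**Route-consistency tests.** Both OWD tests are one-sided, matching the
directional claims they address. `owd_within_vs_among_test()` asks whether
birds keep private corridors across seasons: statistic mean(within) −
mean(among), null built by permuting which pre-route belongs to which
individual. `owd_season_spread_test()` asks whether pre-breeding routes
scatter more than post-breeding ones: statistic mean(pre pairwise) −
mean(post pairwise), null built by independently flipping each
individual's post/pre labels — which mixes seasons, so the test consumes
the cross-season OWD values as well as the two within-season matrices.

**Carry-over slopes** are compared against 1 (full transmission of a delay
to the next stage) with `slope_vs_one_test()`: t = (slope − 1)/SE on the
model's residual df.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes, so that the pipeline can be validated by parameter
recovery. It emulates:

* three breeding areas (colonies at 46°09′N 8°55′E; 45°33′N 8°44′E;
  45°19′N 9°40′E) with a 38/30/15 area mix, deployment years in a
  58/23/2 ratio (the small third-year contingent exercises the year
  exclusion), and a 1:1 sex ratio;
* winter quarters centred near 4.5°N 12.3°E (per-axis sds 3.6° and 5.1°,
  matching the cohort-level spread implied by reported standard errors),
  with ≈4/85 southern outliers (males only, main SP south of 10°S, centred
  near 24°S 24°E) and ≈8/85 itinerants (two SPs 300–900 km apart separated
  by a 5–15 day gap; southern outliers are itinerant with probability
  0.75);
* a clockwise loop: a southbound template through Corsica–Sardinia–Tunisia
  and the central Sahara, and a northbound template detouring over the
  Atlantic side of West Africa, Morocco and Iberia (≈7% longer). Each
  individual-season gets a lateral corridor offset (sd 2.0° post, 3.0°
  pre — pre-breeding routes are the more variable season), applied
  perpendicular to the template and tapered to zero at the endpoints;
* a linear-Gaussian carry-over chain with config-exposed slopes: colony
  departure DD_c ~ N(250.8, 6.75²); arrival AD_sp = 0.41·DD_c + ε (sd 5);
  winter departure DD_sp = 1.0·AD_sp + ε (sd 9); spring speed
  MS_prb = 296 + 5.12·(DD_sp residual) + ε (sd 40). Zeroing the slopes
  yields null cohorts for calibration tests;
* observation noise: independent Gaussian per fix, latitude sd above
  longitude sd. The cohort default (0.3°/0.15°) represents
  particle-filter-smoothed position output; `add_observation_noise()`
  defaults to 1.5°/0.7°, the scale of raw twilight-fix error. Route
  wobble (0.15° per fix) and daily residency scatter (0.35°) are separate
  knobs;
* season availability as a single categorical draw per individual
  (both/post-only/pre-only/none = 58/15/2/10 of 85), which reproduces all
  four margins of the cohort composition it emulates, rather than
  independent per-season missingness (which could not match them all).

Template geometry and noise scales were fixed once so that cohort-level
means sit near the field-typical values the package documents (post LMP
≈5600 km at PS ≈83%, pre LMP ≈6400 km at PS ≈72%, MS ≈190/310 km/day) —
they are scenario fixtures, not estimates. Within a migration episode the
travel speed is constant (fixes equally spaced in arc length): GLS studies
rarely constrain the within-route speed profile, and a constant profile
keeps LMP/DM/MS relationships transparent. What the generator does *not*
emulate: raw light curves and twilight annotation, spatially or temporally
autocorrelated position errors, wind and resource fields, stopover/travel
day alternation, and route curvature beyond the template-plus-offset
family. Passing recovery tests therefore demonstrates the pipeline's
correctness under idealised GLS-like conditions, not robustness to every
pathology of real geolocation.

## Validation summary

The test suite (and `scripts/acceptance.R`) validates, among others:

* great-circle and path-length geometry against closed-form oracles
  (spherical law of cosines; 1° meridian arcs), including the ≈174 km
  displacement corresponding to 1.56° of latitude;
* OWD against a brute-force k × k implementation to 1e−9 relative on 100
  random pairs, plus self-distance, reversal invariance, translation
  monotonicity and per-point k-stability;
* comparison-count bookkeeping (55 complete individuals → 2970
  among-individual ordered comparisons);
* the identities MS·DM = LMP (machine precision) and PS ≤ 100 on a
  200-individual cohort;
* type-I calibration of `permutation_lm()` (1000 null replicates) and
  `paired_two_step_perm()` (500 null replicates) at α = 0.05 with
  B = 200 permutations — rejection rates fall in [0.035, 0.065];
* carry-over slope recovery at n = 200 (100 replicates): 95% CIs cover the
  generating slopes in ≥90 replicates, estimates unbiased;
* loop-structure detection: with pre-season corridor scatter twice the
  post-season value, `owd_season_spread_test()` is significant at α = 0.05
  in ≥95 of 100 cohorts of 40;
* an exact round-trip: a zero-noise cohort pushed through feature
  extraction returns the generating DD/AD/SP centres (to the mode grid)
  and itinerancy flags.

These problem sizes (cohorts of 40–200; 100–1000 Monte-Carlo replicates;
B = 200 for calibration, B = 2000 elsewhere in scripted runs) were chosen
to keep the full validation run in the minutes range while leaving
Monte-Carlo error well inside the asserted bands; production analyses
should use B = 10000 (the package default), which is the convention for
permutation tests of this kind.

## Known limitations

* Linear boundary interpolation and degree-space lateral offsets are
  planar approximations, appropriate at daily step lengths and mid
  latitudes but not near the poles or the antimeridian.
* The compound-symmetry paired model is an approximation to the
  (unidentifiable) random-slope formulation; with two observations per
  individual it is the richest honest structure, but it cannot represent
  season-specific between-individual variance.
* OWD values depend on k and on the comparison band; only values computed
  under identical settings are comparable.
* The mode estimator's 0.05° grid bounds the precision of SP centres; SPs
  with fewer than ~10 daily estimates inherit the bandwidth's instability.
* Upstream errors (twilight misclassification, calibration drift) are out
  of scope and not modelled by the generator.
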