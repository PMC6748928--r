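---
title: "Analysing predator responses to carrion subsidies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing predator responses to carrion subsidies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

subsidytrack implements a telemetry-to-statistics pipeline for asking
whether a reliable anthropogenic food source — typified by the livestock
carcass dump (LCD) — changes how a central-place foraging predator uses
space, how active it is, and what it eats. This vignette is the package's
own account of the models it fits, the parameters that matter, the
numerical choices behind them, and the limits of what its synthetic-data
tests demonstrate.

## The cluster detector

A GPS cluster is evidence of prolonged or repeated use of a site: at least
`min_fixes` fixes within `radius` meters inside a `time_window`. Defaults
are 50 m and 24 h with `min_fixes` of 4 (older collars with poorer fix
rates motivate the alternative of 8). Three conventions pin the algorithm
down where the verbal rule is ambiguous:

* **Membership is measured from the seed fix**, not from a running
  centroid. A seed-based rule is order-independent given the chronological
  scan and therefore deterministic; a one-pass re-collection around the
  final centroid is available behind `cluster_config(recollect = TRUE)`
  for sensitivity analysis, default off.
* **All distance thresholds are closed discs** (`<=`), including the 100-m
  den-exclusion radius and the 50/200-m use buffers, so boundary fixes are
  treated reproducibly.
* **The time window is anchored at the seed's timestamp**: candidates lie
  in `[t_seed, t_seed + 24 h]`.

The greedy scan is validated against an exhaustive brute-force enumeration
(every fix tried as a seed, no vectorisation) on 100 random instances of
up to 50 fixes; the two agree exactly, membership is disjoint, and
lowering `min_fixes` can only add clusters.

Buffer-use counts deliberately include the cluster's own member fixes and
run over the whole season: the LCD vs non-LCD contrast is then "how much
of the animal's total presence concentrated here", which is what the mixed
count model is interpreting. Site classes (den, predation/scavenging, LCD,
undetermined, bed/rendezvous) are field determinations supplied as labels;
for synthetic data `label_clusters_from_truth()` plays the field crew's
role using the simulator's ground-truth site list.

## The dynamic Brownian bridge movement model

The UD estimator conditions on consecutive fixes rather than treating them
as independent points. For a fix pair separated by Δt, the bridge at
fraction α is an isotropic bivariate normal with variance

    Δt α (1 − α) σ²ₘ + (1 − α)² δᵢ² + α² δᵢ₊₁²

with σ²ₘ the Brownian motion variance in m²/s and δ the per-fix location
error sd in meters per axis. δ comes from the collar's dilution of
precision as DOP × UERE (default UERE 5 m, default 20 m when DOP is
missing, floored at 1 m). No collar manual gives a joint
satellites-and-DOP error formula, so only DOP enters; the stand-in is
isolated in `assign_error()` and easy to replace.

**Estimation.** σ²ₘ has no closed-form estimator; the package uses the
leave-one-out profile likelihood: every second interior fix is predicted
from its two neighbours (so consecutive terms share no centre fix), and
the likelihood is maximized by golden-section search on log σ²ₘ over
`sigma_grid` (default 1e-8 to 1e6 m²/s, termination at 1e-4 on the log
scale). The log parameterisation keeps the search scale-free across the
twelve orders of magnitude; with all fixes coincident the optimum
collapses to the lower bound, which is the correct zero-motion limit.
Predicted variances are floored at 1e-12 m² to keep the likelihood finite
when both motion variance and location error vanish.

**The dynamic part.** A 25-fix window slides one fix at a time; within
each window a one-variance model competes against two-variance models
with a breakpoint at any position leaving an 11-fix margin on each side
(positions 12–14 in the default geometry). Selection is by BIC with n the
number of leave-one-out terms in the window; one breakpoint at most. Both
segments of a breakpoint model are scored on the *same* term set as the
no-breakpoint model, with each term assigned to a segment by its centre
fix — scoring segments on their own interior terms would compare
likelihoods over different data and break BIC comparability. The winning
model's variances are recorded for the window's central fixes; a fix's
final σ²ₘ is the mean over all windows covering it, and the first/last
`margin` fixes inherit the nearest interior value. On homogeneous
Brownian tracks the breakpoint model wins under 20% of windows (the BIC
penalty guarding against overfitting); on a track whose σ²ₘ jumps from
0.05 to 2.0 m²/s the profile recovers the ordering. Forcing one window
over the whole track with breakpoints disabled reproduces the single
global estimate exactly — the static model is a special case, which the
tests assert.

**Integration.** Each bridge with Δt ≤ `max_bridge_gap` (default 3600 s,
four nominal fix intervals: bridges across long dropouts assert more than
the data support, so they are skipped and logged) is evaluated at 1-min
midpoint steps; each evaluation deposits a separable Gaussian kernel on
the 30-m raster, truncated at 4.5 sd (mass beyond that is below 3e-5 and
the final normalization absorbs it). A kernel narrower than a cell
(6 sd < cell) is deposited on its containing cell rather than sampled at
cell centres, which would lose it entirely. The pair's σ²ₘ is the mean of
its endpoint values — the method is silent at pair level and the mean is
the symmetric choice. The grid covers the fix bounding box padded by
three maximal bridge standard deviations, with the origin snapped to the
cell size so equal inputs give equal grids.

**Isopleths** take cells in decreasing probability until the target mass
(0.99 for home range, 0.50 for core area) is reached; area is the cell
count × cell area, and the polygon is the union of the selected cell
squares. No contour interpolation: areas are bit-reproducible and
monotone in the level by construction. Ties in cell probability resolve
by cell index order, a stable tie-break that only matters on exactly
uniform UDs. The UD-mass placement is stable under sub-cell origin
shifts (50% isopleth changes by at most 2 cells on smooth fixtures).

Minimum convex polygons use the convex hull with shoelace area;
containment (used for checking depredation records against resident
ranges) counts the boundary as inside. Residency itself is a field
judgment — association with other collared animals, return after
extraterritorial moves — and is therefore an input flag, never inferred.

## Activity and tortuosity

Activity is the sum of the 5-min x- and y-axis accelerometer means;
records within ±450 s (closed) are averaged onto each 15-min fix, so a
fix normally sees three records. The active threshold 30.8 is strict
(`> 30.8`), matching its calibration as a lower bound for activity;
fixes with no records in the window are inactive-with-flag rather than
dropped, so downstream segment logic sees a complete vector.

Tortuosity is the mean **absolute** relative turning angle — the signed
difference between the bearings of consecutive steps wrapped to
(−180°, 180°], with a full reversal mapping to +180°. Absolute values are
deliberate: signed relative angles average toward zero on any long path,
so only the magnitude carries the "more tortuous" ordering the summary is
meant to express. An interior fix contributes only when it and both
neighbouring fixes are active ("daily activity bouts" are taken to be
maximal active-classified runs; no further bout-splitting rule is
imposed). Zero-length steps have undefined bearings and are skipped with
a log message. Rotation invariance holds to 1e-9.

## Diet from scats

The wolf/coyote diameter cut-off is the first quartile of track-verified
wolf scat diameters under the linear-interpolation convention
h = (n − 1)·0.25 + 1 on the sorted sample — quartile definitions differ
across software, so the convention is fixed and documented, and the
unrounded value is returned (callers may round; the conventional field
rule rounds to the millimetre). Classification: tracks dominate;
otherwise diameter ≥ cutoff is wolf — the exclusion rule is "strictly
below", so the boundary passes. Composition tables average per-scat
percent volumes over wolf-classified scats only, zeroing trace entries
(≤ 1%) first, because trace items are not identified to species and so
cannot contribute volume; unknown scats are excluded, never imputed.
`misclassification_rate()` quantifies the cost of the cut-off as the
Monte-Carlo tail mass of the coyote diameter distribution above it,
matching 1 − Φ((cutoff − μ)/σ) within simulation error.

## Comparative statistics

Welch's unequal-variance t with Welch–Satterthwaite degrees of freedom is
provided both from raw samples and from published summary statistics
(mean, SD, n per group) — the summary form is what makes printed tables
checkable. Tests are one-sided with the direction an explicit argument,
mirroring directional hypotheses like μ_subsidy − μ_no-subsidy < 0; the
sample SD uses n − 1 throughout.

Buffer-use counts are modelled as Poisson with log link, cluster type
(LCD vs non-LCD) as the fixed effect and animal identity as a random
intercept, fitted by Laplace-approximated maximum likelihood via
`lme4::glmer`. Poisson is the natural first family for bounded-buffer
location counts; a negative-binomial switch (`family = "nb"`) is exposed
for overdispersion, default off. With no animal heterogeneity the mixed
fit agrees with plain Poisson regression in the LCD coefficient to 1e-6,
and on simulated data with a known effect of 0.6 on the log scale the
estimate lands within two standard errors while null data keep |z| < 1.96
in at least 90% of replicates.

## What the synthetic data emulate — and what they do not

`simulate_track()` generates one animal-season from a four-state
semi-Markov process (exponential dwells) with den-centred structure:

* **DEN_REST** emits den + 15 m Gaussian scatter — attendance at a focal
  site, the central-place anchor.
* **TRAVEL/FORAGE** emit a correlated random walk: gamma step lengths
  (shape 2; mean 400 m and 150 m per 15-min interval respectively),
  wrapped-Cauchy turning errors with concentrations 0.8 and 0.4, and a
  pull (weight 0.5 travel, 0.2 forage) toward an episode target — the den
  or a waypoint inside `ranging_radius`.
* **SITE_VISIT** emits positions within 30 m of a site, an LCD with
  probability w/(1 + w) given attraction weight w, otherwise a random
  kill site; entering a visit jumps to the site, a deliberate
  simplification (the preceding travel is not routed through it).

Accelerometer records follow their own 5-min schedule: rest-like states
draw activity around 12 (sd 6), active states around 60 (sd 15), each
axis truncated at 0. These emissions are separable at the 30.8 threshold
(rest exceedance below 1%, active exceedance above 97%), chosen so that
the classifier's behaviour, not emission overlap, is what the tests
exercise. GPS error is DOP × UERE with DOP uniform on [1, 4] and UERE
5 m (5–20 m error sd, the plausible open-sky collar range); fixes drop
out independently at 5% — no fix-success rate is published for the
source collars, so this is a documented guess held fixed. Diameter
truncation at 5 mm and activity truncation at 0 prevent physically
impossible values.

The two scenario presets encode the study contrast as generator defaults:
LCDP-like animals (attraction 5, ranging radius 2 km, travel steps 250 m,
dwells favouring rest and site visits) against LCDA-like animals
(attraction 0 over the same LCD coordinates, radius 4 km, steps 500 m,
more travel). The radii bracket the km-scale ranges reported for wolves
with and without subsidy access; under them the directional predictions —
smaller 99% UD, more fixes within 200 m of an LCD, lower mean activity
for the subsidy group — hold in every seeded replicate pair the
acceptance tests run.

What the generator does **not** emulate: pack social dynamics or
multi-animal interaction (one animal per call), habitat selection or
roads, serially correlated GPS error, collar duty-cycle changes,
seasonal drift in behaviour, or travel that approaches a site before
visiting it. Passing tests therefore demonstrate that the estimators
recover the structure this process encodes — not that field data meet the
process's assumptions.

Reproducibility is strict: each simulator call seeds its own generator
(restoring global RNG state afterwards), identical configs give
bit-identical outputs, and the pipeline manifest records the seed and a
config hash so a rerun can be checked file-by-file.

## Problem sizes and runtime choices

The test suite and acceptance checks are sized for a single CPU: 6–10
simulated days per animal (≈ 600–1,000 fixes) for trajectory-level
checks, 5 replicate scenario pairs for the directional comparisons,
501-fix tracks for motion-variance recovery (within 20% of truth),
10 animals × 20 clusters for effect recovery and 50 replicates for the
null-size check of the mixed model, and 1,000 × 151 draws for the
diameter cut-off recovery. These sizes keep every stage's sampling error
comfortably inside the asserted tolerances; scaling `n_days` or replicate
counts up tightens nothing qualitative.

## Known limitations

* The isopleth is a union of raster cells; its area converges to the
  smooth-UD area only as the cell size shrinks relative to the UD's
  features. At the 30-m default this is negligible for km²-scale ranges
  but matters for core areas a few cells wide.
* One breakpoint per window caps how fast the motion variance can be
  tracked; rapid multi-switch behaviour within 25 fixes is smoothed.
* The LOO estimator uses every second interior fix, halving the terms to
  keep them non-overlapping; very short runs (< 25 fixes) fall back to a
  single global variance.
* `fit_buffer_glmm` models each radius separately; counts at nested radii
  from the same cluster are correlated and should not be pooled into one
  fit.
* Welch tests from published summaries can only be as consistent as the
  summaries themselves; the package reports what the formula gives and
  does not adjust toward any printed statistic.
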