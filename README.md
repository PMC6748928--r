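# subsidytrack

Movement, space-use and diet analysis of GPS-collared predators around
anthropogenic food subsidies such as livestock carcass dumps (LCDs) —
open-pit sites where livestock carcasses are discarded and where facultative
scavengers like wolves (*Canis lupus*) can feed reliably. The package is
aimed at movement ecologists who want to test whether access to such a
subsidy compresses an animal's home range, concentrates its site use,
lowers its activity, and shows up in its diet.

## What it computes

* **Spatiotemporal GPS clusters** — aggregations of ≥ *k* fixes within a
  50-m radius of a seed fix within 24 h, scanned greedily in time. Clusters
  flag kills, carcass dumps, dens and beds; site classes are field labels
  attached afterwards, never inferred. Den-adjacent clusters (≤ 100 m) are
  excluded from use analyses, and GPS-location counts within 50-m and 200-m
  buffers of each cluster centroid quantify use.
* **Dynamic Brownian bridge movement model (dBBMM) home ranges.** Between
  consecutive fixes *z*ᵢ, *z*ᵢ₊₁ separated by Δ*t*, the position at fraction
  α is bivariate normal with mean (1−α)*z*ᵢ + α*z*ᵢ₊₁ and variance
  Δ*t* α(1−α) σ²ₘ + (1−α)² δᵢ² + α² δᵢ₊₁², where σ²ₘ is the Brownian motion
  variance (m²/s) and δ the per-fix location error (DOP × UERE). σ²ₘ is
  estimated by leave-one-out likelihood in sliding 25-fix windows with an
  11-fix margin and a BIC-selected behavioural breakpoint per window. The
  utilization distribution (UD) is integrated on a 30-m raster at 1-min
  time steps; the home range is the 99% isopleth and the core area the 50%
  isopleth. 100% minimum convex polygons support spatial containment
  checks (e.g. for depredation records).
* **Activity and tortuosity** — collar accelerometer x+y means per 5-min
  period, aligned to fixes (±450 s) and classified active when strictly
  above 30.8 (unitless); tortuosity is the mean absolute relative turning
  angle along active path segments.
* **Diet from scats** — the wolf/coyote diameter cut-off is the first
  quartile of track-verified wolf scat diameters; track evidence dominates,
  scats at or above the cut-off classify as wolf, and percent-by-volume
  composition is averaged per study area with trace (≤ 1%) items zeroed.
* **Comparative statistics** — one-sided Welch two-sample tests (from raw
  samples or published summary statistics, Welch–Satterthwaite df) and a
  Poisson log-link mixed model of buffer-use counts with cluster type
  (LCD vs non-LCD) as fixed effect and animal as random intercept (lme4).
* **A synthetic telemetry generator** — a seeded four-state semi-Markov
  movement process (den rest, travel, forage, site visit) with optional
  LCD attraction, state-dependent accelerometer emissions separable at
  30.8, per-fix GPS error and fix loss, plus scat-diameter and Dirichlet
  composition simulators — so the whole pipeline runs end-to-end with
  known ground truth and no field data.

## Worked example

```r
library(subsidytrack)

# one subsidy-exposed animal, 8 days of 15-min fixes
sim <- simulate_track(scenario_config("LCDP", seed = 11, n_days = 8), "W01")
sim$trajectory
#> <trajectory> animal W01: 743 fixes, 2010-05-01 00:00 to 2010-05-08 23:45

cl <- detect_clusters(sim$trajectory, cluster_config(min_fixes = 4, radius = 50))
cl <- label_clusters_from_truth(cl, sim$truth)
cl <- exclude_near_dens(cl, list(c(0, 0)))
#> 22 cluster(s) within 100 m of a den excluded
table(cl$site_class)
#> BED_RENDEZVOUS            LCD
#>              3              1

home_range_dbbmm(sim$trajectory)
#> <home_range_result> animal W01: 99% UD 3.632 km2, 50% UD 0.008 km2

use <- buffer_use_counts(sim$trajectory, cl)
aggregate(count ~ is_lcd + radius, use, mean)
#>   is_lcd radius     count
#> 1  FALSE     50  4.333333
#> 2   TRUE     50 27.000000
#> 3  FALSE    200 10.666667
#> 4   TRUE    200 29.000000
```

The animal's season is dominated by den attendance (the 22 excluded den
clusters), its 99% home range is a few km² — compressed around den and
subsidy — and its fixes pile up around the LCD cluster relative to other
sites, the pattern the buffer-use mixed model is designed to test.

Published group summaries can be compared directly:

```r
welch_from_summary(31.14, 14.03, 6, 58.34, 21.60, 10, "less")
#> Welch two-sample test (one-sided, less)
#>   t = -3.051, df = 13.81, p = 0.00437
```

`run_pipeline(run_config(seed = 1, outdir = "out"))` chains every stage —
simulation, clusters, home ranges, metrics, diet, statistics — into a CSV
report bundle with a manifest; identical configs reproduce identical files.

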