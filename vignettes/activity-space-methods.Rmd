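---
title: "Activity-space measures from smartphone GPS logs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-space measures from smartphone GPS logs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activityspace)
```

## The problem

Mobile-health (mHealth) studies increasingly collect passive GPS traces
alongside ecological momentary assessment (EMA) — participants' real-time,
self-initiated reports of health behaviors such as alcohol use, smoking, or
condomless sex. Two questions follow naturally: how mobile are participants
(their *activity space*), and where do reported behaviors happen relative to
home? This package implements a complete, tested pipeline for both, designed
around data logged every 1–2 hours by a smartphone app, a home coordinate
per participant from household enumeration, and time-stamped behavior
reports.

The pipeline computes three mobility measures per participant:

1. **Average distance traveled per week** — great-circle (haversine)
   distances between consecutive fixes, totaled over the observation period
   and divided by weeks of observation. A weekly average is used rather than
   daily centrality because day-of-week patterns (e.g., staying home on
   Sundays) bias daily summaries.
2. **Unique locations visited** — fixes deduplicated within 25 m of one
   another, reflecting typical smartphone GPS accuracy of 5–20 m.
3. **Percent of fixes away from home** — fixes dichotomized against
   circular home buffers of 100 m (the home itself, allowing for GPS error
   and physical landscape) and 400/800 m (home neighborhoods that may
   include neighbors, shops, and transit stops).

Behavior reports are linked to the nearest-in-time GPS fix and summarized as
the number of unique locations where each behavior occurred and the number
of reports away from home at each buffer radius. Cohort tables report
median (IQR) and range across participants, and counts/percentages of
reporting participants with one vs. two-or-more behavior locations and with
any away-from-home report.

## Geodesy

All distances are haversine great-circle distances on a sphere of radius
6371.0088 km (the IUGG mean Earth radius), exposed as `EARTH_RADIUS_KM`.
Two numerical choices matter:

* The haversine form `2R·asin(√a)` is used instead of the spherical law of
  cosines because it is numerically stable at the meter scales the 25-m
  deduplication operates on; the law of cosines serves as the independent
  oracle in the test suite, where the two agree to better than 1e-6 km.
* Home buffers are nominally "Euclidean" circles, but at 100–800 m the
  planar and great-circle distances differ by far less than a centimeter,
  so the spherical distance is used uniformly. This avoids configuring a
  projection zone with no measurable effect on any output.

A fix exactly on a buffer boundary counts as **inside** ("outside" means
strictly greater than the radius). Some fixed rule is required; the choice
has measure-zero effect on real data.

## Unique-location deduplication

"Deduplicated points within 25 m of one another" admits several readings
(complete-linkage clustering, grid snapping, greedy absorption). The package
uses a **greedy first-seen-representative** pass in chronological order: the
first fix founds the first location, and each later fix founds a new
location if and only if it is at least 25 m from *every* existing
representative; otherwise it is absorbed. This is deterministic, order
stable, and matches the plain reading of deduplication. The radius is
configurable (`dedup_radius_m`). Because the pass is order dependent,
reports are always processed in timestamp order when the same rule is
applied to behavior locations, making results reproducible. The count is
bounded above by the fix count and below by 1, and agrees with an
independent brute-force re-implementation on randomized instances in the
test suite.

## Report–fix linkage

Each behavior report links to the trajectory fix minimizing the absolute
time difference. A tie between an earlier and a later fix resolves to the
**earlier** fix: the behavior precedes its report, so the earlier fix is the
better guess, and the rule is deterministic. Linkage happens after region
filtering, so a report can never attach to an excluded fix. No maximum gap
is enforced — participants were instructed to report within an hour, but a
phone that was off can produce large gaps — instead `gap_seconds` is always
recorded and an optional `max_gap_hours` threshold flags (never drops)
suspect links. Reports against a participant with no retained fixes are
linkage failures: excluded from location measures and counted in the run
log.

## Region filter

Fixes far outside the study region (international travel, device
malfunction) are removed before any measure is computed. "Sub-Saharan
Africa" has no canonical operational boundary, so the default is a generous
bounding box, lat ∈ [−35, 20], lon ∈ [−20, 55], chosen to keep any
plausible in-region travel while excluding other continents; it is fully
configurable (`region_bounds()`) and every excluded fix is written to
`excluded_points.csv` with a reason. The filter is a partition: every input
fix lands in exactly one of kept/excluded.

## Weekly denominator and observation days

An *observation day* is a UTC calendar date with at least one retained fix.
The weekly distance denominator is `observation_days / 7` by default —
observation days are what cohorts report per participant, and gap days
(phone off) carry no distance information — with `calendar_span`
(`(last − first + 1) / 7`) available as a configurable alternative for
sensitivity analyses. Timestamps are stored and compared in UTC throughout;
ISO-8601 offsets in input files are honored and normalized, avoiding
DST/locale ambiguity.

Duplicate timestamps for one participant are collapsed to the first row in
file order, with a warning; out-of-order rows are sorted. Both policies are
deterministic and order stable.

## Cohort summaries

Quantiles use linear interpolation between closest order statistics
(`stats::quantile` type 7, the default in mainstream numeric stacks);
published tables rarely state their quantile convention, so ours is fixed
and documented. Percentages in the behavior tables are computed from exact
counts at output time; all CSVs retain full precision and any rounding is
left to presentation.

Participants with zero retained fixes are excluded from cohort tables and
listed in the run log. A behavior with no reporting participants is simply
absent from the behavior tables.

## The synthetic cohort generator

The study data this pipeline is designed for are not publicly deposited, so
the package ships a generator (`sim_config()`, `simulate_cohort()`) that
emulates the data's *structure* with exact ground truth. It is deliberately
a controllable mixture, not a mechanistic mobility model:

* **Homes** are placed uniformly on a disc (default 30 km radius) around a
  region center in south-central Uganda.
* **Fixes** are generated day by day with uniform 1–2 h gaps (≈12–23
  fixes/day). Each fix is at home with probability `p_home` (Gaussian
  jitter, σ = 20 m per axis, emulating GPS error), otherwise displaced from
  home by a uniform bearing and a distance of 0.2 km plus an exponential
  with mean `local_radius_km` — or, on trip days (probability
  `p_trip_day`), placed at that day's long-trip destination 50–250 km away.
  Because away fixes are always ≥ 200 m from home and at-home jitter
  essentially never exceeds 100 m, the generated `at_home` flag is exact
  ground truth for the 100-m classification, and the pipeline's
  percent-outside recovers `1 − p_home` to binomial precision.
* **Behavior events** are anchored to a generating fix whose at-home status
  is drawn per behavior (`p_behavior_home`), and the report is stamped a
  uniform 0–30 min after that fix — under half the minimum fix gap, so
  nearest-timestamp linkage provably recovers the generating fix and the
  report-level ground truth is exact. Report counts are Poisson with
  per-week rates per behavior.
* **Geodesic placement** inverts the pipeline's own distance metric
  (bearing + distance on the same sphere), so generated distances are exact
  under the pipeline's measure.
* Each participant's random stream derives from `(seed,
  participant_index)`, so cohorts are reproducible and participants are
  independent — adding participants never perturbs existing ones.

Default parameters are fixed once to the study conditions: 46 participants,
45–90 observation days, 1–2 h cadence, `p_home = 0.1` (cohorts of this kind
spend ~90% of fixes outside the 100-m home buffer), local excursions with a
3-km mean, 15% trip days at 50–250 km, and behavior rates of 0.4–1
reports/week with home-probabilities of 0.3–0.5.

What the generator does **not** emulate: device-specific logging bursts
(real cohorts show up to ~31 fixes/day, above the ≤ 23 a strict 1–2 h
cadence allows), spatially correlated day-to-day routines, road-network
travel (straight-line displacement only), and missingness beyond an
optional whole-day dropout (`p_day_off`, off by default). Passing tests on
synthetic data therefore validate the *measurement pipeline* — distances,
deduplication, classification, linkage, aggregation — not the realism of
any mobility model.

## Problem sizes used in validation

The shipped validation suite exercises: the geodesy oracle on 10,000 random
coordinate pairs; the deduplication oracle on 500 random 200-point
trajectories; linkage against exhaustive scan on over 1,000 report
instances including engineered ties; monotonicity of buffer measures on a
12-participant simulated cohort; recovery of a known 70% away-from-home
fraction across 46 participants with ≥ 1,000 fixes each (99% binomial
interval, at least 44/46 within); an 80,131-fix cohort with 34 injected
out-of-region outliers filtered exactly; and byte-identical outputs across
repeated pipeline runs. These sizes were chosen to match the scales the
pipeline targets in practice.

## Known limitations

* Great-circle distance between successive fixes underestimates true travel
  along roads; with 1–2 h cadence the measure is a lower bound on distance
  traveled.
* The greedy unique-location count depends on visit order by construction;
  a different (e.g., clustering-based) reading of deduplication would give
  different counts. The choice is documented and configurable in radius but
  not in algorithm.
* The bounding-box region filter is a stand-in for a geographic boundary;
  studies needing a political border should supply their own bounds.
* No dwell-time/stay-point detection, kernel-density or convex-hull
  activity-space estimators, or inferential statistics are provided — the
  pipeline counts and summarizes, by design.
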