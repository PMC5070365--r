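---
title: "Measuring rural physician accessibility by car and public transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rural physician accessibility by car and public transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruralaccess)
```

## The problem

In sparsely populated rural regions, health-care providers are few and
catchment areas are large. For the growing elderly population — with higher
morbidity, higher utilisation of general practitioners (GPs), specialist
internists, ophthalmologists and urologists, and frequently no car of their
own — the question is not only *how far* the nearest practice is, but
whether it can be reached at all by public transport within a day built
around a late-morning appointment. `ruralaccess` implements both sides of
that question as a reproducible pipeline:

* **by car** — street-network travel times from district centre points to
  the nearest practice of each physician group, summarised into 5-minute
  service-area bands;
* **by public transport** — timetable-exact round trips (outbound before an
  11:00 appointment, return after it) with walking access, egress and
  transfers, flagging districts with *no connection*;
* **tabulation and comparison** — district and inhabitant shares per
  travel-time band, Kruskal–Wallis comparison of the four physician groups
  with an all-pairs post hoc, and Thiessen-polygon map layers.

Because the street, population, practice and timetable data of such studies
are proprietary, the package ships a seeded synthetic-region generator that
reproduces their structural properties; every analysis below runs on data
the package itself can regenerate from a single integer seed.

## The synthetic region

`generate_region()` builds, deterministically from a `region_config()`:

* **Districts.** `n_districts` centre points anchored to street nodes inside
  the core rectangle. Populations are drawn log-normally
  (`population_skew`, default sigma 1.6 — a few dominant towns, many small
  villages) and largest-remainder rounded so they sum *exactly* to
  `total_population`. The full-scale defaults (464 districts, 239,102
  inhabitants on ~84 × 47 km) mirror the size of a rural north-east German
  county; they are a realistic scale, not a reconstruction of any real
  geography.
* **Streets.** A 1 km lattice with jittered nodes; edges carry length,
  a speed class and a one-way flag. A random spanning tree is kept intact
  and ~20 % of the remaining edges are pruned, so the network is connected
  but not grid-regular. Two full rows and columns form 100 km/h trunk
  lines (motorway-like barriers crossable only at junctions); ~30 % of other
  edges are 70 km/h rural roads, the rest 30 km/h local streets. One-way
  flags are restricted to non-tree edges, which keeps the directed car
  graph strongly connected by construction. Coordinates are planar metres
  in an arbitrary projected frame — at county scale nothing is gained from
  geodesy, and the original analyses also work in a projected GIS frame.
* **Practices.** Specialists are sampled into the highest-population
  districts (the "towns", top 5 % by population, population-weighted);
  GPs cover every specialist town and are then spread population-weighted
  across the villages. Each group also receives practices in the buffer
  ring (default 15 km) around the core, because patients near the border
  consult providers beyond it; buffer practices compete on equal terms.
* **Timetable.** Routes are chains of districts (a population-weighted
  starting town, then greedily the nearest not-yet-served district), whose
  street path gets stops every 400–800 m; street edges are subdivided so
  every stop lies exactly on a network node. Two service-day tags exist —
  `school` (half-hourly pattern base `headway_min` from 06:30 to 19:00)
  and a sparser `vacation` service at twice the headway — reflecting that
  rural public transport is organised around school traffic. The analysis
  day is a school-day Tuesday.

What the generator does **not** emulate: real road geometry and turn
restrictions, time-of-day car speeds, demand-responsive services, fares and
vehicle capacity, or the municipality-to-district aggregation step of real
population registers. Passing tests on generated regions therefore
demonstrate correctness of the *methods* under structurally realistic
conditions, not calibration to any particular real region.

## Accessibility by car

The car graph weights every directed edge with free-flow seconds
`3.6 · length_m / speed_kmh`; one-way edges get a single direction.
Dijkstra shortest paths (via igraph) from each district centroid — snapped
to the nearest street node within 500 m, a tolerance the generator always
satisfies — give the OD cost matrix to all practices. Both the minutes and
the kilometres of a pair are measured along the *time*-optimal path; a
separately distance-optimal route is not computed (with a single OD pass
producing both units, this is the natural reading, and it is stated here as
a deliberate choice).

`nearest_practice()` takes the arg-min over a group's practices (ties:
smaller distance, then lexicographic id), `band_assign()` places minutes
into half-open bands `[0,5), [5,10), …, ≥20` — a ride of exactly 5 minutes
belongs to "5 to <10", which is what the band wording "5 to <10" dictates —
and `summarize_group()` reports mean, sample standard deviation (n−1) and
maximum. No congestion, rush hours, construction sites or parking-search
time are modelled.

## Accessibility by public transport

The model assumes an elderly patient:

| parameter | default | meaning |
|---|---|---|
| `walk_speed_kmh` | 1.8 | half the commonly assumed 1 m/s pedestrian speed |
| `max_walk_origin_to_stop_m` | 1000 | centre point → boarding stop |
| `k_access_stops` | 3 | nearest stops considered (the nearest stop need not give the fastest connection) |
| `max_walk_stop_to_practice_m` | 500 | alighting stop → practice |
| `max_walk_transfer_m` | 250 | between stops at a vehicle change |
| `max_walk_origin_to_practice_m` | 1000 | direct walk fallback |
| `earliest_departure` | 07:00 | patient leaves home no earlier |
| `appointment_time` | 11:00 | school-day Tuesday appointment |
| `appointment_duration_min` | 60 | never part of travel time |
| `return_earliest` | 12:00 | return leg starts no earlier |
| `latest_home_arrival` | 24:00 | must be home by midnight |

The timetable becomes a **time-expanded graph**: nodes are (stop, scheduled
time) events; ride edges join consecutive stop events of a trip, wait edges
chain the events of one stop, and transfer edges jump from an event to the
first event of a neighbouring stop reachable after the ≤250 m walk. Every
edge advances the clock, so one forward pass in chronological order
answers earliest-arrival queries.

Queries distinguish two passenger states per event — *alighted* (may leave
for the practice, wait, or take one transfer walk) and *boarding* (may wait
and board). This enforces the footpath structure of the model exactly: one
access walk, at most one ≤250 m walk per vehicle change, one egress walk
after the final ride. Without the two layers, chained stop-to-stop walks
would act as an uncapped walking mode; an exhaustive-enumeration oracle in
the test suite is what exposed this, and the layered search is checked
against that oracle on hundreds of random timetables.

**Objective.** Among all feasible journeys in a window the search returns
one of *minimum duration* (arrival − departure), with boarding timed
exactly, so waiting at home rather than at the first stop; ties prefer the
latest departure, then the fewest boardings. Whether the original analyses
minimised duration or arrival time is not decidable from their description;
duration matches the "travel time" framing of the results and is the
default here, while `count_practice_wait = TRUE` switches the outbound
objective to latest-feasible-departure, which counts waiting at the
practice before the appointment as travel time.

**Round trips.** Outbound in [07:00, 11:00], return in [12:00, 24:00] —
"return starts latest at 12" is read as noon (appointment 11:00 + 1 h),
the only self-consistent reading, with midnight as the home-arrival bound —
and the total excludes the appointment hour. A district's value per group
is the minimum total over that group's practices; `NO_CONNECTION` means no
practice is feasible on both legs. A direct walking round trip within the
1 km cap is admitted as a fallback by default (`allow_walk_only`): the
wording of the ≤1 km origin-to-practice rule is ambiguous, so the minimum
of walking and transit is reported and a flag restores the strict
always-transit reading. On the return leg the 500 m practice-side cap
applies to boarding stops and the district's ≤3 candidate stops to
alighting; the three-nearest-stops rule stays attached to the district end
in both directions.

The region-wide pipeline (`accessibility_by_transit()`) memoises one scan
per distinct boarding event and evaluates all district × practice pairs
from the resulting arrival tables; its results are identical to the
per-pair operations, which the tests verify on small instances.

## Tabulation, statistics, map layers

`zone_table()` counts districts and inhabitants per band (car: 5-minute
bands; public transport: 1-hour bands plus a `NO_CONNECTION` row) and
reports shares both half-up-rounded to integers — the published-table
style, whose columns may legitimately sum to 99–101 — and exactly to one
decimal. Counts always conserve the regional totals exactly.
`zone_table_from_counts()` recomputes the share arithmetic of an existing
printed table from its raw counts; the bundled county table
(`inst/extdata/county_zone_counts.csv`) reproduces, among others, the
80.2 % / 68.2 % / 82.5 % / 93.7 % / 3.8 % shares and the footnoted
integer-sum of 99.

`compare_groups()` runs the tie-corrected Kruskal–Wallis H test
(`stats::kruskal.test`) and an all-pairs post hoc. "A Tukey correction
after Kruskal–Wallis" is not a fully specified procedure, so the default is
the rank-based Nemenyi test using the Studentized range (the standard
Tukey-type analogue on pooled mean ranks, without tie correction in the
variance term), with Dunn–Bonferroni available via `method = "dunn"`.
When all pooled values are identical the degenerate case is reported as
H = 0, p = 1.

`thiessen_polygons()` tessellates the core extent so that each location
belongs to its nearest district centroid — the layer on which band results
are painted. It is built by clipping the extent rectangle against
perpendicular-bisector half-planes, visiting other seeds by distance with
an early exit once no further seed can cut the polygon; duplicate seeds are
an error. A Monte-Carlo nearest-seed oracle and an exact area-conservation
check (relative tolerance 1e-6) back it in the tests.

## Numerical choices and degenerate inputs

* Clock times are integer seconds from service-day midnight; trips past
  24:00 are not modelled (no overnight wraparound).
* Half-up rounding (`round_half_up()`) is used for published-style
  percentages; base R's round-half-to-even would disagree on exact .5.
* Band edges are half-open with the exact break in the upper band.
* Ties in nearest-practice selection break by distance then id; ties in
  journey choice by latest departure then fewest boardings — all
  deterministic.
* Empty service (`n_routes = 0`) yields a valid empty timetable; under the
  strict no-walking-fallback reading every district is then
  `NO_CONNECTION`, while the default fallback still connects districts
  within 1 km of a practice.
* Unsnappable origins/destinations (beyond the 500 m car snapping
  tolerance) are excluded with a warning and listed, never silently
  dropped.

## Problem sizes

The worked examples and the acceptance script use a scaled-down region
(`demo_region_config()`: 100 districts, 50,000 inhabitants, 40 × 25 km,
10 hourly routes, 6 km buffer) chosen so that the complete car + transit +
report pipeline is a matter of seconds while preserving the full-scale
structure: dispersed GPs versus town-clustered specialists, skewed
populations, school-oriented service, and a realistic minority of
unconnected districts. The full-scale default configuration generates and
analyses equally, only more slowly.

## Known limitations

* Turn restrictions, congestion and parking search are out of scope on the
  car side; accessibility there is free-flow.
* The transit model is deterministic and timetable-exact: no delays,
  no fares, no capacity, no demand-responsive services.
* Walking distances are street-network shortest paths; where the street
  generator's lattice is coarse relative to a walking cap, caps bind
  slightly conservatively.
* The Nemenyi post hoc is one defensible reading of "Tukey correction";
  other rank-based procedures could flag marginal pairs differently
  (clear separations agree across methods, as the tests check).
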