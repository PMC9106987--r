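---
title: "Models and methods behind careops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind careops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

careops bundles four ambulatory-care planning models around one routing
substrate. This vignette records the models and their assumptions, the
parameters that matter, what the synthetic-data generator does and does not
emulate, the numerical and design choices made where the problems left
genuine freedom, and the known limits of each component.

## The street-network substrate

A `street_network` is a directed graph in planar meter coordinates. Two-way
streets are stored as two directed edges sharing a street id; every edge
carries a length and a street-class label. Turn restrictions are
forbidden maneuvers: alternating node–edge walks of at least two edges.
`build_network()` splits raw ways at crossings (nodes used by two or more
ways) and, when requested, smooths out interior degree-2 nodes joining two
streets with identical class and one-way attributes, summing lengths;
total network length is invariant under both steps, and restrictions are
remapped onto the surviving edges. Nodes that act as the interior junction
of a restriction are never smoothed away, which guarantees remapping always
succeeds; a restriction whose edges merge onto a single edge is rejected as
unmappable.

Travel time on an edge is `length_m * 3.6 / speed_kmh` under a
`speed_profile` (street class → km/h, one profile per vehicle type). Two
independent implementations answer restriction-aware queries:

- **state mode** (default): a label search over (current edge,
  restriction-progress) states, efficient when restrictions are few;
- **expanded mode**: the equivalent product graph is materialized and
  searched with the same plain Dijkstra used for unrestricted queries.

Restriction progress is tracked by a KMP prefix automaton over directed
edge sequences, so via walks of any length — including self-overlapping
ones — are matched exactly in both modes. The two modes agree to 1e-9 s on
randomized query suites in the tests; this redundancy is deliberate, as the
expanded construction validates the more intricate label search. Dijkstra
breaks ties by ascending node identifier, so returned paths are
reproducible. Unreachable destinations yield an `Inf` duration with
`reached = FALSE`, never an exception. Mandatory-turn restrictions are out
of scope; only forbidden maneuvers are modeled.

Coordinates are planar meters throughout. Callers with geographic data are
expected to project before building the network (an equirectangular
projection about the region centroid is adequate at the scale of a federal
state); the synthetic generator emits planar coordinates directly.

## Speed-profile estimation

Blue-light driving does not follow ordinary car profiles, so
`estimate_speed_profile()` fits one from trips with known durations: route
every trip under the current profile, record the distance driven per street
class, regress observed duration on the class-distance matrix, update the
profile, repeat. The regression is Huber M-estimation
(`MASS::rlm`, tuning constant k = 1.345, no intercept — a trip of zero
length takes zero time), whose coefficients are inverse speeds. Iteration
stops when the maximum relative speed change drops below `tol = 1e-3` or
after `max_iter = 20` rounds; non-convergence returns the last iterate
flagged `converged = FALSE`. Speeds are clamped to ≥ 1 km/h; classes never
driven by any routed trip keep their incoming speed and trigger one
warning. The fixed point is exact on noiseless data, and the Huber loss
keeps class speeds within a few percent under a 10% contamination of
3×-inflated durations (both properties are asserted in the tests at
n = 200 trips).

## The synthetic-region generator

`generate_region()` replaces the confidential data such studies run on:
a jittered grid street network with diagonal shortcuts, a band of `major`
streets every `major_every` rows/columns, and a few forbidden
straight-through maneuvers; municipalities as Voronoi cells of random
nodes; populations as a symmetric Dirichlet(α = 2) split of the configured
total; pharmacies placed proportionally to population; candidate facility
sites, hospitals and depots as node subsets. Counties — needed only for
aggregated response-time maps — are assigned by the coordinate quadrant of
the municipality center. Everything is drawn under one seed with the
caller's RNG state restored afterwards; identical seed and configuration
give byte-identical regions.

Demand streams: `sample_emergencies()` draws homogeneous Poisson arrivals
(rate per day), scene nodes proportional to municipality population,
log-normal on-scene durations (median 20 min, σ = 0.5 by default) and
Bernoulli hospital legs. `sample_transport_day()` draws plannable requests
with pickups uniform in 06:00–18:00, an in-day Poisson stream of ad-hoc
requests with uniform 10–45 min lead times, Bernoulli Covid flags, and a
configured dialysis fraction routed to the nearest hospital.

What the generator does **not** emulate: demographic realism, rush-hour or
weekday seasonality, spatial correlation of demand beyond the population
weights, heavy-tailed service durations, or data errors of the kind real
dispatch archives contain. Tests passing on these regions therefore
demonstrate algorithmic correctness — optimality, feasibility, invariance,
determinism — not predictive validity on real data.

## Vaccination-center location

`solve_center_location()` minimizes
`w_centers·|open| + w_distance·Σ pop·dist_km + w_physicians·Σ physicians`
with single assignment, staffing `physicians ≥ ⌈load/throughput⌉`, and
optional per-site capacities, prefixed assignments and a maximum
assignment distance. Distances are straight-line, in km, between
municipality centers and sites — at national planning scale, street-level
routing adds little to a scenario comparison. The solver enumerates open
sets (up to 16 candidates) and runs a branch-and-bound over assignments
inside each; the physician term prunes correctly because
`Σ ⌈load/throughput⌉` is monotone under adding population to a partial
assignment. The weighted default (`1, 1e-4, 0.1`) makes one center trade
against roughly 10 000 person-km or 10 physicians; since the original
studies do not state their weighting, a lexicographic mode
(fewest centers, then person-distance, then physicians) is provided as the
alternative reading, implemented with true tuple comparison rather than
scaled weights to avoid floating-point collapse. Demand robustness is
handled by evaluation: `evaluate_plan(..., scenarios =)` reports the
worst-case staffing over a finite list of demand vectors; full robust
optimization is out of scope. The choropleth statistic is the
population-weighted lower median of assignment distances.

## Emergency provision: q-Multiset Multicover

`check_coverage()` decides feasibility of an allocation by max flow
(igraph) on source → locations (capacity `q·suppliers`) → incident regions
→ sink (capacity `clients`). Inside the exact solver a mathematically
equivalent min-cut condition — for every region subset, the q-capacity of
its incident locations covers its demand — replaces the flow call for up to
12 regions, purely for speed; the exported checker remains the flow
construction. `solve_qmsmc()` runs depth-first search over supplier counts
per location (descending counts, locations in id order, so cost ties
resolve toward the lexicographically smallest location ids), pruned by
`⌈total/q⌉` and per-region incident-capacity bounds, seeded with the
stacked per-region upper bound. The robust variant checks every scenario
of an explicit finite uncertainty set at each leaf; the same stacked bound
across scenarios is a valid (and the seeding) upper bound — the maximum of
per-scenario bounds is not, a subtlety worth recording because it bit both
the solver and the first version of the test oracle. Budgeted or
distribution-based uncertainty sets are deliberate extension points, not
implemented.

Incidence is built from travel times: a station is incident to a
municipality iff its blue-light travel time to the municipality center is
within a threshold (default 12 min in `cover_instance_from_region()`,
a customary response-time target).

## The dispatch simulator

`simulate_ems()` is an event-based replay with two event types: alarms and
mission completions. Doctors idle at stations or drive home after a
mission; returning doctors remain alarmable and are re-dispatched from
their current position along the return path (mid-edge positions commit to
finishing the edge; exact node positions may turn anywhere). On each alarm
the available doctor with the smallest estimated travel time is dispatched
— ties by earliest-available-since, then doctor id; with none available the
emergency queues FIFO and is re-examined at the next mission completion.
Busy doctors are never redirected. Response time = arrival − alarm, so it
includes queueing; it is bounded below by the free-flow travel time from
the dispatch position, and the event log always contains exactly one row
per emergency. Piecewise allocations by shift block are not modeled; the
allocation is constant over the simulated horizon.

`response_time_summary()` reports per-municipality and per-county medians
(empty units are `NA`, never zero) and fixed-width histogram bins with an
overflow bin.

## Pharmacy rostering

The full model minimizes total services under five constraint families:

1. **Coverage with quarantine surplus** — every municipality-day needs
   `c + γ` distinct open pharmacies within the coverage radius R (network
   meters from the municipality center). Surplus coverage is a conservative
   sufficient condition: deleting any γ pharmacies still leaves `c`, which
   the tests verify by exhaustive subset deletion for γ ≤ 2.
2. **Dispersion** — no two pharmacies within the vicinity radius V serve
   the same day. Network distance is used for V as for R, for consistency.
3. **Rest** — duty on day t forbids days t+1 … t+r.
4. **Minimum services** — every pharmacy performs at least `s_min` annual
   services (every pharmacy is legally obliged to participate).
5. **Fairness brackets** — totals within
   `⌊(1−δ)·load⌋ … ⌈(1+δ)·load⌉` around the idealized loads (δ = 0.2
   default; δ = 0 forces near-equality within a municipality).

The exact solver enumerates feasible day patterns once (conflict-free,
coverage-satisfying; capped near 2^20 patterns) and searches days
depth-first with three prunes: per-day minimum pattern size, remaining
lower-bound deficits against remaining per-pharmacy capacity
`⌈days/(r+1)⌉`, and upper brackets as running caps.

**Idealized fair loads.** The simplified problem keeps only coverage (count
c, no γ — the reference should reflect the legal requirement, not the
robustness surcharge). Lexicographic fairness means the sorted-descending
load vector is minimal: the largest load is as small as possible, then the
second largest, and so on. A load-balancing greedy alone does not guarantee
this — if one municipality forces a pharmacy that also covers a second
municipality, the greedy may open an unnecessary extra pharmacy first — so
`idealized_fair_plan()` refines the greedy (scarcity-first municipality
order, ties toward pharmacies covering more still-uncovered
municipalities) with an exact branch-and-bound over inclusion-minimal
cover patterns whenever the multiset search space is small (≤ 2·10⁵
nodes); adding a pharmacy to a day only grows the sorted load vector, so
inclusion-minimal patterns and a sorted-loads lower bound make the search
exact. Large instances use the greedy alone.

**Aggregation.** Pharmacies are mathematically equivalent when they share
municipality, covered-municipality set, and vicinity-conflict set apart
from one another, with a uniform mutual-conflict relation inside the class.
A class of k members becomes one representative with an integer 0…k day
variable; the rest constraint becomes a sliding-window cap (at most k
services in any r+1 consecutive days). The window cap is exactly the set
of class patterns admitting a round-robin disaggregation: serving members
cyclically places any member's consecutive services k slots apart in the
service sequence, and a window with at most k slots forces those to be more
than r days apart. Aggregation is therefore exact; paired solves in the
test suite confirm equal optima and feasible disaggregations.

**Rolling horizon.** Windows of W days (default 28) with overlap O
(default 7): the first W−O days of each window are committed; rest state
and totals carry across the boundary. Annual lower bounds are prorated —
by the end of a window covering day e, totals must reach
`⌊lo·e/T⌋` — because deferring them to the final window regularly makes it
infeasible. Upper brackets hold throughout. An infeasible window is
retried without fairness brackets; the committed plan is always validated
independently. The rolling objective upper-bounds the exact optimum; the
tests track the gap rather than asserting a bound.

`validate_plan()` recounts every family with naive double loops,
independent of the solver, and computes the fairness-chart statistics
(within-municipality maximum difference, difference to municipality
average). `reachability_stats()` recomputes, for every day, the network
distance from each municipality center to the nearest open pharmacy and
summarizes median/min/max per municipality, flagging unreachable days as
infinite.

## Patient transport

Waiting (delay) is one-sided lateness: pickups never start before the
requested time — the vehicle waits — and `delay = pickup_start − t_req`.
The objective is lexicographic: minimize the maximum delay, then the total.
Two sequential stages would need no weighting constant; the solver goes one
step further and computes, per vehicle and request subset, the Pareto
frontier over (max delay, sum delay) across stop orders, then combines one
frontier point per vehicle — this equals the two-stage optimum and the
brute-force suites confirm it. Hard constraints: driver shifts (routes
start and end at the depot inside the shift), fleet compatibility
(infectious patients only on covid or floater vehicles, non-infectious only
on clean or floater), vehicle capacity one patient. Infectious stops extend
both service legs by the protective-clothing add-on (default 10 min);
floaters pay a changeover (default = the add-on, as neither is quantified
in the source material) when consecutive transports switch category. A
delay cap and a daily per-vehicle covid-trip quota exist as options,
both off by default. Times are continuous seconds.

`reoptimize()` fixes all stops whose pickup has started (they are returned
byte-identical), anchors each vehicle at the end of its last fixed stop,
and re-solves the remainder; a new request with no feasible insertion is
flagged unserved rather than failing the day.
`make_dummy_returns()` creates replaceable return requests for dialysis
trips (origin/destination swapped, time = outward time plus an estimated
stay, default 4 h); when the real return materializes the dummy is dropped
and the day re-optimized. `simulate_transport_day()` replays a day under
either the re-optimizing policy or the status-quo baseline — append each
request to the compatible vehicle reaching it earliest, ties by earlier
availability then vehicle id, never revising past decisions. Travel is
deterministic, so realized times equal planned times; stochastic travel
times are out of scope.

The exact routing search is capped at 9 open requests per solve; the day
sizes used in the tests and the acceptance script (4–6 plannable requests,
a small ad-hoc stream, two vehicles) keep every re-solve inside that cap.
This mirrors how the solver is meant to be used: ad-hoc re-solves see only
the outstanding tail of the day.

## The command line

`run_cli()` (and the `exec/careops` wrapper) exposes `synth`, `vax`,
`ems`, `pharm`, `transport` and `export` as file-based subcommands — for
strategic planning tools, file interfaces suffice. Exit codes: 0 success,
1 input error, 2 infeasible, 64 usage. Every JSON artifact embeds the
package version, the seed and an FNV-1a hash of the configuration;
identical argv and seed give byte-identical artifacts (asserted in the
tests across all subcommands). GeoJSON exports cover allocation charts
(site points plus municipality–site lines), isochrone fields (street
segments with the later endpoint's travel time) and per-municipality
choropleth values.

## Problem sizes and numerical conventions

- Exhaustive-oracle suites: covering instances up to 5 locations × 5
  regions with clients ≤ 3 and q ≤ 3 (200 nominal + 100 robust); duty
  plans up to 16 pharmacy-day variables (100 instances); transport up to
  4 requests × 2 vehicles (100 instances); all chosen so the oracles
  themselves stay honest and fast.
- Pipeline demonstrations run on an 8×8-node region with 6 municipalities,
  8 pharmacies and a 14-day rostering horizon.
- Tolerances: routing equalities at 1e-9 s; objective comparisons at 1e-9;
  Dijkstra tie-breaks by node id; day patterns ordered by size then
  lexicographically, so all solvers are deterministic.
- Degenerate inputs: empty emergency logs and empty request tables flow
  through and produce empty results; zero-supplier simulations against a
  non-empty log, municipalities with no reachable pharmacy, and orphan
  regions with demand raise typed errors naming the offending units.

## Limitations

- All exact solvers are exponential-time by design and guarded by explicit
  size caps; they target planning-region instances and verification, not
  nationwide production runs.
- The rolling-horizon roster is near-optimal, not optimal, and its
  fairness fallback can relax brackets in a constrained window.
- The dispatch simulator models one vehicle type (emergency doctors) with
  a constant allocation; ambulances, hospital capacity and crew rostering
  are out of scope.
- The generator's regions are statistical stand-ins; conclusions about
  real regions require real networks and demand data through the same
  interfaces.
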