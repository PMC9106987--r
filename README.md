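# careops

Optimization toolkit for ambulatory-care planning: exact solvers,
simulators and cartographic exports for four planning problems that public
health bodies face, all running on street networks with turn restrictions.

## Who this is for

Operations-research practitioners and health-services planners who need
reproducible, *provably optimal* answers to strategic and operational
questions in ambulatory care:

- **Vaccination-center location** (strategic) — which candidate centers to
  open, how to assign municipalities, how many physicians to staff.
- **Emergency-doctor provision** (strategic/tactical) — how many doctors to
  place at which stations so that every region's emergencies can be served,
  including robustness against demand scenarios, plus an event-based
  dispatch simulator for response-time analysis.
- **Out-of-hours pharmacy rostering** (tactical) — which pharmacies serve
  24-hour duty on which days of the year, balancing coverage, geographic
  dispersion, rest periods and fairness, with robustness against quarantine
  closures.
- **Patient-transport scheduling** (operational) — routing vehicles with
  hard driver shifts and soft patient pickup windows, minimizing first the
  maximum and then the total waiting time, with online re-optimization for
  ad-hoc requests and Covid fleet separation.

Because the real municipal, emergency and dispatch data behind such studies
are confidential, the package ships a seeded synthetic-region generator
with the statistical structure the planning problems assume; every analysis
is reproducible from a seed.

## The models

All four case studies share a routing substrate: a directed, classed street
graph with forbidden-maneuver turn restrictions. Travel time on edge $e$ of
class $c$ is $\ell_e / v_c$ for a speed profile $v$; restrictions can be
respected (regular traffic) or ignored (blue-light driving). Blue-light
speed profiles are estimated from historical trips by iterating: route each
trip under the current profile, extract per-class driven distances $x_{ic}$,
and fit the robust regression
$t_i \approx \sum_c \beta_c x_{ic}$ (Huber M-estimation, no intercept),
where $1/\beta_c$ is the class speed — repeated until the profile is stable.

- **Center location** is the mixed-integer program
  $\min\; w_1 |S| + w_2 \sum_m p_m d(m, s(m)) + w_3 \sum_{s} y_s$
  over open sets $S$, single assignments $s(m) \in S$ and staffing
  $y_s \ge \lceil \sum_{m: s(m)=s} p_m / \tau \rceil$, with optional
  capacities, prefixed assignments and distance caps.
- **Emergency provision** is *q-Multiset Multicover*: place the minimum
  number of suppliers at locations so that every region's integral client
  count can be served, each supplier serving up to $q$ clients in incident
  regions; the robust version requires feasibility for every client vector
  in a finite uncertainty set. Feasibility of an allocation is a max-flow
  condition.
- **Pharmacy rostering** minimizes total services subject to, per
  municipality-day, at least $c + \gamma$ open pharmacies within the
  coverage radius ($\gamma$ = quarantine budget), no two open pharmacies
  within the vicinity radius, rest periods between services, minimum annual
  services, and fairness brackets around an idealized lexicographically
  fair load vector.
- **Patient transport** is a vehicle-routing problem with general time
  windows (VRPGTW): hard shift windows, soft pickup times with one-sided
  lateness, lexicographic objective (minimize the maximum delay, then the
  total), infectious/clean/floater fleets, and re-optimization that keeps
  started transports fixed.

The exact solvers are branch-and-bound / implicit-enumeration algorithms
tailored to each model and proven optimal by construction; independent
brute-force oracles in the test suite confirm optimality across randomized
instance suites.

## Worked example

```r
library(careops)

region <- generate_region(region_config(grid = 8, municipalities = 6,
                                        pharmacies = 8, population = 50000,
                                        n_restrictions = 3, extra_sites = 4),
                          seed = 1)
region
#> <synthetic_region> seed 1: 64 nodes, 6 municipalities, 8 pharmacies
#>   population 50000, 10 candidate sites, 2 hospitals, 2 depots

# emergency provision: cover the sampled demand, then replay it
blue <- speed_profile(c(major = 100, minor = 60), "blue_light")
stations <- region$candidate_sites[1:5]
log <- sample_emergencies(region, daily_rate = 6, days = 3, seed = 4)
clients <- pmin(tabulate(match(log$municipality, region$municipalities$id),
                         nbins = 6), 3L)
names(clients) <- region$municipalities$id
inst <- cover_instance_from_region(region, stations, blue,
                                   threshold_s = 900, clients = clients, q = 2)
alloc <- solve_qmsmc(inst)
alloc
#> <cover_allocation> 6 supplier(s)
#>   n009: 6

events <- simulate_ems(region, stations, alloc$suppliers, log, blue)
median(events$response_s) / 60
#> [1] 8.139928
```

Six doctors at station `n009` (the only station within the 15-minute
threshold of every demanding municipality, so the optimum concentrates
there) serve all 18 sampled emergencies with a median response of 8.1
minutes — response times include queueing when both simultaneous
emergencies hit a single free doctor.

```r
vinst <- vax_instance_from_region(region, throughput = 2000)
vplan <- solve_center_location(vinst)
vplan
#> <vax_plan> 5 open center(s), 27 physicians total
#>   n013: 3 physician(s), municipalities: m01
#>   n039: 5 physician(s), municipalities: m02
#>   n041: 3 physician(s), municipalities: m03
#>   n058: 9 physician(s), municipalities: m05
#>   n060: 7 physician(s), municipalities: m04, m06
evaluate_plan(vinst, vplan)$median_km
#> [1] 0
```

Five centers staffed with 27 physicians (⌈population/throughput⌉ per
center); the population-weighted median travel distance is 0 km because
five of the six municipalities host a center at their own center node.

The same pipeline is scriptable from a shell:

```sh
Rscript exec/careops synth --seed 7 --municipalities 5 --out runs/demo
Rscript exec/careops vax   --region runs/demo/region.json --out runs/demo
Rscript exec/careops pharm --region runs/demo/region.json --horizon 14 --out runs/demo
```

All artifacts embed the seed and a configuration hash; identical arguments
reproduce byte-identical files.

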