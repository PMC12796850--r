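# hauloutnet

Harbour seals (*Phoca vitulina*) haul out on coastal sites that often lie
in different administrative jurisdictions than the ones where the animals
were counted — and hunted under quota. `hauloutnet` is an R package for
asking, from wet/dry-sensor telemetry, **how often and how fast seals
haul out across management boundaries, and which sites form the corridors
of that movement**. It is aimed at movement ecologists and marine-mammal
managers working with GPS phone-tag (or similar) haul-out records.

The package covers the full workflow:

* **Events** — reconstruct haul-out events from wet/dry sensor streams
  (continuously dry ≥ 10 min opens an event; a wet period ≥ 40 s ends
  it), merge events separated by < 10 min, and drop deployments shorter
  than 10 days.
* **Jurisdictions** — assign events to labelled management-unit polygons,
  flag cross-boundary haul-outs (unit differs from the previous
  haul-out's unit), and build gap-time risk intervals: each jurisdiction
  *spell* ends either with a crossing (event) or at the end of tracking
  (censored), and the clock restarts at every crossing.
* **Survival** — Kaplan–Meier curves S(t) = Π (1 − dᵢ/nᵢ) per
  jurisdiction with Greenwood variance and median crossing times, and Cox
  proportional-hazards fits of

  &nbsp;&nbsp;&nbsp;&nbsp;*h(t) = h₀(t) · exp(β₁·X₁ + β₂·X₂ + b)*

  with X₁ the departure jurisdiction, X₂ body weight, and *b* an optional
  Gaussian per-seal frailty — implemented from first principles (Efron
  ties, Newton–Raphson, Laplace-profiled frailty variance), with
  `survival::coxph` used only as a cross-check in the test suite.
* **Network** — chain-rule clustering of haul-out locations into nodes at
  a 10 km threshold, edge density (trips), occupancy (unique seals),
  weight (trips per seal = density/occupancy), node degree, and
  betweenness centrality on distance-corrected weights
  (weight/distance), normalized to [0, 1] with explicit, logged
  conventions.
* **Simulation** — a semi-Markov generator of multi-seal haul-out
  cohorts with known per-unit crossing hazards, frailty and site
  geometry, plus a sensor-stream emitter, so every stage can be tested
  against ground truth.

## Worked example

The package ships the published 13-node haul-out network for the
Skagerrak–Kattegat region as a printed edge table. Reconstructing it:

```r
library(hauloutnet)
edges <- read_edge_table(system.file("extdata", "table3_edges.csv",
                                     package = "hauloutnet"))
net <- network_from_edges(edges)
net
#> <haulout_network> 13 nodes, 17 edges (threshold NA km, edge table)
#> betweenness convention: cost = inverse_dc_weight, normalization = pairs

node_degree(net)[c("H", "F", "B")]
#> H F B
#> 6 5 4
round(net$nodes$betweenness[match(c("H", "B"), net$nodes$node)], 2)
#> [1] 0.62 0.64
```

Node H (the transnational Hvaler/Koster area on the Norway–Sweden
border) touches 6 other nodes and carries betweenness 0.62; node B (the
Aust-Agder tagging site) scores 0.64 — both central hubs seals must pass
through to move between the western, northern and Danish parts of the
network. An edge's weight is its trips-per-individual: the
Vestfold–Buskerud edge F–E carries 34 trips by 7 seals, weight
`edge_weight(34, 7)` = 4.9.

The survival side, on a simulated cohort with the default
Skagerrak-like configuration:

```r
co <- simulate_cohort(sim_config(n_seals = 26, seed = 1))
tracks <- cohort_tracks(co)
tracks$events$unit <- assign_unit(tracks$events$lon, tracks$events$lat,
                                  sites_unit_map())
ri  <- build_risk_intervals(tracks)
km_fit(ri, group_by = "unit")[["Vestfold"]]
#> Kaplan-Meier curve [Vestfold]: 18 at risk, 10 crossings, median 52.42 days

summary(cox_frailty(ri))
#> Cox proportional hazards (frailty effects), reference level: Sweden
#> 95 risk intervals, 69 cross-boundary events
#>           term    beta exp_beta     se      z      p
#>  unitAustAgder -0.6918    0.501 0.7150 -0.968 0.3332
#>   unitBuskerud -1.0028    0.367 0.6877 -1.458 0.1448
#>    unitOstfold -0.5142    0.598 0.6681 -0.770 0.4415
#>   unitTelemark -1.3706    0.254 0.8147 -1.682 0.0925
#>  unitVestAgder -0.2875    0.750 0.7293 -0.394 0.6934
#>   unitVestfold -1.6824    0.186 0.7166 -2.348 0.0189
#>      weight_kg -0.0114    0.989 0.0073 -1.563 0.1181
#> Frailty (seal ID) variance sigma^2_b = 0.1775
```

Each β is a log hazard ratio against the reference jurisdiction (by
default the one with the highest empirical crossing rate — here Sweden):
seals hauled out in Vestfold cross a boundary at exp(−1.68) ≈ 0.19 times
Sweden's rate, with a median of 52 days in-unit before the first
crossing, while body weight has no significant effect. `run_pipeline()`
wires all stages together and writes per-stage CSV/JSON/GraphML outputs
plus a run log; `inst/scripts/haulout_pipeline.R` is a thin command-line
wrapper around it.

See the vignette (`vignettes/haulout-connectivity-methods.Rmd`) for the
models, numerical choices and simulation design in detail.

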