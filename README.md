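# migratrack

Tracklet-based motility analysis for 3D single-cell migration, plus an
agent-based simulator of leader–follower chemotaxis with a short-range
paracrine relay.

## What it is for

Time-lapse chemotaxis-chamber experiments on heterogeneous lymphoma
populations produce long tables of per-frame cell positions. The question
behind this package is *cell-to-cell-induced migration*: chemokine-
scavenging (ACKR3⁺) "leader" cells chemotax up a CXCL12 gradient and emit
a short-range LTB4 cue that — only together with CXCL12 — rescues the
motility of otherwise immobile ACKR3-deficient "follower" cells.
`migratrack` provides, for anyone analyzing such tracks (or building the
analysis without access to raw imaging):

* **Track I/O** — ingest delimited tracking exports (configurable
  dialects, including a commercial-tracker layout), validate invariants,
  fill or split gaps, resample to a uniform grid.
* **Tracklet motility metrics** — decompose tracks into fixed-length
  tracklets and compute displacement *D*, path length *L*, velocity *v*,
  the continuous arrest coefficient *A* (fraction of steps below an
  arrest speed — the proportion of time a cell does not move) and
  directionality *Γ = D/L* (with a polarity-coherence fallback for
  near-stationary tracklets).
* **Four-gate classification** — on the (*A*, *Γ*) plane: chemokinesis
  (low/low), immobile (high/low), polarized (high/high), directional
  (low/high); seeded 1000-tracklet samples per group.
* **Neighborhood influence** — instantaneous velocity stratified by the
  number of motile leaders within 50 µm (0 / 1 / ≥2, rank tests), and a
  lead–lag precedence score for directionality-change events with a
  circular-shift permutation null.
* **Simulator** — persistent biased random walks in a 1000×500×100 µm
  arena with a linear CXCL12 gradient, an exponential LTB4 kernel around
  secreting leaders, a hard LTB4×CXCL12 synergy gate for follower
  activation, and presets for the experimental arms (`ko_alone`,
  `wt_alone`, `mixed_1to1`, `mixed_ptx_wt`, `mixed_ptx_ko`,
  `mixed_deltaC`, `mixed_blt1rko`).

## Worked example

```r
library(migratrack)

cfg <- run_config(preset = "mixed_1to1", seed = 1)
report <- run_pipeline(cfg)
print(report)
#> migratrack run report
#>   cells: 200  tracklets: 21600
#>   gate counts (N = 1000 per group):
#>    chemokinesis immobile polarized directional
#> ko          223      530       122         125
#> wt           74      485       118         323
#>   lead-lag: fraction = 0.114  p = 0.443
```

Reading the numbers: out of 1000 sampled follower (`ko`) tracklets, 125
are in the directional gate versus 323 for leaders (`wt`) — followers in
the mixture migrate, but less directionally than leaders — while a
follower-alone run (`run_config(preset = "ko_alone", seed = 1)`) puts
1000/1000 in the immobile gate. The conditional-velocity table in the
report shows the relay at work:

```r
report$conditional_velocity$summary
#>   group bin     n mean_velocity median_velocity
#> 1    ko   0 79934          1.01           0.287
#> 2    ko   1 21011          1.97           1.669
#> 3    ko >=2  7055          1.99           1.691
```

Follower velocity roughly doubles when at least one motile leader is
within 50 µm (rank test p < 1e-15) and does **not** increase further with
a second leader (p = 0.26): activation is a saturating threshold, so there
is no additive effect. The near-null lead–lag score is expected for the
simulated data — the generator couples follower activation, not heading,
to leaders (see the methods vignette).

Single pieces are available as plain functions, e.g.:

```r
sim  <- simulate_tracks(sim_preset("mixed_1to1", seed = 1))
met  <- tracklet_metrics(decompose_tracklets(sim$tracks))
gate_count_matrix(gate_counts(met, gate_config(seed = 1)))
transwell_surrogate(sim$tracks, plane = 750)
```

A thin CLI wrapper lives at `inst/scripts/migratrack-cli.R`
(`simulate` / `analyze` / `report` subcommands).

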