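---
title: "Tracklet motility analysis and the leader-follower relay model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracklet motility analysis and the leader-follower relay model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migratrack)
```

## The problem

Diffuse large B-cell lymphoma populations are heterogeneous: only a
subpopulation expresses the atypical, chemokine-scavenging receptor ACKR3,
yet in 3D chemotaxis chambers the whole population migrates along a CXCL12
gradient. The working model is a contact-independent relay: ACKR3+
"leader" cells chemotax through CXCR4 along the CXCL12 gradient and, while
CXCL12-stimulated, release the lipid chemoattractant LTB4, whose effective
range is short (below ~50 µm). ACKR3-deficient "follower" cells are nearly
immobile on their own, but the combination of local LTB4 and ambient
CXCL12 — neither cue suffices alone — restores their motility and, partly,
their directionality.

`migratrack` implements the quantitative side of this story twice over:
an analysis pipeline for time-lapse single-cell track tables, and an
agent-based simulator of the relay mechanism that generates such tables
with known ground truth, so every analysis stage is testable without any
imaging data.

## Motility measures on tracklets

Tracks are decomposed into *tracklets*: windows of `W` consecutive frames
(default `W = 10`, disjoint, i.e. stride `W`). Per tracklet with positions
$p_0,\dots,p_{W-1}$ at interval $\Delta t$:

* displacement $D = \lVert p_{W-1} - p_0 \rVert$ (µm),
* path length $L = \sum_k \lVert p_{k+1} - p_k \rVert$ (µm),
* velocity $v = L / \big((W-1)\,\Delta t\big)$ (µm/min),
* continuous arrest coefficient
  $A = \frac{1}{W-1}\#\{k : \lVert p_{k+1}-p_k \rVert / \Delta t <
  v_{\mathrm{arrest}}\}$ — the proportion of time the cell does not move,
* directionality $\Gamma = D/L$ (straightness) when $L \ge
  \varepsilon_{\mathrm{path}}$.

Tunable parameters, with defaults and rationale:

| parameter | default | unit | why |
|---|---|---|---|
| `W` | 10 | frames | 3.3 min at 20 s sampling, the timescale of visible turning/pausing; source window length is not standardized, so it is configurable and stamped into outputs |
| `stride` | `W` | frames | disjoint windows avoid autocorrelated duplicates when sampling 1000 tracklets per group |
| `v_arrest` | 2 | µm/min | below motile lymphocyte speeds, above positional jitter |
| `eps_path` | 1 | µm | floor under which $D/L$ is numerically meaningless |

**Near-stationary directionality.** When $L < \varepsilon_{\mathrm{path}}$,
$D/L$ is unstable. If per-frame polarity unit vectors are present (they
must arrive in the track table; the package extracts nothing from images),
$\Gamma$ falls back to the norm of their mean — the coherence of cell
polarization — so that visibly polarized but arrested cells can reach the
high-directionality, high-arrest gate. Without polarity data that gate is
reachable only through small-$L$, high-straightness motion; this is a
stated limitation, not a claim about how polarity was originally derived
from cell shape.

## The four gates

On the $(A, \Gamma)$ plane, thresholds $a^\ast$ (default 0.6) and
$d^\ast$ (default 0.5) tile the unit square into four gates:
low/low = chemokinesis, high/low = immobile, high/high = polarized,
low/high = directional. "At or above the threshold" counts as high on
both axes — any fixed convention works, but it must be documented for the
boundary cases. The published gates were drawn visually and their numeric
thresholds are unknown; the defaults here are chosen so that pure
archetypes (stationary; ballistic) land well inside the intended gates,
and both thresholds are echoed into every output.

Gate counting draws `sample_N = 1000` tracklets per group without
replacement. For platform-stable determinism the sampler sorts tracklets
by (cell id, window start) and then applies a seeded shuffle
(Mersenne-Twister, rejection sampling pinned), so identical seeds give
identical samples regardless of input order.

## Neighborhood influence

A cell counts as *motile* at frame $f$ when its covering tracklet (the
latest-starting window containing $f$) is in the chemokinesis or
directional gate — motility is defined once, through the gates, not
re-defined from raw speed. For every (cell, frame) the pipeline records
the instantaneous velocity and the number of motile leader cells within
`radius` (50 µm, boundary inclusive); counts of 2 and more are pooled
because the biological claim is saturation, not dose response. Rank-based
(Wilcoxon) comparisons of bin 0 vs ≥1 and bin 1 vs ≥2 are reported with
Benjamini–Hochberg adjustment whenever several comparisons are emitted in
one run.

Directionality *change events* are frames at which the heading (the unit
step vector, defined only at instantaneous speeds ≥ `eps_speed`, default
equal to `v_arrest`) turns by more than `turn_angle` (default 60°)
relative to the previous defined heading. The lead–lag score of a
follower is the fraction of its events preceded within `lag_window`
(default 60 s = 3 frames) by an event of an in-radius leader; the null
distribution circularly shifts the leader event train (999 seeded
shifts). The event definition, window and test are declared surrogates:
the original observation ("changes were in most cases preceded…") names
no operational threshold or statistic.

## The simulator

Agents move by a persistent biased random walk. With heading $h$,
persistence $p$, bias $\chi$, gradient direction $g$ and a uniform random
unit vector $u$:

$$h' = \mathrm{normalize}\!\big(p\,h + (1-p)\,(\chi\,g + (1-\chi)\,u)\big),$$

with half-normal step lengths of scale $\sigma \Delta t$. The arena is a
1000 × 500 × 100 µm box with reflecting boundaries and a linear CXCL12
profile $c(x) = c_0 x / x_{\max}$ ($c_0 = 400$, after the nominal nM of
the loaded chemokine; an error-function profile is available). Defaults:
6 h at $\Delta t = 20$ s, 100 leaders + 100 followers in the mixture.

LTB4 is a quasi-steady-state field, re-evaluated each frame:
$\ell(x) = \sum_j q\, e^{-d_j/\lambda}$ over secreting leaders, with
$\lambda = 15$ µm and activation threshold $\ell^\ast = q\,e^{-50/\lambda}$,
so a single secreting leader is effective exactly out to the 50 µm
analysis radius and no further. A leader secretes iff it is neither
PTX-treated nor carries the truncated scavenger receptor and its local
CXCL12 is at least `c_min` (0.5 % of $c_0$ — release starts just above
background). A follower activates iff $\ell \ge \ell^\ast$ **and** local
CXCL12 > 0 **and** it can respond (not PTX-treated, LTB4 receptor intact):
a hard synergy gate, because LTB4 alone does not move these cells. An
optional *deposit* mode drops decaying point cues where a secreting leader
pauses (followers often arrest where a leader briefly stopped); both modes
satisfy the same field contract. An optional CXCL12 sink around leaders
exists for exploring scavenging-shaped micro-gradients but is off by
default — the default model commits to the LTB4 route.

Motility defaults were calibrated once, as part of the generator's design,
so the mixed preset reproduces the described population structure and then
frozen: leader speed 4 µm/min with run-and-pause switching (enter/exit
0.02 per frame, giving roughly half immobile windows), persistence 0.3,
leader bias 0.5; follower jitter 0.2 µm/min (all sub-arrest), activated
followers 2.5 µm/min with bias 0.05. At these values followers in the
mixture place ~110–170 of 1000 tracklets in the directional gate — fewer
than the leaders — with mean velocity strictly between followers-alone and
leaders, and the perturbed arms (PTX on leaders, truncated receptor,
LTB4-receptor knockout) collapse the follower profile onto
followers-alone.

What the simulator does **not** emulate: PDE-accurate chemokine transport,
receptor occupancy and desensitization, cell–cell mechanics or volume
exclusion, collagen-matrix anisotropy, imaging noise or tracking errors
(gap closing, identity switches), and division/death. Passing tests
therefore demonstrate that the *analysis* recovers the structure the
generator encodes — not that real lymphoma cells obey these equations.

## Numerical and design choices

* Canonical units µm / seconds, frames 0-based; one convention everywhere.
* Regularization interpolates linearly onto the target grid, never
  extrapolates, preserves each cell's start time, and refuses to upsample.
  Within-track gaps of ≤ 2 missing frames are interpolated; longer gaps
  split the track (suffix `#k`), since tracklet metrics assume uniform
  sampling.
* $\Gamma$ is clamped to $[0,1]$ against floating-point overshoot;
  $D \le L$ holds by the triangle inequality and is property-tested.
* Neighbor queries are per-frame vectorized all-pairs distance scans; at
  hundreds of cells per frame this is faster than building a spatial index
  each frame, and tests pin it to a loop-based brute-force oracle.
* The lead–lag permutation uses circular shifts of the (pre-filtered,
  in-radius) leader event train; per-follower scores are pooled with
  event-count weights and the pooled null reuses the same shifts. The
  number of scored followers is capped (default 20, most events first) to
  bound permutation cost on large simulations.
* The transwell surrogate reports, per group, the percentage of agents
  that started at or before the readout plane and finished beyond it; a
  group that starts entirely beyond the plane is already past the input
  plane and reports 100.
* A single pipeline seed drives all stages via fixed offsets (simulation
  +0, gate sampling +1, permutation +2), so one integer reproduces a whole
  report.
* Reported problem sizes: the reference analyses in the tests and the
  acceptance script use the full default presets (200 cells × 1081 frames,
  ~10 800 tracklets per group) — the same scale as the chamber experiment
  they emulate.

One structural consequence worth knowing: the generator couples follower
*activation* (speed) to nearby leaders, but not follower *headings* to
leader headings, so simulated data show the velocity-by-neighbor effect
strongly while the lead–lag precedence score stays near its null — the
relay model as implemented predicts rescue, not directional mimicry. The
lead–lag machinery is therefore validated on constructed event-train
fixtures with known precedence rather than on the simulator.

## Known limitations

Polarity-based directionality for arrested cells is a surrogate for an
image-derived quantity; the event/lag definitions behind the lead–lag
score are package choices; gate thresholds are not fitted to data; and the
printed gate counts of the original imaging experiments are not exact
reproduction targets, because the underlying videos and tracks are not
publicly deposited — the simulator's presets stand in for them with known
construction.
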