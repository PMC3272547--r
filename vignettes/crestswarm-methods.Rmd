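---
title: "Model and methods behind crestswarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind crestswarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crestswarm)
```

crestswarm models the collective migration of mesenchymal cell groups —
prototypically the cephalic neural crest — as the interplay of two
antagonistic local interactions: **contact inhibition of locomotion
(CIL)**, a short-range repolarisation away from cell–cell contacts that
on its own disperses a cluster, and **coattraction (CoA)**, a mutual
chemoattraction mediated by a secreted ligand (in the neural crest,
complement fragment C3a acting on C3aR) that pulls cells back toward
their neighbours. Neither interaction requires an external cue; together
they let a cluster of otherwise independent random walkers behave as a
cohesive, efficiently migrating swarm. This vignette documents the model
equations, every tunable parameter, the design decisions taken where the
biology does not dictate a unique formalisation, what the synthetic data
generators do and do not emulate, and the package's numerical
conventions.

## The agent-based model

Each cell is a point agent with position $x_i$ (μm), unit heading
$h_i$, a group label and an `arrived` flag. Agents move at constant
speed: only the *direction* of motion is dynamic. At every step of
length $\Delta t$ a non-arrived agent updates its heading to

$$h_i' = \mathrm{normalize}\big(w_p\,h_i + n_i + w_{cil}\,R_i +
w_{coa}\,\hat g_i\big)$$

and moves $v\,\Delta t$ along $h_i'$, where

* $n_i$ is a unit vector at a von Mises angle centred on the old
  heading (concentration `noise_kappa`) — the persistent random-walk
  component;
* $R_i = \sum_{j:\ \lVert x_i - x_j\rVert < r_{cil}} \widehat{x_i - x_j}$
  is the CIL repolarisation: one unit vector per contacting neighbour,
  pointing away from it. Exactly coincident agents repel along a random
  direction. There is no volume exclusion: CIL is a repolarisation, not
  a force;
* $\hat g_i$ is the unit gradient of the attractant field (zero when
  the gradient vanishes).

A numerically zero resultant keeps the previous heading. Normalising
the direction only — never the speed — preserves the constant-speed
property exactly, which the test suite asserts to $10^{-9}$ relative at
every step.

### The attractant field

Every agent secretes a diffusible attractant. The field is the
quasi-static superposition

$$C(x) = \sum_j \exp\!\big(-\lVert x - s_j\rVert / \lambda\big),$$

one unit-amplitude exponential plume of length scale `lambda_coa` per
source cell; there is no explicit production/decay PDE (a deliberate
non-goal). Cells sense the analytic gradient of this field, excluding
sources within `self_exclusion_radius` (default $r_{cil}/2$) so that a
cell does not chase its own secretion — without the exclusion the self
term is singular in direction at the cell's own position. Only the
gradient *direction* biases the heading; saturation and adaptation are
not modelled. The analytic gradient is validated against central finite
differences at $10^{-6}$ relative tolerance.

### Contact-triggered repolarisation persistence

Cells that have just undergone CIL do not immediately resume their
baseline random walk: the contact-induced repolarisation is stable on
the tens-of-minutes scale. The model represents this with a refractory
phase: any contact (re)starts a countdown of `cil_persist_steps` steps
during which the agent's angular noise concentration is multiplied by
`cil_persist_gain`, so freshly repolarised cells run near-straight
before relaxing. The phase belongs to the CIL machinery and is inactive
when `w_cil = 0`, so the non-interacting control is untouched.

This is the one place where the package goes beyond the minimal
reading of the published model description, which states the two
interactions but not whether repolarisation persists. We resolved the
open point in favour of persistence for two reasons. Biologically,
contact-induced repolarisation is a Rho-GTPase switching event whose
polarity outlasts the contact by roughly 10–20 minutes. Mechanistically,
without it a CIL kick is forgotten within a few steps, and contact
repulsion then scatters cells as much as it transports them: the
hallmark efficiency gain of CIL-driven corridor migration over
non-interacting cells becomes a weak, unreliable effect, while with
persistence it is large and reproducible in essentially every seeded
run. Setting `cil_persist_steps = 0` recovers the memoryless variant.

### Arenas

* **Corridor** (`arena_corridor()`): $x \in [0, W]$, $y \in [0, L]$.
  Side and top walls reflect specularly (position folded, heading
  component flipped); the bottom strip $y \le$ `target_depth` absorbs:
  an agent entering it is clamped to the strip boundary, marked
  `arrived`, and never moves again (it remains a contact obstacle and
  an attractant source — an arrived cell is still a cell). The cluster
  is released as a hexagonally packed block spanning the corridor
  width, its first row `release_depth` below the top wall.
* **Confrontation** (`arena_confrontation()`): unbounded plane, two
  hexagonally packed discs with centroids `separation` apart (default
  500 μm — about ten cell diameters, far beyond contact range).
* **Unbounded** (`arena_unbounded()`): a single disc, no boundaries.

### Parameters, defaults and their rationale

| parameter | default | unit | meaning |
|---|---|---|---|
| `n_agents` | 60 | – | agents per cluster |
| `speed` | 2 | μm/min | migration speed (constant) |
| `dt` | 1 | min | time step |
| `n_steps` | 500 | – | run length |
| `r_cil` | 20 | μm | contact radius (sub-diameter contact zone of a ~50 μm cell) |
| `lambda_coa` | 200 | μm | attractant decay length |
| `w_cil` | 2 | – | repulsion weight |
| `w_coa` | 2 | – | attraction weight (0 = coattraction-deficient, the morphant analogue) |
| `w_persist` | 1 | – | heading-memory weight |
| `noise_kappa` | 2 | – | angular noise concentration |
| `cil_persist_steps` | 20 | steps | refractory duration after contact |
| `cil_persist_gain` | 50 | – | noise concentration multiplier while refractory |
| `init_spacing` | 20 | μm | initial hexagonal packing distance |
| corridor | 300 × 500, target 40, release 80 | μm | arena geometry |

The qualitative phenotypes do not depend on finely tuned values, but
the defaults are deliberately *centred* so that the entire ±50% band of
each interaction weight, the attractant length scale and the noise
concentration stays inside the working regime — the test suite
re-checks every phenotype at each band edge. Three defaults deserve
comment.

`lambda_coa = 200` μm: the model cluster of 60–100 agents stands in
for an explant of several hundred cells. The far field of a cluster
scales with the number of secreting cells, so a literal per-cell decay
length fitted to a large explant underestimates the reach of a small
model cluster. Below roughly 100 μm the attractant of a 100-agent
cluster is attenuated to numerical irrelevance across the 500 μm
confrontation gap and the mutual-approach phenotype disappears; the
default places the lower band edge (100 μm) just inside the working
range. λ remains the longer-range interaction by an order of magnitude
over the 20 μm contact radius, as the model requires.

`w_coa = 2` (parity with `w_cil`): the swarm's steady-state density is
governed by the repulsion-to-attraction ratio. Beyond a ratio of about
two the cluster loosens sharply and its dispersion approaches that of
non-interacting cells, blurring the cohesion phenotype; weights at
parity keep the loose edge of the ±50% band (ratio 3) clear of that
cliff while the tight edge merely condenses the swarm further (the
model has no volume exclusion, so condensation is benign).

Corridor geometry: the width (~15 cell diameters) gives the
no-interaction control room to disperse measurably — under tight
confinement its Delaunay dispersion is dominated by the corridor width
rather than by the cells' behaviour — while the 80 μm release headroom
below the reflecting top wall lets the cluster spread isotropically.
The target strip begins ~330 μm below the released cluster's front
row: far enough that few pure random walkers reach it in 500 steps,
well within reach of CIL-driven migration.

## Trajectory statistics

All statistics consume the same track table (`track_id,t,x,y,group`)
produced by the simulator, the synthetic generators, or any external
tracking export converted to CSV.

* **Delaunay dispersion** — for each cell, the Delaunay triangulation
  of the positions supplies its natural neighbours; the cell's score is
  the area of the triangle formed with its two *closest* Delaunay
  neighbours, and the summary is the median over cells. The measure is
  local, hence independent of explant size. The median (rather than the
  mean) is deliberately robust to the huge triangles of hull cells; it
  is also insensitive to a minority of far-scattered cells, so it
  measures the crowding of the typical cell, not the extent of the
  cloud. Ties among equidistant neighbours (exact lattices) are broken
  in favour of the non-collinear candidate, so degenerate zero-area
  triangles are never preferred.
* **Coattraction vector** — per-track (or per-explant-group) net
  displacement angles relative to the direction toward a partner
  explant, summarised by the mean resultant vector and circular
  dispersion and tested with a V test toward the partner. Both
  granularities are exposed because published vector plots do not state
  which was used; with fewer than four angles only the summary is
  reported.
* **Rayleigh and V tests** — implemented from their standard series
  and normal approximations (the package deliberately carries no
  circular-statistics dependency); both are calibrated in the test
  suite to a type-I error within [0.04, 0.06] at α = 0.05 under 5000
  uniform nulls. Circular dispersion is the circular standard deviation
  $\sqrt{-2\ln\bar R}$.
* **Chemotaxis index** — cosine between a track's net displacement and
  the start-to-source direction; **persistence** — net displacement
  over path length. Both are bounded, translation/rotation invariant,
  and invariant under time resampling that preserves the visited
  points.
* **Angular deviation** — at each time point, each moving track's step
  direction relative to the direction of the vector-mean step of the
  group; reported as the per-time-point deviation distribution, its
  circular SD and (because the published box plots might show either)
  the IQR of the wrapped angles.
* **Proximal/distal bias** — per-step stratification of scattered
  single-cell tracks by starting distance to a cluster centroid
  (default threshold 300 μm; a step starting exactly at the threshold
  is distal), V test toward the centroid and an 18-bin rose histogram
  per stratum.

## Synthetic data

The generators produce data with *analytically known* directional
statistics, standing in for unavailable time-lapse tracking data:

* `gen_biased_walks()` — fixed-length steps, von Mises step angles
  about a fixed drift direction or recomputed each step toward a
  stationary target (pursuit). The mean cosine of step deviations has
  the closed form $I_1(\kappa)/I_0(\kappa)$, and isotropic walks have
  mean persistence $\to \sqrt{\pi}/(2\sqrt{n})$, which the tests
  recover.
* `gen_point_cloud()` — jittered hexagonal lattice; at zero jitter the
  dispersion summary equals $(\sqrt3/4)\,\mathrm{spacing}^2$ exactly.
* `gen_two_explant_snapshot()` — two clouds at a stated separation with
  partner directions attached.

Real cell tracks are not von Mises walkers: they show heterogeneous
speeds, temporally correlated turning, and cell–cell interactions that
the generators deliberately omit. Passing the recovery tests therefore
certifies the *statistics* (and the seeded reproducibility of the
generators), not any claim that the generator mimics real data.

## Numerical conventions

* Angles are radians internally, reduced to $(-\pi, \pi]$; CLI reports
  convert to degrees.
* One global R random stream per run, seeded from the config; identical
  config + seed gives bit-identical tracks. The draw order is: cluster
  headings at initialisation, then per step any coincident-pair
  directions followed by the von Mises noise (drawn grouped by noise
  concentration).
* von Mises sampling uses the Best–Fisher (1979) rejection scheme;
  κ < 10⁻⁹ falls back to the uniform distribution.
* Delaunay triangulations come from `deldir`; cocircular degeneracies
  follow its infinitesimal-perturbation convention, and the
  brute-force empty-circumcircle oracle used in the tests applies a
  strict-inequality rule that matches it.
* Dispersion of a corridor run is evaluated over the non-arrived
  agents of the final state (arrived agents sit clamped on the target
  line, where their collinear, frozen positions would measure the
  absorbing boundary rather than the migrating population).
* Degenerate inputs fail loudly: fewer than 3 or collinear points for
  the dispersion metric, duplicated points (the caller decides whether
  to jitter), zero net displacement for the chemotaxis index, fewer
  than 4 angles for the circular tests.

## Study conditions and problem sizes

The packaged experiments (`corridor_phenotype_experiment()`,
`confrontation_phenotype_experiment()`) run 20 seed-matched
simulations per condition: corridors of 60 agents for 500 steps, and
confrontations of 2 × 100 agents for 800 steps at 500 μm separation —
explants are larger than a migratory stream segment, and the larger
cluster mass both strengthens the interface repulsion between
colliding control clusters and quiets their centroid fluctuations; 800
steps is the window at which coattracting clusters have approached
distinctly while dispersing control clusters have expanded into
contact but not yet mixed through one another. Calibration tests use 5000 uniform-null
replicates (n = 20) for the circular tests, 200 random configurations
for the geometry oracle, and 100 for the field gradient.

## Known limitations

* The attractant field is quasi-static; secretion/decay dynamics,
  degradation sinks and boundary effects on diffusion are not
  modelled.
* CIL is isotropic and memory-simple (a single refractory countdown);
  real repolarisation has richer dynamics and contact-angle
  dependence.
* No volume exclusion: transiently overlapping positions are legal.
* 2-D only; no division, death or EMT; no mechanics (forces, adhesion,
  substrate stiffness).
* Model parameters are not fitted to imaging data (none are published
  with the original study); defaults are order-of-magnitude choices
  placed in the robust swarming regime.
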