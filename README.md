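# crestswarm

Agent-based simulation and trajectory statistics for collective cell
migration of mesenchymal cell groups, modelled on the cephalic neural
crest.

Migrating neural crest cells are mesenchymal — they have largely lost
cell–cell adhesion — yet they move as a coherent group. Two antagonistic
local interactions can explain this: **contact inhibition of locomotion
(CIL)**, a short-range repolarisation away from cell–cell contacts that
disperses a cluster and drives it into unoccupied territory, and
**coattraction (CoA)**, mutual chemoattraction through a secreted ligand
(complement fragment C3a and its receptor C3aR in the neural crest)
that pulls wandering cells back. crestswarm implements this
two-interaction model as constant-speed self-propelled particles and
ships the full statistical toolkit used to quantify such behaviour in
tracking data — so the same metrics run on simulated and experimental
tracks.

## The model in brief

Each cell updates its heading each minute to

    h' = normalize( w_p·h + n + w_cil·R + w_coa·ĝ )

where `n` is von Mises angular noise about the current heading, `R` the
sum of unit vectors away from all neighbours within the contact radius
`r_cil` (CIL; a fresh contact also triggers a transient low-noise
"repolarised" phase), and `ĝ` the unit gradient of the attractant field
`C(x) = Σ_j exp(−|x − s_j|/λ)` secreted by all cells. Position advances
`speed·dt` along `h'` — speed is always constant, only direction
changes. Arenas: a migration corridor with reflecting walls and an
absorbing target strip, a two-cluster confrontation, or a free field.

Statistics: Delaunay-triangulation dispersion (median area of each
cell's two-nearest-neighbour triangle), coattraction vectors with
circular dispersion, Rayleigh and V tests, chemotaxis index,
persistence, angular deviation from the group path, and
proximal/distal rose-plot analysis. Synthetic von Mises walks and
jittered hexagonal point clouds with closed-form expectations make
every statistic testable offline.

## Worked example

```r
library(crestswarm)

## corridor migration with both interactions
res <- run_model(sim_config(arena = arena_corridor(), seed = 1))
res
#> Simulation (corridor arena): 60 agents, 500 steps
#>   arrival fraction 0.000

## CIL alone disperses the cluster but reaches the target
cil <- run_model(sim_config(w_coa = 0, arena = arena_corridor(), seed = 1))
cil$arrival_fraction
#> [1] 0.1166667

## dispersion of the still-migrating cells at the end point
final <- cil$final_state
delaunay_dispersion(final$positions[!final$arrived, ])
#> Delaunay dispersion of 53 cells: median triangle area 423.66 um^2
#>   per-cell range [4.74, 1822.62]

## the same metric on the cohesive swarm is ~30x smaller
both <- res$final_state
delaunay_dispersion(both$positions[!both$arrived, ])$summary
#> [1] 13.57818

## two-explant confrontation: clusters approach only with coattraction
conf <- run_model(sim_config(n_agents = 100, arena = arena_confrontation(),
                             n_steps = 800, seed = 1))
tail(conf$centroid_distance, 1)
#>       t distance
#> 801 800 70.56555

## circular statistics on synthetic chemotaxis tracks
walks <- gen_biased_walks(36, 60, target = c(500, 0), kappa = 2, seed = 2)
mean(vapply(split_tracks(walks), chemotaxis_index, numeric(1),
            source = c(500, 0)))
#> [1] 0.9939894
```

Interpretation: with CIL alone ~12% of cells reach the target strip
within 500 min and the cluster spreads (median neighbour-triangle area
424 μm², up from 173 μm² at plating density); adding coattraction
condenses the group into a tight swarm (14 μm²) at the cost of
arrival. In the confrontation, two 100-cell clusters close from 500 μm
to ~71 μm in 800 min. The synthetic pursuit walks recover a chemotaxis
index near 1, as expected for strongly biased motion toward the
source.

A command-line interface wrapping the same functions is installed with
the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "crestswarm.R", package = "crestswarm"))')" \
  simulate --mode corridor --seed 1 --out tracks.csv --summary run.json
```

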