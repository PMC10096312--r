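# moltopo

Topological 2D molecular graphs for molecular-dynamics trajectories — and the
road back from a 2D graph to a 3D structure.

`moltopo` is for computational chemists and structural-bioinformatics
developers who post-process atomistic MD trajectories (ab initio, force-field
or coarse-grained) and want conformational analysis that is *topological*
rather than geometric, plus a first-principles-free way to regenerate 3D
coordinates from a molecular graph alone.

## What it computes

**Forward direction — trajectory to graphs.** Every snapshot is encoded as a
coloured mixed graph

> G = (V, E_C, A_H, E_I, E_O)

where `V` are the heavy atoms coloured by element, `E_C` the covalent bonds,
`A_H` directed hydrogen-bond arcs (donor heavy atom → acceptor, the mediating
hydrogen recorded on the arc), `E_I` electrostatic contacts around ions and
`E_O` organometallic contacts around metals. Interactions are perceived from
distance/angle thresholds and per-element covalent radii and valence caps
(greedy nearest-first assignment under the caps), with per-atom *orbits*
refreshed at reference snapshots so rescans avoid an all-pairs search.

Two snapshots belong to the same **conformer** exactly when their graphs are
isomorphic as coloured mixed graphs (vertex colours, every edge set and arc
direction preserved). The engine is a colour-refinement +
individualisation-backtracking canonical labelling, so each conformer gets a
canonical key and registry lookup is exact. The trajectory then yields:

* a **conformer registry** (representative graph, appearance list, occupancy %),
* a directed **graph of transitions** whose edges count observed
  interconversions and carry the bonds formed/broken (exported as DOT and
  GraphML, red/green colouring by an occupancy threshold `P_min`),
* **cycle analytics**: a Horton minimum cycle basis per graph, H-bonded
  ring-size distributions, connected-component histograms, the percentage of
  vertices participating in polygons, and the coarse-grained *graph of
  cycles* (H-bonded cycles as vertices, shared atoms as edges) — the natural
  toolbox for interfacial water H-bond networks.

**Reverse direction — graph to 3D.** A hydrogen-inclusive graph is turned into
coordinates by a sequential game with no energy function anywhere. Each
covering-tree edge `(u, v)` is a player that places `v` on one of 42 icosphere
directions around `u` (radius = ideal bond length). After each round every
vertex is scored by

* `Direct(u)` — minimal summed deviation of its placed neighbours from the
  VSEPR ideal directions (tetrahedral, trigonal, bent, linear), and
* `Indirect(u) = Σ_v Local(v) / dist_T(u, v)` over proper tree descendants,
  where `Local` collects off-sphere non-tree neighbours and steric intrusions,

giving the player cost `R = (Direct + Indirect)/2`. Utilities are normalised
per player and strategy, `U = (Max(s) − R)/(Max(s) − Min(s))`, and strategy
probabilities follow the linear reward–inaction update
`V(s) ← V(s) + (1 − V(s))·b·U` (others scaled down accordingly). Blocks are
independent restarts; the best round-average utility `m_k` selects the
reported structure, evaluated by least-squares superposition RMSD.

## Worked example

```r
library(moltopo)

# a scripted water-dimer trajectory whose H-bond toggles on a known schedule
tr  <- make_scripted_trajectory(schedule = c(0, 0, 1, 1, 0))
res <- analyze_trajectory(tr$trajectory)
tidy(res$registry)
#> # A tibble: 2 × 4
#>      id count percentage first_frame
#> 1     1     3         60           1
#> 2     2     2         40           3
tidy(res$transitions)
#>    from    to count formed    broken
#> 1     1     2     1 ""        "hbo 1-4"
#> 2     2     1     1 "hbo 1-4" ""
```

Two conformers at 60 % / 40 % occupancy; the single transition in each
direction breaks/forms the O1→O4 hydrogen-bond arc — exactly the scripted
ground truth.

```r
# regenerate water's 3D structure from its graph alone
w   <- make_molecule("water")
fit <- run_game(w$graph, blocks = 2, rounds = 5000, t = 500, seed = 1,
                target = w$structure)
glance(fit)
#> # A tibble: 1 × 5
#>   best_m best_block blocks rounds best_rmsd
#> 1      1          1      2   1022    0.0240
```

The recovered structure has O–H bond lengths of 0.970 Å (the covalent-radius
sum, exact by construction) and an H–O–H angle of 108.0° — the nearest
42-direction grid approximation to the 104.5° bent template — an RMSD of
0.024 Å against the reference geometry.

A thin CLI covering the same operations lives at `inst/cli/moltopo.R`
(subcommands `analyze`, `cycles`, `predict3d`, `fixtures`).

## Package layout

* `R/params.R`, `R/io.R` — element database, thresholds, XYZ/PDB I/O
* `R/molgraph.R` — interaction perception, orbits, GraphML export
* `R/isomorph.R` — canonical labelling, conformer registry
* `R/transitions.R` — trajectory loop, graph of transitions, exports
* `R/cycles.R` — Horton basis, ring/component/polygon analytics
* `R/geometry.R`, `R/game.R` — icosphere grid, VSEPR templates, the game
* `R/fixtures.R` — synthetic molecules, scripted trajectories, water sheets
* `vignettes/moltopo-methods.Rmd` — the methods vignette (model, parameters,
  numerical choices, limitations)
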