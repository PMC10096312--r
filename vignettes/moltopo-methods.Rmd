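---
title: "Topological molecular graphs and graph-to-3D generation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological molecular graphs and graph-to-3D generation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moltopo)
```

## The model

`moltopo` treats a molecular configuration as a coloured mixed graph
`G = (V, E_C, A_H, E_I, E_O)`. Vertices are the heavy atoms, coloured by
element; hydrogens are not vertices and enter only as mediators of directed
hydrogen-bond arcs. Four edge types are perceived geometrically:

* **covalent** (`E_C`): `d(a, b) ≤ r_cov(a) + r_cov(b) + tol`, subject to
  per-element valence caps;
* **hydrogen bond** (`A_H`): a directed arc from the donor heavy atom to the
  acceptor whenever a covalently bound hydrogen sits between them with
  `d(D, A)` below a heavy-heavy cutoff and a D–H···A angle (measured at the
  hydrogen) above a linearity threshold;
* **electrostatic** (`E_I`) and **organometallic** (`E_O`): distance contacts
  in which exactly one endpoint is flagged as an ion candidate or a metal.

Because the representation is purely topological, a *conformer* is an
isomorphism class of such graphs: two snapshots are the same conformer
exactly when a colour-preserving bijection maps every edge set onto its
counterpart with arc directions intact. Conformational dynamics then reduces
to walks between isomorphism classes, summarised by the graph of transitions.

## Tunable parameters

All distances are in Ångström, angles in degrees. The perception thresholds
are a user-editable database; the built-in values are conventional choices
for organic and aqueous systems, not fitted constants:

| parameter | default | meaning |
|---|---|---|
| `covalent_tolerance` | 0.40 | slack added to the covalent-radius sum |
| `hbond_heavy_max` | 3.5 | maximum donor–acceptor heavy-atom distance |
| `hbond_angle_min` | 140 | minimum D–H···A angle at the hydrogen |
| `electrostatic_max` | 3.0 | ion-contact cutoff |
| `organometallic_max` | 2.8 | metal-contact cutoff |
| `acceptor_elements` | N, O, F, S, Cl | H-bond acceptors |

Covalent radii follow the Cordero (2008) table. Valence caps are H = 1,
O = 2, N = 4 (admitting protonated amine termini), C = 4, B = 3, halogens = 1
and metals = 8; elements flagged as ion candidates (Li, Na, K, Mg, Ca) have a
cap of 0 — in MD snapshots these species occur as ions, and giving them
covalent bonds would swallow the electrostatic contacts they are meant to
form. When more neighbours satisfy the covalent criterion than an atom's cap
allows, bonds are granted greedily in ascending distance order with a
(distance, smaller-id-pair) lexicographic tie-break, which makes perception
order-independent and reproducible.

### Orbits and reference snapshots

Perception is restricted to per-atom *orbits*: the set of atoms within
`orbit_radius = largest cutoff + 2.0 Å` at the last reference snapshot.
Orbits are refreshed when any atom has drifted more than
`(orbit_radius − largest cutoff)/2` since the reference, or after 100 frames,
whichever comes first. The triangle inequality then guarantees that the
orbit-restricted scan finds exactly the pairs an all-pairs scan would — a
property the test suite checks on random-walk trajectories.

## Isomorphism engine

Graphs are compared by canonical labelling rather than pairwise search:
vertex colours start as element symbols and are refined by the multiset of
(incident edge type, neighbour colour) pairs, with H-bond in- and out-arcs
distinguished. If the stable partition is not discrete, the first
non-singleton cell is individualised and refinement recurses; the certificate
is the lexicographic minimum over the resulting discrete orderings of the
(element sequence, ordered pairwise edge codes) string. Equal keys therefore
*prove* isomorphism (the certificate reconstructs the graph up to
relabelling) and unequal keys refute it; nothing rests on hashing. The
mediating hydrogen's identity is deliberately not part of the certificate:
hydrogens are represented only through arc direction, so two graphs differing
solely in which hydrogen mediates an arc are the same conformer.

The trajectory loop checks the previous frame's conformer before consulting
the registry, since consecutive snapshots usually coincide; the shortcut is
instrumented (a counter of avoided registry lookups) for testability.

## Graph of transitions

Vertex labels carry occupancy percentages computed over frames, not
integrated time — MD output with a constant time step makes the two
proportional, and frames stay exact for subsampled trajectories. Consecutive
identical conformers are not self-loops; residence lives in the vertex
percentages. Edges carry raw interconversion counts plus the typed bond
difference between the two representatives, with atoms named
element-plus-ordinal (N1, O8, ...) in first-appearance order. The export
threshold `P_min` (default 4 %) only affects colouring (red for major, green
for minor conformers), never the graph's content. No kinetic model (rates,
Markov states) is fitted: the counts are the data.

## Cycle analytics

The minimum cycle basis uses Horton's candidate set — for every vertex `v`
and edge `(x, y)`, the cycle formed by the BFS shortest paths `v→x`, `v→y`
and the edge, kept when the paths meet only at `v` — sorted by weight and
filtered by greedy GF(2) independence until the cyclomatic number
`|E| − |V| + C` is reached. All edge types are pooled as undirected edges.
Horton bases are not unique, so equal-weight candidates are ordered by their
canonical (rotated/reflected, lexicographically minimal) vertex sequence:
the basis is deterministic and reproducible.

An *H-bonded cycle* is a basis cycle containing at least one H-bond arc; the
term is used informally in interfacial-water work, and this definition makes
it precise while keeping purely covalent rings (e.g. phenyl) out of the
H-bond statistics. Ring-size histograms pool the per-frame bases of all
supplied graphs (rather than deduplicating rings across frames), so a ring
that persists for 100 frames weighs 100 times a one-frame ring — the
statistically meaningful convention for occupancy-style distributions.
Interfacial-layer selection is an input: the caller provides the atom
subset (a convenience z-slab filter exists but no claim is made that it
reproduces any published layer definition).

Cross-conformer "polymorphic" cycle matching and the trajectory-level
polygraph are deliberately out of scope: they require an equivalence notion
between cycles of different conformers that is not yet well defined.

## The structure-generation game

The reverse mapping works on a hydrogen-inclusive graph (covalent bonds plus
target H-bonds as heavy-heavy edges). A BFS covering tree is built with
deterministic neighbour order; the root is the highest-degree vertex (ties to
the lowest id) and sits at the origin. Each tree edge `(u, v)` is a player
whose 42 strategies are the unit directions of one icosphere refinement (12
icosahedron vertices + 30 edge midpoints) scaled by the edge's ideal length:
the covalent-radius sum for bonds, 2.9 Å heavy–heavy for H-bonds (both
configurable). Direction 1 of the grid (a fixed lexicographic convention) is
the *virtual parent* slot: before placing children, the grid of `u` is
rotated by the minimal rotation taking direction 1 onto the actual direction
of `u`'s parent, which is also the rotation minimising the average
displacement of the grid points. The grid is antipodally closed, so linear
arrangements are exactly representable.

### Utilities

`Direct(u)` compares the unit directions of `u`'s placed neighbours with a
VSEPR template chosen by (bonded degree, lone pairs): single, linear 180°,
bent 107°/104.5° (one/two lone pairs), trigonal planar 120°, trigonal
pyramidal 107°, tetrahedral 109.47°. Lone pairs come from a small per-element
table (O and S: 2, N: 1, halogens: 3, otherwise 0). The deviation is the
minimum over neighbour-to-slot assignments and rigid template rotations of
the summed Euclidean distances. Minimising a *sum of distances* (not
squares) over rotations has no closed form, so the exact path starts from
the least-squares (Kabsch) alignment and polishes with a Nelder–Mead search
over an axis-angle offset; the test suite checks it against a brute-force
multi-start oracle to 1e-3. Inside the game loop the un-polished
least-squares alignment is used: it preserves the ordering of costs that the
learning consumes at a fraction of the cost, and the polished version remains
available (`refine = TRUE`) wherever the exact number matters.

`Local(w)` adds, for each non-tree neighbour, the distance between the
neighbour and its projection onto `w`'s sphere, plus the distance of every
non-adjacent vertex that intrudes into the sphere (an intruder contributes
its distance as printed in the method's definition, even though an inverted
term would penalise closer intruders more strongly).
`Indirect(u)` sums `Local(v)/dist_T(u, v)` over the *proper* descendants of
`u`: including `u` itself would divide by zero, and `u`'s own discomfort is
already `Direct(u)`. The player cost is `R = (Direct + Indirect)/2`, shared
by all players with the same parent vertex.

### Learning and selection

The normalised utility `(Max(s) − R)/(Max(s) − Min(s))` uses per-player,
per-strategy running extremes including the current round; when the extremes
coincide (first plays of a strategy) the utility is the neutral 0.5. The
linear reward–inaction update with slowing factor `b = 0.1` then reinforces
the played strategy proportionally to its utility; the update is an affine
combination of the vector with a unit vector, so the simplex is preserved
exactly. Blocks (default 10 × 5 000 rounds, early-stopped after `t = 500`
rounds without improvement of the round-average utility `m_k`) are
independent restarts: strategy vectors and cost histories reset, matching
the interpretation of per-block best values as independent draws. Within a
block the best `m_k` and its positions are tracked; among rounds with *equal*
best `m_k` the latest is kept, because once strategies have converged the
same best value recurs and the late geometry reflects the learned
equilibrium rather than a lucky early round.

### What the game can and cannot do

Because utilities are relative to each strategy's own cost history, any
locked-in pure strategy profile eventually looks acceptable to its players:
linear reward–inaction absorbs at some equilibrium, not necessarily the
VSEPR-optimal one. For very small systems this has two visible consequences,
both reproduced by the acceptance checks. First, the recovered geometry sits
on the 42-direction grid: water's H–O–H angle converges to one of the grid
angles near the bent template (frequently 108°, sometimes 90° or 116.6°).
Second, with only a handful of players the round-average utility spikes to
exactly 1.0 in early rounds (every player simultaneously at a per-strategy
record), and a 5-atom chain reaches the ideal linear arrangement only in a
minority of seeds — the per-block best-RMSD of roughly 0.4–1.7 Å that
`scripts/acceptance.R` reports is the method's honest small-system
performance, consistent with the ~1.5–2.3 Å it achieves on peptide-sized
inputs. Improving the utility's global anchoring is the obvious next step
and out of scope here. Bond lengths, by contrast, are exact by construction
(children sit on the grid sphere), and superposition RMSD uses the standard
Kabsch least-squares alignment.

## Synthetic data

The fixtures module generates every input the tests need:

* canonical small molecules (water 104.5°/0.9572 Å, tetrahedral methane,
  pyramidal ammonia, a 2.9 Å water dimer with exactly one H-bond arc under
  the default thresholds);
* peptide-like chains built from internal coordinates: a 34-atom
  tri-alanine (C9H18N3O4, protonated N terminus, COOH C terminus) and an
  80-atom benzyloxycarbonyl-capped hexa-alanine amide (C26H39N7O8). Both are
  *extended* reference geometries whose declared H-bonds are part of the
  target topology fed to the generator, not of the geometry — the
  self-consistency tests therefore re-derive the covalent graph geometrically
  and treat the H-bond as topological;
* scripted water-dimer trajectories: a binary schedule rotates the donor
  hydrogen by −100° about the donor, which breaks the single arc; the
  builder verifies that the toggle really changes the graph and returns the
  ground-truth conformer sequence, making end-to-end tracking exactly
  checkable;
* planar honeycomb water sheets (O–O 2.8 Å, bridging hydrogens on the O–O
  lines, surplus hydrogens out of plane, donor assignments capped at two per
  oxygen) whose perception yields a pure hexagonal H-bond network — the
  idealised analogue of the collective interfacial layer.

What these fixtures do *not* emulate: thermal noise, quantum-quality
geometries, threshold-straddling bond flicker, periodic boundaries and
condensed-phase disorder. Passing tests therefore demonstrate correctness of
the graph constructions and algorithms under controlled topology changes,
not robustness of the thresholds against borderline real-world geometries —
the thresholds themselves remain the user's scientific responsibility.

## Numerical choices and problem sizes

Determinism everywhere possible: perception tie-breaks are lexicographic,
BFS neighbour order ascending, Horton candidates canonically ordered, the
icosphere rows lexicographically sorted. Degenerate inputs are defined, not
special-cased: empty graphs have a sentinel canonical key, trees an empty
cycle basis, isolated vertices count as size-1 components, a single-neighbour
vertex has zero VSEPR deviation, and the polygon-membership fraction of an
empty graph is an error rather than a silent 0/0. Antiparallel alignment
rotations use a deterministic perpendicular axis. The simplex is asserted to
1e-12 after every reward–inaction update.

Test and acceptance problem sizes are chosen to characterise the algorithms
well within a desktop minute-scale budget: 200 random mixed graphs of up to
7 vertices against the exhaustive oracle (with 50 relabellings each for key
invariance), 100 random graphs for cycle-space dimensions, 10^5
reward–inaction updates, water games of 5 000 rounds and five 3-block chain
games. The trajectory-scale constructs (43k-frame peptide runs, 400-frame
interfacial ensembles) exercise the same code paths through the scripted
fixtures at smaller frame counts.

## Known limitations

* No bond orders, no periodic-image bonding, no binary trajectory formats.
* Percentages are frame-based; subsampled trajectories weight frames equally.
* The Horton implementation targets molecular-scale graphs (hundreds of
  vertices), not large dense graphs.
* The generator handles isolated molecules only, with the 42-point grid as
  its angular resolution floor, and inherits the selection weaknesses
  discussed above for very small systems.
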