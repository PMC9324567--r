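---
title: "Morphogenetic self-assembly of bacterial cells: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphogenetic self-assembly of bacterial cells: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphosys)
```

## The model

A morphogenetic self-assembly system couples three object kinds in
continuous 3D space and discrete time. *Floating objects* are point
particles with a label, a mobility and (optionally) an environment
supply concentration. *Tiles* are rigid 1D rods or planar polygons whose
boundary connectors carry glue labels; a pre-specified symmetric glue
relation decides which connectors may bond. *Protions* are catalysts
fixed at a position on their host tile; they enable reactions and carry
floating objects across the tile, the package's abstraction of a
membrane transport channel.

Dynamics alternate two phases per iteration (one iteration represents
one minute of real time). First, every floating object takes one
Brownian step: a displacement of length `mobility * r` — `r` being the
system's interaction radius — in a direction drawn uniformly on the
sphere, reflected at the environment box walls and, for objects inside a
closed cell, at the cell's confinement sphere. Second, the engine
collects every applicable rule instance — a rule together with a
reaction site and the nearest reagents within distance `r` on the
correct side of the membrane — and applies a maximal conflict-free
subset in uniformly random order: each object is consumed at most once
and each placement slot filled at most once. Nondeterminism enters only
through this ordering and the Brownian phase; a run is bit-reproducible
given its seed.

Rules come in exactly four classes, all reactions `u -> v` over
multisets: metabolic (transport), creation (tile synthesis from floating
objects — tiles are never available for free), destruction (tile
annihilation) and division (severing a completed septum interface so
that one compartment becomes two). Structural preconditions of rules are
expressed as declarative guards (`closed`, `scaffold_complete`,
`septum_complete`) evaluated on the cell a rule instance would act in.

## The bacterial cell

The shipped bacterial system has two floating objects — nutrient `a`,
maintained by the environment at a supply concentration until a nutrient
budget is spent, and division signal `s`, produced only by transport —
one protion type, four polygonal tile types (pole cap, two side-wall
types that carry the transport protion, septum face), three auxiliary
rod types, and nine rules:

1. one metabolic rule, `a(out) -> a(in) + s(in)`: each imported
   nutrient releases one unit of division signal inside;
2. two wall creation rules consuming `a`, one per side ring;
3. one septum-seed rod creation rule consuming `s`;
4. two further rod creation rules (arm and bridge) consuming `s`,
   completing a triangular mid-cell scaffold;
5. one septum-face creation rule consuming `2 a` inside, which also
   closes a bare pole (poles are septum-derived faces, as in rod-shaped
   bacteria where each new pole is a remodelled septum);
6. one destruction rule that annihilates all three rod types once the
   septum is complete;
7. one division rule triggered by the structural predicate "septum
   complete and scaffold cleared", which severs the ring-ring and
   face-face bonds, yielding two closed daughters of equal tile count.

The developmental cycle — seed pole, first ring, second ring, far pole,
closure, import, scaffold, septum, fission — is not scripted anywhere:
each stage becomes applicable only when its structural preconditions
emerge, and its timing is set by stochastic reagent encounters. Division
time therefore varies from run to run, and an adult (a cell on which
division is applicable) is defined by its configuration, not by a clock.

### Reduced geometric fidelity

Population-scale runs use a capsule placement template: tile poses live
on a fixed frame of named slots (two poles, two rings of three octagonal
side tiles, two septum faces, three rod scaffold positions), the bond
graph is derived from slot occupancy by a fixed adjacency map, and slot
poses provide the 3D positions used in every radius-`r` reagent test.
Floating objects keep genuine continuous positions throughout. Three
further simplifications are deliberate: daughters re-anchor on fresh
frames after fission (an elastic relaxation of the envelope; tile
identity and bonds are preserved), cell-cell obstruction is not
enforced at the population scale, and transport into a not-yet-closed
cell deposits objects in the concavity, from which they leak back out at
a rate proportional to the open wall fraction. The full obstruction test
(`overlap()`) remains available for single-assembly work.

The adult pre-division cell exposes exactly 34 injurable components: 10
tiles (2 poles, 6 side tiles, 2 septum faces), 6 protions (one per side
tile) and 18 derived bonds. This component inventory is enumerated from
a grown cell by `injury_targets()`, never hard-coded.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| interaction radius `r` | 1 | tile edges | reaction reach and Brownian step scale |
| `diffusion_a`, `diffusion_s` | species preset | multiples of `r` per iteration | the species calibration constants |
| supply concentration | 0.25 | objects per unit³ | environment nutrient density target |
| nutrient budget | species preset | objects | total supply; `Inf` for injury protocols |
| interior capacity | 8 | objects | transport stalls against a full interior |
| leak rate | 0.4 | per iteration per open fraction | loss from unclosed compartments |
| re-adhesion rate | 0.16 | per iteration | healing of severed but intact bonds |

The interior capacity is the self-control feedback: a closed cell that
has accumulated what a division cycle needs stops importing, so nutrient
consumption tracks growth rather than population size. Growth then
halts, without any external intervention, when the budget is spent —
the census is sigmoidal with plateau ≈ budget / per-division cost.

Species presets were calibrated once, by the shipped grid search
(`scripts/calibrate.R`), against the target mean final populations of
74 cells at 100 iterations, 76 at 150 and 85 at 400 under the
limited-nutrient protocol; only the two diffusion constants and the
budget differ between species. With the defaults the E. coli preset
averages ≈ 74 cells over 100 seeded runs, giving the closed-form
doubling time `100 * log(2) / log(74)` ≈ 16.1 min against 17 min for
the living organism.

## Injury and self-healing

An injury is a state change no single rule application could produce:
removing a tile (a hole in the membrane), removing a protion (the tile
stays, its channel is gone — permanent unless the tile itself is later
destroyed and rebuilt), breaking a bond without destroying its tiles, or
injecting floating objects into a compartment. A severed bond between
two tiles still in place re-adheres stochastically (their glues still
match and remain in contact); until every wall bond is intact the
compartment does not count as closed, which stalls the septum machinery.
There is no repair rule: recovery is re-growth by the nine ordinary
rules.

Two replicated protocols are provided, both under unlimited nutrients.
The *sequential* schedule spreads injuries of the four kinds (chosen
uniformly, targets uniform among eligible components, float injection
included) over random times before division. The *simultaneous*
schedule draws `k` of the adult's 34 components without replacement,
damages each according to its kind just before division, and asks
whether the cell still reaches a completed division within three times
the uninjured mean generation time — the package's operationalisation of
"survival to adulthood and reproduction", since no cutoff is inherent in
the model. Any completed division counts as survival. Recovery time is
reported as the ratio of injured to uninjured generation time, averaged
over surviving runs only, and explicitly undefined when no run survives.

With the shipped constants the survival curve is 1.0 uninjured,
declines monotonically, first drops below 0.5 around 23–25 simultaneous
injuries, and is identically 0 from about 30 onwards (at 34 every
component is destroyed). The decline is driven jointly by bond-healing
delays, protion (import) attrition and the repair-time cap; the exact
tail position is sensitive to the calibration constants.

## Configuration spaces and the formal framework

The abstract counterpart works on transition digraphs: nodes are
equivalence classes of configurations, arcs are single-rule
transitions, and the space may contain nodes unreachable from the root
that still feed into it. The homeostatic decomposition is the fixpoint
of three clauses: the transitive closure of every directed cycle seeds
an h-component (overlapping closures merge), every leaf seeds one, and
any node whose descendant set meets exactly one h-component is absorbed
into it; the remainder is the morphogenetic phase. The implementation
seeds components from strongly connected components and their
descendants, then iterates absorption; tests verify it against an
independent oracle that literally iterates the clauses, on hundreds of
random digraphs, together with the invariant that no arc leaves any
h-component. One consequence worth noting: a linear chain ending in a
leaf is entirely homeostatic, because every prefix node's closure meets
only the leaf's component — the morphogenetic phase is nonempty only
when some node faces two or more distinct components downstream.

An injury `(x, y)` in this picture is sustainable iff both endpoints
share an h-component; its degree is the undirected graph distance. For
the self-healing degree the package draws the injured node uniformly
among homeostatic nodes and the landing node uniformly among
homeostatic nodes within distance `m` (all of them in the unbounded
case, including the injured node itself). This choice — one of several
the informal definition admits — is fixed because it reproduces the
framework's boundary cases exactly: two equal disjoint h-components sit
precisely on the 0.5 boundary (flagged as a tie), three equal
components give sustain probability 1/3, and a component holding a
fraction `p` of all nodes bounds both draws below by `p`, which yields
the dominating-component criterion: `p >= 0.71` guarantees
`p² > 0.5`, hence self-healing of any degree. Exact enumeration is used
up to 1000 nodes, Monte Carlo sampling beyond.

Exhaustive enumeration of a continuous system's configuration space is
not attempted — equivalence of continuous configurations is not
decidable in practice. Instead `enumerate_configspace()` accepts small
discrete toy systems (tiles on a line of slots with attach/detach
rules), breadth-first enumerates their spaces with equivalent states
merged, flags depth-capped partial graphs, and lets the caller add
off-path nodes and arcs.

## Numerical choices and degenerate inputs

Growth fits run on the mean census across runs, on the log-count
response `y = ln(B_t/B_0)`, with the Zwietering forms
`y = A exp(-exp(mu e / A (lambda - t) + 1))` (Gompertz) and
`y = A / (1 + exp(4 mu / A (lambda - t) + 2))` (logistic) via
Levenberg–Marquardt least squares; starting values come from the
plateau, the steepest rise and its tangent intercept. Non-convergence is
reported in the fit object, never silently; a flat census short-circuits
to a degenerate fit with `mu = 0`. `doubling_time()` returns an explicit
`NA` when the population has not grown. Note one reporting convention:
when the census table derives a doubling time, the package always
reports the formula value `t log 2 / (log B_n - log B_0)`; for the
slowest species the formula value at `B_n = 85`, 62.41 min over 400
iterations, differs in the second decimal from some published roundings
of the same quantity.

The brownian step's direction is an isotropic normal deviate
renormalised to unit length; a zero-length deviate (probability zero,
but guarded) is left in place. Box and sphere reflections handle
multiple bounces by folding. The obstruction test samples polygon
vertices, edge midpoints and centroids with a clearance of 0.01 tile
edges, adequate at whole-tile granularity.

## Problem sizes

Simulation-backed checks use the protocol sizes the census tables are
based on: 100 seeded runs of 100 iterations for the growth average, 100
replicates per injury count for survival sweeps, decomposition oracles
on 200 random digraphs of up to 12 nodes (where exhaustive checks are
feasible), and parameter recovery on noiseless synthetic censuses of 31
time points.

## What the synthetic experiments do and do not show

Every quantitative result in the package is computed on simulations of
the model itself; the model emulates the *macro-level* phenomenology of
bacterial populations — sigmoidal census curves, doubling times of the
right order, graceful degradation under injury — not the biochemistry
that produces it in living cells. No DNA replication or segregation, no
peptidoglycan chemistry, no primary/secondary septum distinction, no
hydrodynamics, and no cell-cell mechanics are modelled. Passing tests
demonstrate internal consistency of the formalism and reproduction of
the published macro-observables under the stated calibration; they are
not evidence about any particular molecular mechanism.

## Known limitations

* The capsule template fixes the wall topology; models with other
  geometries need their own template implementation.
* Injury experiments at high counts are sensitive to the re-adhesion
  and leak constants; the measured survival tail (first-below-0.5 near
  23–25, extinction near 30) should be read with that sensitivity in
  mind.
* The continuous engine requires a placement template; free-space
  attachment of arbitrary tile systems is supported only in the
  discrete toy enumerator.
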