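---
title: "Laguerre tessellations and the topology of protein hydration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laguerre tessellations and the topology of protein hydration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrotopo)
```

## The model

`hydrotopo` treats a solvated molecular system as a set of weighted sites
`(p, w)` — heavy-atom centres in Å with weights in Å² — and partitions a
bounded region into Laguerre (power) cells: site `i` owns the points `x`
with `|x − p_i|² − w_i` minimal. The partition is a complex of convex
polyhedra; two sites are *neighbours* exactly when their cells share a
polygonal face, which lies in the radical plane of the pair. The resulting
contact graph is the edge set of the dual regular (weighted Delaunay)
triangulation.

The key modelling assumptions are:

* hydrogens are discarded and each water molecule is represented by its
  oxygen only, carrying a compensating weight (default **1.48 Å²**, i.e. an
  effective radius of about 1.22 Å); every other atom, including ions, has
  weight 0. Treating ions at weight 0 is a choice — their effective size in
  a power diagram is not well constrained — and is isolated behind
  `GroupingConfig` so it can be revisited.
* the system is tessellated *whole* (protein, lipids, ions, water), and
  group-specific analyses select sub-complexes afterwards. This is what
  makes the protein surface, pockets and channels physically meaningful:
  every boundary is an interface with real neighbouring matter, not with
  vacuum.
* all analyses are per snapshot; multi-snapshot statistics (means ± rms,
  persistence, contact-area differences) are computed over whichever
  snapshot list the user passes, with no implicit time filtering.

## Building the diagram

Cells are constructed by direct half-space clipping: each cell starts as
the bounded region and is cut by the radical plane against every site that
can possibly affect it, scanned in order of increasing distance with a
security-radius early stop (no site farther than
`(d² + w_i − w_max) / 2d > r_max` can cut a cell whose vertices all lie
within `r_max` of the site). This is the construction used by radical
Voronoi codes such as Voro++. We chose it over the classical lifting of
`(p, w)` to a 4D convex hull because it needs no convex-hull primitive,
yields volumes, faces and the adjacency graph in one pass, and makes
volume conservation — the sum of cell volumes must equal the region volume
— an exact, testable invariant. The construction is deterministic for a
fixed input order; grazing (tangent) contacts are ignored at tolerance, so
ties are resolved identically on every run.

Two boundary treatments are provided for box regions and give identical
geometry (a tested invariant): direct clipping by the wall planes
(default), and ghost mirroring, where every site is reflected through each
wall so that the radical plane to its equal-weight mirror image *is* the
wall. Spherical regions are materialised as a polyhedral ball (tangent
planes at 42 near-uniform directions); `regionVolume()` returns the exact
polytope volume so conservation stays exact there too.

Degenerate inputs behave as follows: coincident sites with identical
weights are an error; coincident sites with different weights are legal
(the lighter one gets an empty cell); globally collinear or coplanar site
sets are *not* an error under clipping — the cells are well-defined prisms
— and are covered by a test. Empty Laguerre cells (sites swallowed by
heavier neighbours, a normal power-diagram phenomenon) are flagged,
excluded from all graphs, and reported via `emptyCells()`.

## Numerical choices

| quantity | default | rationale |
|---|---|---|
| plane-classification tolerance | `1e-10 ×` region diagonal | separates genuine cuts from floating-point grazing |
| sliver face threshold | `1e-10 Å²` | sliver faces create spurious contacts that corrupt genus and path counts |
| surface vertex deduplication | `1e-6 Å` (grid hash + union-find) | Laguerre vertices of adjacent cells coincide only up to floating-point noise; the union-find merge also catches pairs straddling a rounding boundary |
| water weight | `1.48 Å²` | calibrated value (see below) |
| widest-path potential | `(3 Å / d)⁶`, penalty `(3/d_p)⁶` | strongly penalises approach to protein atoms; `d_p = 0.1` enforces disjointness, `d_p = 1` soft bundles |
| source shell thickness | `3 Å` above the membrane slab | a thin extracellular band; configurable |
| enclosing-sphere augmentation | `1.4 Å` | the standard water radius |
| opening cluster cutoff `d_open` | `6 Å`, single linkage | entries closer than two water shells belong to one mouth |
| effective-radius vdW subtraction | `1.1 Å`, floored at 0 | converts centre–centre distance to an effective channel radius |

## Surfaces, gluing and the genus

The boundary surface of a site cluster is the set of faces with exactly one
endpoint in the cluster, plus the region-wall faces of cluster cells (so
surfaces are closed at the region boundary). Faces are glued
*combinatorially*: edge instances are matched pairwise, corners are merged
through the gluing, and `V`, `E`, `F` are counted on the glued complex, so
`χ = V − E + F` and `g = (2 − χ)/2` are well-defined per connected
component. The headline genus of a domain is that of its largest-area
component; smaller closed components bound water inclusions and are
reported separately.

Pinched (non-manifold) edges — an edge shared by four or more faces where
two sheets of the surface touch — are resolved by default by splitting the
sheets: the faces around the edge are sorted by angle, wedges are
classified interior/exterior using the face orientation towards the
cluster, and faces sharing an interior wedge are glued together
(`pinch = "strict"` raises instead). Splitting keeps the genus
well-defined and counts the passages in the intended way; both behaviours
are exposed because there is no canonical answer for pinched complexes.

## Paths

Disjoint-path counting is greedy: the shortest (Euclidean edge length)
source→target water path is found by Dijkstra, its nodes are removed, and
the search repeats. The count is a lower bound on the Menger number
(maximum vertex-disjoint paths); the test suite checks `DP ≤ Menger` on
200 seeded random graphs against an exhaustive max-flow oracle, with
equality on all engineered channel fixtures. Greedy removal matches the
iterated-Dijkstra semantics of the method and is what the reported DP
means.

Widest paths minimise the summed vertex potential `φ`. The vertex-cost
search is reduced exactly to an edge-weighted Dijkstra by assigning each
edge `(φ_u + φ_v)/2` and attaching half the endpoint costs at virtual
terminals, so path cost equals `Σ φ` over visited vertices, endpoints
included; path length enters only through the number of terms. Iteration
increments the visit multiplicity `m(x)` and stops at `nIter` paths or when
the cheapest remaining path reaches `maxCost` (default `1e6`, far below
the `d_p = 0.1` revisit penalty of `30⁶ ≈ 7.3·10⁸`, so strict runs stop
before any reuse). A path is **direct** when, once inside the protein
envelope (membrane slab ∩ augmented enclosing sphere), it stays there
until its final exit; this operationalisation of "does not escape back to
the external medium" is deliberately simple and configurable through the
region specification.

## Water-weight calibration

The reference computation keeps water hydrogens (all weights 0) and
records mean and rms of the per-molecule Laguerre volume of *interfacial*
waters — those sharing a face with protein, lipid or ligand. The
production representation (O only, weight `w = r²`) is then scanned over a
radius grid and `f(r) = Σᵢ ((v̄ᵢ − v̄_ref)² + (σᵢ − σ_ref)²)` is minimised.
Two details matter in practice:

* molecules whose cells are clipped by the region boundary are excluded
  from the interfacial statistics: their truncated volumes are artifacts of
  the bounded region, not of the solute interface, and they dominate the
  variance if kept;
* when the reference is generated from the stripped configuration itself at
  some weight `w₀`, the scan recovers `w₀` with `f = 0` exactly — the
  self-consistency test.

## Synthetic systems and what they do (not) show

The generators build toy systems on jittered lattices: waters at 2.9 Å
spacing with ±0.2 Å uniform jitter (dense enough that lattice neighbours
are Laguerre-adjacent, jittered enough to avoid degenerate cosphericity),
wall atoms at 1.8 Å spacing (dense enough that no water contact leaks
through a wall). Ground-truth facts — channel counts, genus, traversal,
inclusion counts — are validated by voxel-grid oracles (flood fill for
connectivity, Euler counts of the voxel boundary surface for genus) that
never touch the tessellation code.

Passing these suites shows that the geometry, graph and topology machinery
is correct on systems with known answers. It does **not** show that the
biological conclusions drawn from any particular simulation are right:
real systems have disordered interfaces, flexible side chains,
heterogeneous atom sizes and much larger interfacial layers, none of which
the lattice toys emulate. In particular the calibrated weight recovered on
toy slabs is a property of the toy geometry, not a substitute for the
production value of 1.48 Å² obtained on real solvated systems.

Problem sizes used by the default test and acceptance runs — packings of
10–500 sites, slabs and barrels of one to a few thousand sites, 3-snapshot
calibration sets resampled 5 times — were chosen as the smallest systems
on which the tested properties are stable and sharply defined.

## Contact-area tables

Group-pair interface areas are averaged over snapshots with the population
rms (divide by *n*) as the deviation, matching the mean ± rms convention
used throughout; sample standard deviation is available as an option. In
difference tables, `ΔA = A_comp − A_free`, and the relative column divides
by `A_p`, the *complexed-condition* mean total domain surface — the one
denominator convention that reproduces every percentage of the reference
bookkeeping replayed in the acceptance suite; it is configurable
(`ApCondition`). Key-residue selection applies fixed thresholds to
per-residue `ΔA` values (defaults −20 Å² against the barrel partner,
+20 Å² towards water) and orders hits by `|ΔA|`.

## Known limitations

* No periodic boundary conditions: snapshots are tessellated in a bounded
  region, and cells at the region boundary are flagged rather than wrapped.
* The greedy disjoint-path count can undercount the Menger number on
  adversarial graphs (it never overcounts).
* Spherical regions are polyhedral approximations; for exact spherical
  clipping use a box region enclosing the sphere and filter afterwards.
* The direct/indirect classification and the opening census depend on the
  membrane-slab and sphere parameters; both are reported with their
  configuration so runs are comparable.
* Exact rational arithmetic is not used; all tolerances are documented
  above and the conservation/duality invariants are tested at `1e-6`
  relative or better.
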