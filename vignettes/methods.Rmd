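---
title: "Methods: graph decomposition, proofreading and connectivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph decomposition, proofreading and connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurodecomp)
```

This vignette is the package's own account of its models and procedures:
what each stage assumes, which tunable parameters matter (with units and
defaults), what the synthetic generator does and does not emulate, and the
numerical choices made where the design was genuinely open. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The decomposition model

A reconstruction arrives as a triangle mesh in nanometre coordinates plus
a synapse table (id, presynaptic and postsynaptic segment ids, position,
cleft size in voxels). The central representation is a *soma-rooted
directed tree of non-branching segments*: the soma is the singular root
node; cutting the skeleton at the soma surface and at every branch point
yields maximal unbranched paths, each of which becomes one node (a
*branch*) carrying its sub-polyline, per-point width, mesh face set,
synapses and spines; edges point downstream, and a root child together
with its descendants forms a *stem*. This graph is small (tens of nodes
for a cell with hundreds of micrometres of cable), so queries that mix
geometry ("width jump against the parent"), topology ("descendant
closure") and annotation ("outgoing-synapse fraction") are cheap — that is
what the proofreading rules, the classifiers and the connectivity
analyses all exploit.

All internal lengths are nm; densities are quoted per µm and converted
once at parameter intake; SWC output alone is written in µm (the
NeuroMorpho convention: space-separated `id type x y z radius parent`,
type codes 1 soma / 2 axon / 3 basal / 4 apical, root parent −1).

## Soma detection

Candidate soma interiors are found by an inward chord probe: from each
sampled surface vertex, the nearest opposite surface point inside a
narrow cone around the inward normal gives a local thickness; vertices
whose half-chord reaches `min_radius` (default 2 500 nm, cap 15 000 nm)
vote for a ball centre. Vote clusters are screened twice: the putative
ball surface must surround its centre in all directions (mean unit
direction of shell vertices below 0.4 — chords between distant parallel
processes fail this), and the submesh sphericity
\((36\pi V^2/A^3)^{1/3}\) must reach `compactness_threshold`
(default 0.7). Detections are ordered by volume and deduplicated by
non-maximum suppression. On the generator's scenes with 0–2 somas this
recovers every soma and nothing else (see `test-mesh-preprocess.R`).

## Skeletonization

The centreline is extracted TEASAR-style. One Dijkstra pass over the mesh
vertex graph from the soma surface (a virtual source ties all soma
vertices at distance zero) gives geodesic distances and a predecessor
tree. The skeleton grows by repeatedly walking the predecessor tree from
the farthest vertex not yet covered and invalidating a corridor of
`invalidation_radius` (default 4 000 nm) around the extracted path —
the corridor swallows spines and surface detail, so they do not become
skeleton branches. Paths are resampled at `step` (default 1 000 nm) and
each kept point is recentred to the centroid of nearby surface vertices.

Two details matter in practice and are worth recording:

* **Corridor mapping must respect geodesic structure.** Later paths may
  run along the far side of a tube already skeletonized; they attach to
  the existing node their surface corridor maps to. That mapping is
  restricted to vertices of the same Dijkstra region (same source soma)
  and compatible geodesic depth — otherwise branches that merely pass
  close in space (or a second welded neuron) would be captured and the
  topology corrupted.
* **Recentring must resist spines.** Kept points are recentred by chord
  casting — the axis sits halfway along the chord from the surface vertex
  to the opposite wall, found inside a narrow cone around the inward
  normal — which is unaffected by spines and passing branches by
  construction (a neighbourhood-centroid recentring gets pulled hundreds
  of nanometres off axis next to large spines, degrading width and
  protrusion estimates downstream). Where no valid chord exists the
  fallback is a trimmed centroid over a geodesic-depth band.

Leaf twigs shorter than `prune` (default 4 000 nm — above the tallest
generator spine, below any genuine terminal branch) are removed, and
degree-2 points are lightly smoothed. With several somas the per-soma
predecessor trees meet at a geodesic watershed without sharing vertices;
the components are stitched across the mesh edge closest to the watershed
minimum. The contract, not the algorithm, is normative: total length
within 5% of the generated cable, exactly one degree-3 point for a
T-junction, endpoints at the mesh tips, soma collapsed to its centroid.

## Mesh correspondence and width

Every face goes to its nearest skeleton edge (face-centroid to segment
distance, ties to the lower edge index). The width at a skeleton point is
**twice the lower quartile** of the distances of the faces assigned to
its incident edges. The lower quartile, rather than the median, is a
deliberate robustness choice: next to a large mushroom spine the spine
contributes more faces than the shaft locally, and the median jumps to
the spine surface while the lower quartile stays on the shaft. On a clean
cylinder the two agree to within a few percent.

## Automated proofreading

Four rule families are implemented behind one flag-and-strip interface;
each returns flagged branch ids, and `apply_filters()` removes every
flagged node's descendant closure (including the node) before the next
rule runs, marks the removed synapses invalid, and logs an edit record
with the rule, parameter snapshot, cut location, removed nodes, synapses
and skeletal length. Rules run coarse-to-fine — whole foreign subtrees
first, local geometry last — because a single subtree edit subsumes many
local ones:

1. `axon_on_dendrite` — subtrees hanging off a dendrite whose aggregate
   profile is axon-like: spine density ≤ 0.2 µm⁻¹, outgoing-synapse
   fraction ≥ 0.75, thinner than the host, and at least 3 synapses of
   evidence (a synapse-free subtree is never flagged).
2. `axon_degree` — axonal branch points with more than 3 children, plus a
   crossover variant: a pair of children forming a near-collinear
   throughway (pass-through deviation < 35°) that is not the parent's
   continuation is a foreign axon passing through. Since a crossing often
   skeletonizes as two nearby degree-3 points, the rule looks through
   connector branches shorter than 4 µm.
3. `double_back` — children whose branching angle against the parent
   exceeds 120° *and* whose mean direction points back at the soma.
4. `width_jump` — children whose starting width exceeds the parent's
   ending width by more than 500 nm, with the additional requirement that
   the jump is sustained over the branch bodies (endpoint widths alone
   are contaminated by the neighbour's faces at the junction; without the
   sustained-jump condition clean bifurcations are occasionally flagged).

All thresholds are engineering defaults exposed in the configuration;
start/end widths are medians over the proximal/distal third of the
profile for the same junction-contamination reason.

Multi-soma splitting scores every edge on the soma-to-soma skeleton path
with a suspicion score — 0.5 · (inverted, path-normalised width minimum)
+ 0.3 · (local double-back angle) + 0.2 · (outgoing-fraction mismatch
between 20 µm windows on either side, using only synapses lying within
5 µm of the path) — and cuts the maximum, excluding a 10 µm buffer at
each soma where a cut would be degenerate. The windowed, path-local
mismatch matters: aggregating whole-side synapses makes both sides of a
two-neuron merge look identical (each side is a complete neuron), whereas
locally an axon-to-dendrite weld joins stretches of opposite synaptic
polarity.

## Spines

Faces farther from the branch skeleton than `shaft_factor` (1.4) times
the local shaft radius are protruding; the local radius is capped at 1.2×
the branch median so a spine cannot mask itself. Components are formed at
a higher core threshold (+400 nm) and grown back through the protruding
skirt (a surface watershed) so adjacent spines whose skirts touch do not
merge; skirt regions unreachable from any core (short spines entirely
below the core threshold) form their own components. Components need at
least `min_faces` (20 at the bundled meshing resolution) and a height
below 4 µm (taller protrusions are junction geometry, not spines). The
spine's skeletal length is the height of its farthest face centroid above
the local shaft surface.

Head/neck segmentation bins the radial width profile along the base-to-tip
axis; if a bin falls below `neck_ratio` (0.6) times the maximum width
distal to it, the minimum such bin is the neck, faces beyond it are the
head, and the head volume is computed by the divergence theorem over the
head face set closed at the cut ring (exact for closed meshes; verified
against spheres). "No neck" is a valid outcome and is what stubby spines
produce. The 700 nm skeletal-length threshold used in the detection
benchmark is deliberately straddled by the generator: mushroom spines
(800–2 400 nm) lie above it, stubby spines (300–600 nm) below.

## Cell typing and compartments

The excitatory/inhibitory classifier is a two-feature logistic
regression — dendritic spine density and dendritic shaft-synapse density,
both per µm — fit by maximum likelihood (`glm`, convex, deterministic).
Whether counts or densities, and over which compartments, the features
are computed is configurable; densities over non-axonal branches are the
default because they are scale-free across cell sizes. The axon stem is
the stem maximising outgoing-synapse fraction penalised by spine density
and width, above a 0.5 outgoing-fraction floor; ties break to the lowest
stem id. The AIS is the proximal window of the axon (walk distance below
`ais_window`, default 50 µm — a default, not a measured value). For
excitatory cells the dendritic stem pointing most directly away from the
depth axis with the largest initial width is apical and its offshoots
oblique; inhibitory cells keep all dendrites basal.

## Proximities, conversion rates, motifs

The axon skeleton is resampled at 500 nm; for each sample the nearest
postsynaptic dendritic (optionally somatic) skeleton distance is found;
contiguous runs of samples within `radius` (default 5 000 nm) merge into
one proximity event, and events on the same pair merge when separated
along the axon by less than `min_gap` (default 10 000 nm — the paper-scale
separation of distinct passes is not pinned down anywhere, so this is an
explicit operational choice). Run-length merging along the axon, rather
than spatial clustering, keeps events deterministic and order-free. A
synapse links to the event whose axon run passes nearest, within
`link_radius`; the conversion rate is the fraction of events with at
least one linked synapse, and stratified rates re-threshold stored
minimum distances without recomputation. Skeletal walks are exact tree
path sums from the projected point to the root.

The connectivity graph collapses valid synapses into weighted directed
edges (autapses excluded by default). The triad census counts all
\(\binom{n}{3}\) triples over the 16 directed isomorphism classes
(igraph's census, cross-checked in the tests against a hand-rolled
dyad-state enumeration), with an edge-count coarsening (0–6 edges per
triple). Three null ensembles: directed double-edge swaps with a
10·|E| burn-in between samples (degrees conserved); |E| edges drawn
uniformly from a companion proximity edge set; and uniform endpoint
rewiring without self-loops. Enrichment is the per-class z-score and fold
ratio against the ensemble; 250 samples is the default ensemble size.

## The synthetic generator, and what passing tests do not show

The generator emulates exactly the structure the pipeline assumes:
frustum-swept tubes with monotone taper, an icosphere soma, spines and
synapses placed by Poisson statistics with compartment-dependent
densities (axon 1 µm⁻¹ outgoing, dendritic shaft 0.15 µm⁻¹ incoming,
spine density 1 µm⁻¹, head-synapse probability 0.9 with synapse size
coupled to head volume), and five merge-error families welded on with
exact face labels. Welds avoid boolean union: parts interpenetrate and a
small labelled collar keeps the mesh one connected component while the
face-level truth stays exact. One integer seed drives everything through
fixed sub-stream offsets; identical parameters and seed give identical
output.

It does **not** emulate electron-microscopy noise, mesh holes,
non-manifold artifacts, realistic cortical neuropil density, vasculature,
or glia beyond a spine-free lumpy blob preset. Passing the synthetic
benchmarks therefore demonstrates that the algorithms are correct on
geometry satisfying their assumptions — not that the default thresholds
transfer to any particular real volume, where they would need the same
kind of proofreader-in-the-loop calibration any heuristic system needs.

Problem sizes in the tests (neurons of ~250–300 µm cable at meshing
resolution 10, 20-seed benchmarks, 30–50 node connectomes) were chosen as
the smallest scales at which the statistical claims are meaningful;
generator parameters are fixed study conditions, not tuning knobs.

## Known limitations

* Merge errors that continue a branch collinearly (no branch point in the
  skeleton) are invisible to node-level rules by construction.
* Proofreading only removes data; false splits are out of scope.
* Soma-proximal spines inside the soma cut-ball accrue to the root and
  are not detectable.
* The multi-soma suspicion score assumes the merged cells carry synapse
  annotations; on synapse-free meshes only the width and angle terms act.
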