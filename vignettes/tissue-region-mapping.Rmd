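---
title: "Mapping tissue regions from multiplexed imaging: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping tissue regions from multiplexed imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tissuemap` analyzes tables of segmented cell objects — one record per cell
with a sample id, a phenotype label from a fixed per-run vocabulary, a
position in micrometers, and per-channel mean fluorescence intensities
(columns prefixed `ch_`). This vignette explains the model behind each
stage, the tunable parameters and their defaults, and the numerical and
design choices a maintainer would want spelled out. Landmark "spot" objects
have no special status: import them as ordinary phenotypes (e.g.
`"CD3_spot"`) and they flow through every stage like cells.

## Neighborhoods

The elementary unit of analysis is the *neighborhood*: all cells within a
fixed radius of a center point, counted per phenotype, plus the summed
channel intensity over member cells. Two ways of placing centers are
provided:

* `raster_neighborhoods(cells, radius)` lays an axis-aligned grid over each
  sample, anchored at the per-sample coordinate minima, with center spacing
  of **half the radius**, running through the maxima. The factor-of-two
  overlap means each interior cell belongs to at least four neighborhoods
  in 2D, which smooths the composition field without losing locality.
* `cell_neighborhoods(cells, centers, radius)` puts one neighborhood on
  every center object (e.g. each blood-vessel landmark), for object-focused
  questions such as which cell types associate with vasculature.

Membership is the **closed** Euclidean ball (distance ≤ radius): the closed
boundary makes the brute-force contract exactly reproducible. Whether the
ball is a cylinder (distance in x–y only) or a sphere (x–y–z) is decided
per sample: if the z extent `max(z) − min(z)` is smaller than the radius,
the section is effectively 2D and a cylindrical window is used. This
matches thin physical sections (a 20 µm section with a 30 µm radius) while
volumetric data get true spherical neighborhoods. The rule can be forced
either way with `geometry =`.

The default radius of 30 µm balances spatial granularity against noise:
much larger windows over-smooth real heterogeneity, much smaller ones
produce noisy compositions and more neighborhoods than cells. It is also
commensurate with cytokine dispersion distances, i.e. the scale at which
"cellular neighborhood" is biologically meaningful.

Empty neighborhoods are **kept**: background is informative (it forms its
own region and carries the tissue outline). The counting kernel is an exact
all-pairs scan in C++; its contract (and its test oracle) is the brute-force
recount, so no spatial-index approximation can change results.

In cell-centered mode the center object itself is counted when its
phenotype is in the feature vocabulary; `include_center = FALSE` subtracts
each center's own contribution, assuming centers are rows of the cell
table. Both behaviors are exposed because either convention is defensible.

## Features and region clustering

`nbhd_features()` turns counts into one of three clustering spaces:
`raw` counts, `composition` (row fractions; empty rows stay zero), or
`standardized` (per-column z-scores pooled across all training samples).
Standardization statistics are frozen on the returned object so held-out
samples can be projected onto the training scale (`stats =
feature_stats(trained)`); zero-variance columns are set to 0 with a warning
rather than an error, since a phenotype absent from a run should not abort
it. Channel-intensity features (`include_channels = TRUE`) are off by
default: counts alone define regions, intensities are for embeddings.

Regions are found with a **1-D self-organizing map**: a chain of NR
prototypes initialized on NR distinct data rows (sampled with the run
seed), trained with 200 batch epochs. The chain neighborhood is a bubble
whose radius decays linearly from ⌈NR/3⌉ to 0 over the first 100 epochs;
thereafter updates are nearest-only, i.e. Lloyd iterations constrained to
the learned ordering. Ties in the nearest-prototype assignment go to the
lowest index. If a prototype loses all members during the nearest-only
phase it is relocated to the currently worst-quantized data row — the
standard deterministic empty-cluster repair; without it a stranded unit can
silently merge two genuine regions. Everything is deterministic given the
seed, which the tests assert across repeated runs.

The number of regions is selected by the **Davies-Bouldin index**,

> DB = (1/k) Σᵢ maxⱼ≠ᵢ (sᵢ + sⱼ) / dᵢⱼ,

with sᵢ the mean Euclidean distance of cluster members to their centroid
and dᵢⱼ the centroid separation. `select_regions()` trains one SOM per
candidate k (default sweep 2–10, allowed range [2, min(50, n−1)]), scores
the *SOM's own labels* (not a separate k-means — the model selected is the
model used), and picks the minimum, breaking ties toward the smaller k.
Singleton clusters are legal (sᵢ = 0); a candidate whose SOM occupies fewer
than two clusters scores Inf.

`annotate_regions()` attaches composite labels (e.g. regions 3 and 4 both
→ "TZ") without touching the underlying indices, mirroring the common
workflow of clustering finely and then merging by expert annotation.

## Spatial statistics

`correlate_counts()` computes pairwise Pearson correlations of phenotype
counts across neighborhoods, per sample, and averages the per-sample
matrices without weighting to give the cohort view; restricting the scope
to one region answers "who associates with whom *inside* this
compartment". Zero-variance phenotypes yield *missing* correlations, never
0 — absence of evidence is not independence — and missing entries are
excluded pairwise from the cohort mean. Significance uses the exact
Student-t transform t = r√(n−2)/√(1−r²) on n−2 degrees of freedom
(two-sided); p-values are reported unadjusted, with `stats::p.adjust` a
one-liner away for users who want Benjamini-Hochberg across pairs. The
per-sample-then-average convention (rather than pooling neighborhoods) keeps
samples exchangeable; pooling remains available by concatenating tables
under one sample id.

`pseudo_space()` collapses tissue organization onto one axis: each
neighborhood's sort key is Σ w_c f_c over the chosen per-phenotype feature
(composition by default), so negatively weighted phenotypes sort left and
positively weighted ones right. The sort is ascending and stable with the
input index as final tie-break, making the ordering reproducible and
invariant to positive rescaling of the weights. Curves are smoothed with an
edge-truncated boxcar (the window is expressed in neighborhoods; window 1
is the identity) and normalized each to its own maximum so cell types of
very different abundance share one y axis; all-zero curves stay zero. A
boxcar was chosen because the smoothing amount should be the only free
parameter — no kernel shape to tune.

## Surfaces, distances, and random controls

`make_surface()` wraps a point set in an **alpha shape**: a boundary facet
is any segment (2D) or triangle (3D) whose vertices admit an empty
circumscribed disk/sphere of radius alpha. This is the literal definition,
implemented directly in C++ (O(n²·n) in 2D, O(n³·n) in 3D) — at the point
counts involved (region outlines, boundary samplings of a few hundred
points) exactness is worth more than asymptotics, and the convex hull is
recovered in the alpha → ∞ limit, which the tests check against an
independent hull routine. Numerical guards: a point counts as violating a
candidate facet only if it is inside the alpha ball by more than a 1e-9
relative tolerance, so cocircular grids do not flicker; degenerate inputs
(all collinear / all coplanar) are rejected with the degeneracy named.

When the input is a neighborhood table the default alpha is **twice the
raster grid spacing** (= the neighborhood radius): region surfaces wrap
centers spaced radius/2 apart, and 2× spacing is the smallest alpha that
cannot fall through the grid.

Containment is even-odd (crossing parity in 2D, ray-triangle parity in 3D,
with an irrational ray direction to avoid grazing hits); boundary points
count as inside, and gating keeps contained points. `signed_distance()`
returns the Euclidean distance to the nearest boundary facet (faces, not
vertices, in 3D), negated inside — "left of zero means inside the region".
The accuracy of boundary-sampled surfaces is limited by the sampling: a
256-point circle approximates the disk's center distance to within
1 − cos(π/256) ≈ 7·10⁻⁵, well inside the 0.02 relative tolerance the tests
use.

`nearest_object_distance()` is the exact nearest-neighbor distance (kd-tree
backed, brute-force verified); `proximal_fraction(d, cutoff = 20)`
summarizes it as the fraction of cells strictly below the cutoff, 20 µm
being the conventional vascular-proximity threshold.
`generate_random_points()` draws uniform control points on the reference
bounding box — only over the plotted axes: a flat reference keeps z
constant — with all channels 0 and phenotype `"RDP"`; gate them with a
tissue surface to obtain a spatial null for any distance analysis.

## Region networks and embeddings

`region_contact_matrix()` reports, for every ordered region pair (i, j),
the percentage of region-i neighborhoods with at least one region-j
neighborhood within the contact radius (self-pairing excluded; the
diagonal is the self-contact). "Direct contact" needs a definition on a
raster grid: the default contact radius is 1.1 × spacing × √2, the smallest
distance class that captures the full 8-neighborhood of the grid with 10 %
slack against floating-point drift. The matrix is deliberately directional
(region sizes differ); `build_network()` takes the larger of the two
directions as the edge weight and keeps an edge iff the contact percentage
**exceeds 0.005 %**. That printed threshold is strikingly permissive —
nearly any observed contact qualifies — but it is the documented default
and is kept as such rather than "corrected"; it is configurable. Node size
carries the region's neighborhood count; self-contact is a node attribute
rather than a loop edge. Force-directed layout is presentation only and
outside the tested surface.

`reduce_dimensions()` wraps PCA (deterministic), Barnes-Hut t-SNE
(Euclidean distance, perplexity 30, theta 0.5, exaggeration 4 as defaults),
and UMAP, all seeded; only plumbing and determinism are promised, the
internals belong to their packages. PHATE is not wrapped (no maintained R
implementation); PCA/t-SNE/UMAP cover the use cases.

## The synthetic tissue generator

`simulate_tissue()` draws, per compartment and phenotype, a homogeneous
Poisson point process at the stated intensity (cells/µm²), clipped to the
compartment and thinned by later-painted compartments (later-wins
precedence), so realized densities are exactly the specified ones. z is
uniform over a section thickness (default 20 µm — a realistic physical
section, and thin enough to engage the cylindrical-window rule at the
default radius). Channels are lognormal with a bright own-marker channel
(meanlog 4) against dim off-target channels (meanlog 1, sdlog 0.5),
emulating well-separated staining. The ground truth is a position→label
*oracle function*, so neighborhood centers — not only cells — can be truth
labeled for adjusted-Rand-index validation.

`ln_preset()` emulates lymph-node organization on a 1,000 µm-diameter
disk: a central T zone (radius 400 µm; T 0.015, B 0.002, DC 0.004 /µm²), a
100 µm medullary ring (Mac 0.010, DC 0.006, T 0.002, B 0.002), and six
peripheral follicles (radius 120 µm at 380 µm from the center, painted on
top; B 0.020, T 0.002, DC 0.001 — a 10:1 B:T contrast). These intensities
were fixed once as realistic relative density contrasts at desk scale
(≈ 17,000 cells per tissue, ≈ 4,500 raster neighborhoods at radius 30 µm);
the validation suite runs the full pipeline on 10 such tissues and the
acceptance script on 5, sizes chosen so the whole battery stays
interactive.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: spatial interaction between cells (no
attraction/repulsion beyond compartment boundaries; Poisson only),
segmentation errors and doublets, intensity spillover between channels,
staining gradients, irregular organ outlines, and 3D compartment geometry
(compartments are prisms through the section). Region recovery on this
tissue validates the machinery, not the biology of any particular organ.

## Degenerate inputs and edge policies, in one place

* Empty cell table, empty centers, radius ≤ 0, window < 1, n < 4 for model
  selection, NR > n: typed errors (`tissuemap_*_error` classes).
* Missing required CSV columns: schema error naming the columns;
  non-numeric positions: parse error naming the row.
* Composition of an empty neighborhood: zero vector (not NaN).
* Zero-variance features: standardized to 0 with a warning; zero-variance
  phenotypes in correlation: missing, not 0.
* |r| = 1: p = 0 by convention.
* Equal-distance prototype ties: lowest index; sort ties in pseudo-space:
  input order.
* Boundary membership: closed ball for neighborhoods, boundary-inclusive
  containment for surfaces, distance 0 on the boundary.
* Expected synthetic cell count above 10⁷: refused.

## Limitations

The alpha-shape kernels are exact but cubic/quartic; for boundary point
sets beyond a few thousand points a Delaunay-filtered implementation would
be the next step. The SOM is a 1-D chain by design (regions are a
partition, not a 2-D map); consensus clustering and automatic region naming
are out of scope. FCS input is not parsed: phenotypes must arrive
pre-assigned in the CSV dialect (gating belongs to upstream tools), and CSV
is the canonical interchange format throughout.
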