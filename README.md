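# tissuemap

Quantitative spatial analysis of multiplexed tissue imaging data in R.

Modern multiplexed imaging (histo-cytometry, CODEX-style panels, confocal
volumes segmented into single cells) produces tables of hundreds of
thousands of cell objects, each with a phenotype label, an x/y/z position in
micrometers, and per-channel mean fluorescence intensities. `tissuemap`
turns such tables into a quantitative picture of tissue architecture:

1. **Neighborhoods.** A circular (2D) or spherical (3D) window of radius
   *r* is raster-scanned over the tissue on a grid with spacing *r*/2 (or
   centered on a chosen object type, e.g. blood vessels), recording the
   number of cells of each phenotype and the summed channel intensities in
   every window. Samples whose z extent is smaller than *r* are treated as
   effectively 2D with a cylindrical window.
2. **Regions.** Neighborhood composition vectors are clustered with a 1-D
   self-organizing map (a chain of NR "neurons" pulled toward the data);
   the number of regions NR is chosen automatically as the minimum of the
   Davies-Bouldin index, DB = (1/k) Σᵢ maxⱼ≠ᵢ (sᵢ+sⱼ)/dᵢⱼ, over a sweep of
   candidate counts. Regions can be manually annotated and merged.
3. **Spatial statistics.** Pearson correlations of per-phenotype counts
   across neighborhoods (whole-tissue or within-region, per-sample and
   cohort-averaged, with Student-t p-values) reveal which populations
   co-occur or avoid one another; *pseudo-space* sorts neighborhoods along
   a weighted 1-D composition axis to visualize compositional transitions.
4. **Geometry.** Alpha-shape surfaces wrap any point set (region
   boundaries, tissue outlines) and support point gating, signed distances
   to borders (negative = inside), nearest-object distances with a
   proximal-fraction summary, and uniform random control points (RDPs).
5. **Networks.** A region-interaction graph connects regions whose
   neighborhoods are in direct contact (above a 0.005 % contact
   threshold), with node size proportional to region abundance. Seeded
   t-SNE/PCA/UMAP wrappers embed neighborhoods for visualization.

A seedable synthetic-tissue generator (`simulate_tissue()`, `ln_preset()`)
produces compartmentalized Poisson point patterns — peripheral B-cell
follicles, a central T zone, a macrophage/DC-rich medullary ring — with a
ground-truth label oracle, so every stage of the pipeline can be validated
without any imaging data.

## Worked example

```r
library(tissuemap)

cells <- simulate_tissue(ln_preset(), seed = 1)   # 16,855 cells
table(cells$phenotype)
#>    B   DC  Mac    T
#> 6433 2671 1702 6049

nb  <- raster_neighborhoods(cells, radius = 30)   # 4,489 neighborhoods
fx  <- nbhd_features(nb, mode = "composition")
mod <- select_regions(fx, sweep = 2:10, seed = 1)
mod
#> Tissue region model
#>   regions (Davies-Bouldin minimum): 4
#>   sweep: 2..10; feature mode: composition; seed: 1
#>   neighborhoods: 4489
```

The four regions are the B-cell follicles, the T zone, the medullary ring,
and the empty background — against the generator's ground truth the
clustering reaches an adjusted Rand index of 0.83:

```r
truth <- compartment_label(ln_preset(), nb$x, nb$y)
mclust::adjustedRandIndex(mod$labels, truth)
#> [1] 0.8309
```

Spatial correlations recover the planted organization — B cells avoid T
cells and macrophages (mutually exclusive compartments), DCs co-occur with
both T cells and macrophages (shared T-zone/medullary presence):

```r
round(correlate_counts(nb)$cohort_r, 2)
#>         B    DC   Mac     T
#> B    1.00 -0.29 -0.18 -0.26
#> DC  -0.29  1.00  0.48  0.51
#> Mac -0.18  0.48  1.00 -0.29
#> T   -0.26  0.51 -0.29  1.00

build_network(region_contact_matrix(nb, region_assignment(mod)))
#> Region interaction network: 4 regions, 6 edges (threshold 0.005%)
```

`autoplot()` methods draw the DB curve, pseudo-space curves, correlation
heatmaps, embeddings and region networks; `plot_regions(nb, assignment)`
draws the region map itself. A command-line front end over the same
functions lives at `inst/cli/tissuemap.R`
(`Rscript inst/cli/tissuemap.R simulate --preset ln --seed 3 --out cells.csv`, etc.).

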