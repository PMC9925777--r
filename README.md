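# topoholes

Topological quantification of micro-hole microstructure in 2D microscopy
images.

Bone imaged by label-free non-linear microscopy — second harmonic generation
(SHG, collagen-specific) or two-photon autofluorescence (TPaF) — shows its
porosity as *micro-holes*: connected regions of low signal that span
structures such as osteocyte lacunae and vascular canals. `topoholes`
measures the number, size, crowding and arrangement of these holes with
persistent homology, turns them into interpretable per-patch statistics,
and uses those statistics for hypothesis testing and classification of
pathological versus control tissue. The same machinery applies to any
binary "signal with holes" imagery.

## Method at a glance

1. **Preprocess** — Otsu-threshold the whole greyscale image, trim empty
   borders, pad, and tile into non-overlapping 300 × 300 binary patches,
   discarding all-background tiles.
2. **SEDT** — each pixel gets the signed Euclidean distance to the opposite
   phase: negative inside holes, positive in signal.
3. **Cubical persistent homology** — the sublevel-set filtration of the
   SEDT field (V-construction: pixels → vertices, 4-neighbour edges, 2 × 2
   squares, cell value = max over vertices) is swept from the most negative
   to the most positive distance δ. H0 tracks connected components, H1
   tracks loops; each feature is a point (b, d) with b < d.
4. **Quadrants** — with the SEDT filtration the diagram quadrants carry
   direct meaning. For a hole point in H0 quadrant 2 (b < 0 < d):
   −b is the radius of the largest circle inscribed in the hole, and d is
   half the distance to its nearest hole (crowding). H1 quadrant 1 holds
   loops of signal surrounded by holes. The single never-dying H0 class
   (usually exterior background) is excluded from all statistics.
5. **Statistics** — per patch and quadrant: point count, persistent entropy
   `−Σ (p_i/P) log(p_i/P)` with lifetimes `p_i = d_i − b_i` and total
   persistence `P = Σ p_i`, mean/median/quartiles/IQR/s.d. of births and
   deaths, and counts of holes with radius ≥ 2 px and < 2 px — a canonical
   panel of 28 statistics.
6. **Inference** — permutation tests (10,000 shuffles) on group mean
   differences, paired sign-flip tests between modalities, and
   Benjamini–Hochberg FDR control per test family; a radial-basis SVC
   (C = 3) under repeated stratified 10-fold cross-validation classifies
   patches from 10 (H0) or 20 (H0 + H1) statistics.

A synthetic generator plants disk/annulus micro-holes with known radii and
spacing so the entire chain is validated against ground truth.

## Worked example

```r
library(topoholes)

fld   <- make_disk_field(n_holes = 12, radius_mean = 4, radius_sd = 1,
                         min_gap = 15, side = 300, seed = 42)
field <- signed_edt(fld$mask)
diag  <- split_quadrants(compute_persistence(field))
diag[diag$dim == 0 & diag$quadrant == 2, ][1:5, ]
#>   dim     birth     death birth_row birth_col essential quadrant
#> 1   0 -4.123106  8.062258        15       242     FALSE        2
#> 2   0 -5.099020  8.062258       105       109     FALSE        2
#> 3   0 -3.162278  9.219544       120       262     FALSE        2
#> 4   0 -4.123106 15.297059        24       280     FALSE        2
#> 5   0 -4.123106 18.384776       136       243     FALSE        2

round(compute_panel(diag)[, c("H0Q2_n_points", "H0Q2_birth_mean",
                              "H0Q2_death_mean", "H0Q2_entropy",
                              "H0Q2_n_radius_ge")], 3)
#>   H0Q2_n_points H0Q2_birth_mean H0Q2_death_mean H0Q2_entropy H0Q2_n_radius_ge
#> 1            11          -4.658          22.979        2.306               11
```

Twelve holes of mean radius 4.67 px were planted; the diagram shows 11
finite quadrant-2 points (the twelfth, largest hole is the essential class)
with mean birth −4.66 — i.e. a mean recovered hole radius of 4.66 px —
and mean death 22.98, the average half-distance to the nearest hole.
`plot_diagram()`, `plot_scoremap()` and `plot_group_boxes()` draw the
diagnostic figures; `run_pipeline()` composes every stage from greyscale
images (or generated patches) to the test and classifier reports, and
`inst/cli/topoholes.R` exposes the same stages as shell subcommands.

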