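# shellmorph

Three-dimensional valve morphometrics for bivalve shells.

Comparing the shapes of whole regional faunas needs more than linear
measurements: micro-CT surface meshes capture the full form of a valve, but
bivalves offer almost no discrete homologous landmarks to anchor a
comparison. `shellmorph` implements a complete, reproducible pipeline from a
scanned valve surface plus a manually digitized commissure curve to
fauna-level statistics:

- **Non-shape traits.** Shell volume and internal volume by summing signed
  tetrahedra over the mesh, giving the *shell proportion*
  `propSV = TSV / (TSV + TIV)`; body size as centroid size
  `sqrt(sum_i ||p_i - p_bar||^2)` of a 100,000-point strict Poisson-disk
  resampling of the surface; and *ornamentation height*, the exceedance of
  the local shell thickness (nearest-neighbour distance between the exterior
  and interior point clouds) over the modal thickness of a hypothetically
  smooth shell.
- **Internal shell shape.** Each valve is split at the commissure, scaled by
  the centroid size of a 75-point commissure resample, and aligned by a
  rigid fit of the four fixed landmarks (beak, anterior, ventral, posterior
  — the 0/25/50/75% points of the clockwise commissure arc) to a reference
  square. One hundred planes perpendicular to the beak-to-ventral axis each
  contribute 101 "flat-sorted" semilandmarks (sorted by projected distance
  in the commissure plane, so recurved spines and flanges do not scramble
  the ordering), for a grid of exactly 10,100 points per valve. Grids are
  superimposed by generalized Procrustes analysis of the fixed landmarks.
- **Between-fauna statistics.** PCA morphospaces with back-projection of
  arbitrary score vectors into shapes; disparity as the sum of per-axis
  variances; dispersion as the median edge of the Euclidean minimum spanning
  tree; morphospace occupation as the cumulative sum of per-axis score
  ranges; label-reshuffling null models (1000 permutations, percentile 95%
  intervals); pairwise Wilcoxon (Bonferroni-corrected) and
  Kolmogorov–Smirnov tests.
- **Range-shift classification.** Per-trait, per-subgroup changes in minima
  and maxima between two regions (traits scaled, not centered), partitioned
  into nine qualitative fields by one standard deviation of the deltas
  around their mean on each axis.
- **Synthetic valves.** Parametric hemispherical and helicospiral
  (Raup-style) valve generators with analytic or high-resolution reference
  volumes and implantable spines/ribs, plus a two-region fauna simulator, so
  the whole pipeline is testable without scan data.

## Worked example

```r
library(shellmorph)

valve <- make_helicospiral_valve(W = 2, D = 0.25, a = 1, b = 1.2, resolution = 16)
valve
#> synthetic_valve: 4096 faces; truth SV 0.5348, IV 1.5319, propSV 0.2588, ornament 0.000

split <- split_at_commissure(valve$mesh, valve$commissure)
q     <- quarter_landmarks(valve$commissure,
                           reference_point = colMeans(valve$mesh$vertices))
q
#> quarter_landmarks (beak / anterior / ventral / posterior):
#>                 x       y z
#> beak       1.1842 -0.1400 0
#> anterior  -0.1242 -1.2318 0
#> ventral   -0.9910  0.3101 0
#> posterior  0.3156  1.3991 0
#> commissure centroid size (75-point resample): 10.5941

vs <- volume_summary(list(list(whole = valve$mesh, interior = split$interior,
                               cloud = poisson_disk_points(valve$mesh, 5000, seed = 1))),
                     equivalve = TRUE)
vs
#> volume_summary (equivalve): TSV 1.0659, TIV 3.0508, propSV 0.2589, body centroid size 140.2018

aligned <- orient_and_scale_valve(split$interior, q, side = "left")
grid    <- build_semilandmark_grid(aligned)
grid
#> semilandmark_grid: 10100 points (100 sections x 101)
```

The measured `propSV` (0.2589) agrees with the generator's reference value
(0.2588) to 0.05%: the valve is about a quarter shell material by volume.
The equivalve flag doubles the single-valve volumes and centroid size, as
for a specimen whose two valves are mirror images.

Fauna-level comparison on simulated species scores:

```r
fauna <- simulate_fauna(fauna_config(n_species = c(FK = 40L, GM = 20L)), seed = 2)
rep   <- run_disparity(fauna$scores, fauna$traits,
                       config = run_config(n_perm = 1000L, seed = 2))
rep$fauna
#> disparity_summary
#>  observed:
#>  group  n sum_of_variances median_mst_edge cumulative_range
#>     FK 40        1.0959986       0.9405427         17.77058
#>     GM 20        0.9841179       0.9388674         14.93110
#>  nulls: 1000 reshuffles (seed 2)
#>  tests:
#>  groupA groupB wilcoxon_p wilcoxon_p_bonferroni      ks_D      ks_p
#>      FK     GM 0.02986673            0.02986673 0.2105263 0.5441334
```

Here the two simulated regions share one distribution, and the summary reads
accordingly: similar disparity (sum of variances), similar dispersion
(median MST edge), and a larger cumulative range for the richer fauna simply
because 40 species span more than 20.

A thin command-line front end over the same functions lives at
`inst/cli/shellmorph.R` (`simulate`, `traits`, `grid`, `disparity`,
`range-shift`).

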