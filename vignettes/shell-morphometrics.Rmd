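---
title: "Valve morphometrics from surface meshes: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valve morphometrics from surface meshes: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellmorph)
```

`shellmorph` turns a bivalve valve — a triangular surface mesh from a
micro-CT scan, paired with a manually digitized commissure polyline — into
three non-shape traits, a dense semilandmark description of the internal
shell shape, and fauna-level comparative statistics. This vignette explains
the procedures, the conventions we had to fix where the underlying methods
leave choices open, and what the synthetic fixtures do and do not establish
about real scan data.

## Volumes and shell proportion

All volumes are signed-tetrahedra (divergence-theorem) sums over mesh faces
with respect to an apex point. For a closed, consistently outward-wound
surface the sum is apex-independent and equals the enclosed volume;
`cone_volume()` verifies this invariance on closed inputs and warns when an
apex shift changes the result (inconsistent winding).

The shell volume SV of a valve is the volume of its closed surface. The
internal volume IV is the volume "under" the open interior surface bounded
by the commissure. An open surface has no canonical enclosed volume: the
signed sum implicitly caps the boundary with the fan of triangles to the
apex. We place the apex at the **centroid of the interior surface's boundary
loop** (the commissure), so the implicit cap is a near-planar fan across the
commissure opening. The alternative — the apex at the centroid of the
surface itself — systematically undercounts deep valves, because the fan
then cuts a cone out of the bowl: for a hemispherical cap of radius $r$ the
surface-centroid convention converges to $\tfrac{1}{2}\pi r^3$ rather than
the analytic $\tfrac{2}{3}\pi r^3$, a 25% deficit. The boundary-centroid
convention converges to the analytic value, which is how the hemispherical
oracle in the test suite is able to pin `propSV` to
$(R^3 - r^3)/R^3$ within 1% at $\geq 10^4$ faces. `volume_summary()` exposes
`iv_apex = "surface"` for sensitivity analysis.

Equivalve specimens are scanned as one valve and doubled; inequivalve
specimens as two valves and summed — for SV, IV, and body centroid size
alike. The tests verify that processing an equivalve specimen as an
explicit mirror pair through the inequivalve path reproduces the doubled
values exactly. Note that for specimens with a permanent gape the planar
commissure cap overestimates nothing but includes no soft parts outside the
commissure; IV is an underestimate there by construction.

## Surface point clouds

Body size and shell thickness are computed on point clouds of the mesh
surface, 100,000 points per surface by default, placed by strict
Poisson-disk dart throwing: candidate points are drawn area-weighted and
uniformly within triangles, and accepted only if no accepted point lies
within the exclusion radius. The radius starts at 0.75 of the ideal
hexagonal packing spacing $\sqrt{2A/(\sqrt3\,n)}$ and relaxes by a factor
0.9 whenever a round of attempts cannot place the remaining points, so
exactly `n` points are always returned. The sampler runs on R's RNG: a seed
is a required, logged parameter and results are bit-reproducible. Sampled
points lie on the *triangulated* surface — on a curved shell they sit up to
the facet sag ($O(h^2)$ in the edge length $h$) inside the true surface,
which bounds how precisely cloud-based quantities can match analytic ones at
a given mesh resolution; the tests assert exactly that bound rather than an
arbitrary small number.

## Thickness, the smooth-shell baseline, and ornament

Shell thickness is the exact (not approximate) nearest-neighbour distance
from each exterior-cloud point to the interior cloud. The 100,000 distances
are binned into 100 equal-width intervals spanning the observed range; the
mean of the most populated bin is the *modal baseline* — the thickness of
the hypothetically smooth shell. Ties for the modal bin break toward the
thinner bin, consistent with the smooth-shell reading. Ornament heights are
the *signed* differences from this baseline (no flooring at zero), and the
summary reports the absolute maximum alongside the 99th, 98th and 95th
percentiles. The mode is the right location statistic here because spines
are tall but rare: they drag the mean and median upward while leaving the
mode at the unornamented wall thickness — the generators reproduce this
right skew (mode < median < mean) and the tests check it.

On synthetic spined valves the implanted amplitude is recovered within one
histogram bin width across amplitudes from 10% to 100% of the wall
thickness, using 10,000-point clouds. Two resolution conditions make that
work and are worth knowing for real data: the mesh must resolve the spine
(vertex spacing below the spine width) and the cloud spacing must be fine
enough that some sample lands near the spine tip.

## The common frame and its degeneracy

The four fixed landmarks are the points at 0, 25, 50 and 75% of the
clockwise cumulative arc length of the commissure, starting at the point
nearest the beak. "Clockwise" needs an orientation convention: we project
the curve onto its best-fit plane, sign the plane normal toward a reference
point on the convex (outer) side of the valve — by default the valve mesh
centroid — and require negative signed area, flipping the traversal
otherwise. With the reference point derived from the geometry the whole
construction is invariant under rigid motions of the digitized valve, which
the tests verify to $10^{-6}$ through the entire gridding pipeline. For a
**right** valve the convention must be viewed from the other side
(`side = "right"` flips it); otherwise the anterior and posterior labels
swap and a mirror pair would not align onto a common configuration. With
the flip, an aligned right valve of a mirror-symmetric pair coincides with
the aligned left valve exactly.

The valve is scaled by the centroid size of the 75-point commissure
resample and the four landmarks are fitted by a rigid (rotation +
translation, no scaling) least-squares motion to the targets beak (0,0,0),
anterior (1,1,0), ventral (1,0,0), posterior (0,1,0); right valves are then
mirrored across the XY plane. Scaling is excluded from the fit because size
was already divided out; the target square cannot be hit exactly anyway
(real quarter configurations are not unit squares), so the fit residual is
reported, not minimized to zero.

One genuine subtlety surfaced during implementation: the fixed
correspondence maps the *cyclic* order beak–anterior–ventral–posterior onto
target corners in a crossed (non-cyclic) way. If the quarters possess two
perpendicular mirror axes — a perfect circle or ellipse — the rigid-fit
cross-covariance drops to rank one and the roll of the aligned frame is
arbitrary. Real commissures are asymmetric, so the scheme works in
practice; `orient_and_scale_valve()` warns when it detects the degeneracy,
and the helicospiral generator carries a small aperture asymmetry
(`asym = 0.1`) by default so shape fixtures are generic. The symmetric
hemispherical valve is kept as the volume oracle only.

## Sectioning and flat-sorting

The sampling axis runs from the beak landmark to the ventral landmark, with
sampling planes perpendicular to it at 1%, 2%, …, 100% of its length. Each
plane is intersected with the mesh edges; when a plane cuts the valve in
more than one closed curve (strongly recurved shells), only the loop
containing the anteriormost point is kept, matching the single-curve
assumption of the ordering step. Candidates are *selected*, not
interpolated: each chosen point is an existing intersection point whose
original Z coordinate is restored after the planar sort. When a section
yields fewer than twice the requested 101 points, the face segments are
densified by midpoint refinement (midpoints of plane–face segments lie on
both the plane and the surface), which bounds duplicate selections.

Ordering within a section is the *flat sort*: zero the Z coordinate,
take the candidate furthest along the anterior direction (toward the
(1,1,0) corner) as reference, and sort by increasing projected distance to
it. The projected distances are then monotone by construction, whereas a
sort on 3D distances inverts neighbours across overhanging flanges and
recurved spines; the tests construct such a flange and check both
behaviours against a brute-force oracle. Subsampling picks the candidates
nearest to 0%, 1%, …, 100% of the maximum projected distance.

The 100% plane passes through the ventral landmark and usually degenerates
to at most a couple of points; the policy is to pad with repeated points
(the ventral point itself when the section is empty) and flag the section,
so every grid has exactly $100 \times 101 = 10{,}100$ points. An empty
*interior* section is an error naming the section percentage — it means the
frame or the split is wrong.

## Procrustes superimposition and the morphospace

Specimens are superimposed by generalized Procrustes analysis **of the four
fixed landmarks** (translation, rotation, scaling; iterated to a consensus
change below $10^{-10}$), and each specimen's full grid is carried along by
its fitted similarity transform. Because the commissure centroid size was
already divided out, the GPA scaling step re-scales by the centroid size of
the four landmarks alone; the two scalings are not redundant (they
normalize different point sets) and `do_scale = FALSE` is available to
examine the interaction. Alignment is invariant to similarity transforms of
any input specimen to $10^{-8}$ and re-running it on its own output is a
fixed point.

The morphospace is a centered (never variance-scaled) PCA of the flattened
grids. The default retains 23 axes, with two alternative policies: a 95%
cumulative explained-variance threshold, and stabilization of the
per-specimen reconstruction RMSE (the rank-$k$ reconstruction error, which
is nonincreasing in $k$ and zero at full rank). Back-projection —
mean shape plus rotation times a zero-padded score vector — renders any
morphospace position as a shape; a specimen's own scores reproduce its grid
to machine precision.

## Disparity, dispersion, occupation, and nulls

Per group: the sum of per-axis sample variances (disparity; $n-1$
denominator, the standard choice, material only for tiny groups), the
median edge length of the Euclidean minimum spanning tree (dispersion — low
"stacking" of similar morphologies appears as large MST edges), and the
cumulative sum of per-axis score ranges (occupation; convex hulls are
intractable beyond ~10 dimensions). The MST uses exact distances and
deterministic lexicographic tie-breaking, and is tested against exhaustive
spanning-tree enumeration up to $n = 7$ and against an independent library
implementation. Cumulative range is axis-dependent by design (it lives in
the PCA basis); sum of variances and MST statistics are rotation-invariant,
and the tests pin both facts.

Null models reshuffle the group labels (preserving sizes), recompute the
statistic per group 1000 times, and report the permutation mean with a
percentile 95% interval — percentile rather than normal-approximation,
because the statistics (medians, ranges) can be visibly non-Gaussian at
realistic group sizes. Group differences are tested by Wilcoxon rank-sum on
per-specimen squared deviations from the own-group centroid (the
per-observation disparity contribution; plain distances are a switch), with
Bonferroni correction across the comparisons in a run, and by two-sample
Kolmogorov–Smirnov on the groups' MST edge-length distributions. Only
subgroups with more than two species in both regions enter comparisons;
exclusions are listed in the reports.

## Range-shift fields

For each trait (scaled by its standard deviation, not centered, so deltas
are in SD units and sign information survives), each eligible subgroup
contributes the change in minimum and in maximum between the focal and
reference regions. The (Δmin, Δmax) plane is cut into nine fields at one
standard deviation of the subgroup deltas around their mean per axis;
values within one standard deviation (boundaries inclusive) count as "no
interpretable change" on that axis. The whole-fauna point is classified but
excluded from the threshold statistics — it is a reference marker, not a
subgroup — and thresholds are computed per trait and per subgroup kind
(families and functional groups are separate panels); both choices are
switchable. Swapping the two regions negates all deltas and reflects the
fields through the center, and a common affine rescaling of the raw trait
is absorbed by the scaling step; both are property-tested.

## Synthetic data: what it emulates, what it does not

The hemispherical valve (shell between concentric hemispheres, closed by an
equatorial annulus, commissure along the inner rim) has exact analytic
volumes and exists to oracle the volume path. The helicospiral valve sweeps
a generating ellipse with whorl expansion `W`, apex translation `D`,
elongation `b/a` and a radial-offset inner surface; its reference volumes
come from a ~10× finer mesh of the same parametrization, since no closed
form exists. Implanted ornament displaces exterior vertices radially with a
Gaussian-spine or sinusoidal-rib field normalized so the maximum
displacement equals the requested amplitude at a mesh vertex, tapering to
zero at the rim.

The fauna simulator draws species scores from region-wise multivariate
normals over a decaying variance spectrum (first two axes roughly a third
and a fifth of the variance, 23 axes), lognormal centroid sizes, gamma
ornament with an optional clade-linked lognormal heavy upper tail, and
logit-normal shell proportion centered near 0.28 (most species between 20
and 40%, overall range roughly 6–80%). Default fauna sizes are 355 and 90
species for the tropical and boreal pools. The heavy ornament tail is
carried by designated families rather than spread fauna-wide, reflecting
the concentration of strong defensive ornament in particular cemented
epifaunal clades; this is also what makes the whole-fauna range-shift point
separate cleanly from the family-level threshold band.

What passing tests show: the geometry, ordering, superimposition and
statistics are correct on meshes with known truth, and the statistical
machinery is calibrated (on exchangeable simulated faunas the observed
between-region disparity difference falls inside the 95% reshuffling
interval in ≥90% of 200 runs) and sensitive (doubled within-region score
variance is detected as a larger median MST edge in effectively every run;
a clade-linked heavy ornament tail lands the fauna in the
greater-focal-maximum / bounded-minimum field as the modal outcome across
replicates). What they cannot show: robustness to scan artifacts that the
generators do not model — borings, epibionts, broken margins, digitization
jitter beyond the snap tolerance of twice the median edge length, or
commissures digitized off-surface — nor the biological question of whether
hundreds of real valves separate by region.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately reduced sizes
chosen to exercise every code path at full fidelity: valve meshes of a few
thousand faces, clouds of $10^3$–$10^4$ points, faunas of 25–55 species for
permutation work (with 1000 reshuffles throughout), and 200 replicate
faunas for the calibration study; the full-size defaults (100,000-point
clouds, 355 + 90 species) remain the package defaults. Other fixed
numerical choices: faces with area below $10^{-12}$ mm² are dropped at
load; component ties in debris removal break toward the lowest minimum
vertex index; the commissure snap tolerance is twice the median edge
length; GPA converges at $10^{-10}$; plane sections nudge the plane by
$10^{-9}$ of the coordinate scale when a vertex lies exactly on it, keeping
the edge-crossing construction simple and deterministic.
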