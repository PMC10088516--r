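---
title: "Quantitative cerebrovascular morphometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative cerebrovascular morphometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvmorph)
```

## The measurement problem

Bright-blood time-of-flight MR angiography renders flowing blood as the
high-intensity compartment of a 3D volume, so the *lumen* of intracranial
arteries can be delineated without contrast. cvmorph turns such a volume
into per-point morphological measurements along vessel centerlines and into
longitudinal comparisons between two imaging timepoints. The chain is

1. **Lumen segmentation** — threshold-connected region growing from
   user-placed seeds;
2. **Surface extraction** — a watertight triangle mesh of the lumen;
3. **Centerline computation** — one curve per branch, with the maximal
   inscribed sphere radius (misr) at every point;
4. **Resampling** at a fixed 0.284 mm pitch and computation of nine
   per-point features: luminal area, misr, minimal and maximal diameter,
   their ratio, curvature, torsion, perimeter, and circularity;
5. **Territory aggregation** — points are allocated to named arterial
   branches (74 in the shipped atlas) grouped into 19 chunks, and chunk
   means are formed;
6. **Longitudinal statistics** — percent changes between baseline and
   follow-up, paired Wilcoxon signed-rank tests, and covariate regression.

Because no clinical volumes ship with the package, every stage is validated
against parametric tube phantoms with analytic ground truth.

## The phantom generator and what it does (not) emulate

`tube_spec()` + `make_tube_phantom()` build volumes containing a cylinder,
a torus arc, a circular helix, or a Y bifurcation. The analytic centerline
gives exact references: a torus arc of bend radius $R$ has curvature $1/R$
and zero torsion; the helix $(a\cos t, a\sin t, b t)$ has curvature
$a/(a^2+b^2)$ and torsion $b/(a^2+b^2)$; circular cross-sections have
circularity $4\pi A/P^2 = 1$ and minimal = maximal diameter $= 2r$.

Rasterisation is a voxel-centre membership test without anti-aliasing, so
the voxel-count volume is an exact oracle up to surface voxels and
converges to $\pi r^2 L$ as the spacing shrinks. Three numerical choices
matter here:

* **Spacing default 0.284 mm isotropic** — the target angiographic
  resolution of the intended acquisitions.
* **Anti-resonance placement.** The auto-fitted grid offsets its origin by
  half a voxel so that analytic symmetry axes fall mid-cell. If a cylinder
  axis sits exactly on a voxel-centre line, the cross-section voxel count
  hits the Gauss-circle lattice resonance (≈ −4% at $r \approx 7$ voxels);
  mid-cell placement restores the generic sub-1% behaviour. Real vessels
  are never lattice-aligned, so the generic case is the representative one.
* **Flat ends.** Distance-to-polyline rasterisation would add spherical
  caps at branch ends; these are clipped back to the end planes (within the
  cap ball only, so coiled tubes are unaffected) to keep the analytic
  volume oracle exact. Bifurcation daughters keep their start caps, which
  fill the wedge at the junction.

Acquisition noise is Rician — the magnitude-MR model,
$\sqrt{(v+\sigma X)^2 + (\sigma Y)^2}$ with standard normal $X, Y$ — with
an explicit seed everywhere. The generator does **not** emulate flow
saturation, pulsation artefacts, intensity inhomogeneity, vessel
tapering, wall signal, or neighbouring bright tissue. Passing the phantom
suite therefore demonstrates the geometric correctness of the measurement
chain at this resolution, not robustness to every clinical confounder;
thresholds and seeds still need per-study review on real data.

## Segmentation

Region growing collects voxels with intensity in `[lower, upper]` that are
26-connected to a seed; 26-connectivity is used throughout because thin
oblique vessels disconnect under 6-connectivity. The documented default for
the lower threshold is `mean + 2·SD` of a user-marked background box
(`suggest_lower_threshold()`); the upper threshold defaults to infinity.
Seeds are always user-supplied. Noise islands are removed by
`largest_connected_component()` (ties broken toward the lexicographically
smallest voxel). On noiseless phantoms the grown mask equals the
membership oracle voxel-for-voxel; at Rician noise of 5% of the foreground
intensity the Dice overlap stays above 0.95 for radii of five voxels and
up.

## Surface extraction

The mesh is the 0.5-level iso-surface of the binary mask, extracted on the
six-tetrahedra Kuhn decomposition of the voxel lattice. This decomposition
is translation-consistent, which makes the surface closed and consistently
oriented by construction (every edge borders exactly two triangles — the
watertightness the tests assert). Two refinements control accuracy:

* **Gaussian pre-smoothing of the indicator, σ = 0.9 voxel (default).**
  A raw binary iso-surface carries an angular caliber ripple of a few
  percent at $r \approx 7$ voxels (staircase corners along the ±45°
  directions). Smoothing suppresses the ripple but shrinks curved surfaces
  by approximately $\sigma^2/(2r)$. σ = 0.9 voxel is the balance point on
  noiseless phantoms: cylinder circularity recovers to ≥ 0.98 while the
  area bias at a 4-voxel radius stays within the 5% validation band. Both
  ends of the tradeoff degrade outside roughly 0.85–0.95 voxel.
* **Trilinear bisection of crossing vertices**, so vertices lie on the
  true trilinear iso-surface rather than the linearly interpolated one
  (the difference matters on cell-diagonal edges).

Taubin smoothing (λ = 0.5, μ = −0.53, 20 iterations) then relaxes residual
staircase without the volume shrinkage of plain Laplacian smoothing; on a
voxelized sphere 20 iterations change the enclosed volume by under 2%
while monotonically reducing area. Masks touching the grid boundary are
padded with background by default (`pad = FALSE` turns this into an
error), since an unpadded boundary mask cannot produce a closed surface.

A deliberate consequence of the iso-surface contract: a single isolated
voxel is rejected (no fully interior voxel). Any midpoint-style iso-surface
of one voxel encloses $h^3/6$, not $h^3$, so "surface of a lone voxel" is
not a meaningful lumen measurement.

### The resolution limit worth knowing about

Binary voxelisation at $r \approx 7$ voxels carries an irreducible angular
caliber ripple of about ±2.5% that no smoothing can remove without also
removing genuine millimetre-scale shape (for example a stenosis). The
minimal Feret diameter sits in the dips (≈ −4.5% for an axis-aligned
cylinder) and the maximal Feret on the bumps (≈ +2%). Radius-type
quantities derived from the inscribed sphere (misr) or from the area are
much less affected (&lt; 1–2%). This is why validation checks each caliper
quantity against the true diameter (all within 5%) rather than demanding
that min- and max-Feret agree with each other to better than the ripple
permits.

## Centerlines and the maximal inscribed sphere radius

The centerline is the minimal-cost path through the 26-connected
foreground voxel graph with edge cost $\ell / d^4$, where $\ell$ is the
physical step length and $d$ the Euclidean distance transform (EDT)
averaged over the edge's endpoints. The quartic penalty is required: with
$\ell/d^2$ the path still corner-cuts a bend of radius 10 mm by almost a
millimetre, because the length saved outruns the quadratic penalty.
Endpoints are user-supplied world-mm pairs; paths sharing a source are
merged into a branch tree at their divergence points.

Voxel paths are then recentered: each point moves to the centroid of the
lumen in the plane perpendicular to the local tangent (three sweeps;
window radius twice the local EDT so an off-centre start still sees the
whole cross-section). Tangents come from a ±3-point stencil — voxel paths
zig-zag on oblique runs, and nearest-neighbour tangents flip direction
step to step — and two light Laplacian passes remove the residual
transverse sawtooth. On phantoms this lands the centerline within
0.1 voxel (cylinder) to 0.5 voxel (helix) of the analytic curve.

misr is computed *exactly* as the minimal distance from the point to any
background voxel centre (a local box search). The obvious alternative —
trilinear interpolation of the EDT — is biased ≈ −9% on the medial axis,
because the EDT is a cone there and interpolation clips the apex. No
half-voxel correction is applied: along a tube many background centres
graze the lumen surface, so the minimum itself is already a tight estimate
(cylinder: 2.013 mm recovered for a true 2.0 mm).

Resampling fits a natural cubic spline per coordinate against arclength
and produces $n = \mathrm{round}(L/\mathrm{pitch}) + 1$ exactly uniform
stations with both endpoints preserved. Exact endpoint preservation and a
spacing of exactly 0.284 mm are mutually exclusive unless $L$ is a
multiple of the pitch; uniformity plus endpoint exactness was chosen, with
the realised spacing within 0.5% of nominal. Branches shorter than two
pitches are dropped with a warning.

## Frenet curvature and torsion

Curvature $\kappa = |r' \times r''|/|r'|^3$ and torsion
$\tau = ((r' \times r'') \cdot r''')/|r' \times r''|^2$ are evaluated from
moving local polynomial fits of the resampled points against arclength.
Raw finite differences on voxel-snapped points are noise-dominated; local
polynomial differentiation is the standard remedy. Two defaults matter:

* **Degree 5.** Torsion needs the third derivative; an even degree
  truncates the expansion asymmetrically and biases helix torsion by about
  −3%, while degree 5 recovers the analytic helix to 0.01%.
* **Half-window 4 mm** (≈ 28 points at the default pitch). Chosen so that
  a noiseless circle of radius 10 mm recovers $1/R$ to well within 1%
  while pipeline-extracted helix torsion stays within ≈ 2% of
  $b/(a^2+b^2)$. Narrower windows let centerline jitter through to the
  third derivative; wider ones start to flatten genuine curvature.

Endpoints use the same machinery with clipped (one-sided) windows. Where
$|r' \times r''|$ falls below tolerance the point is flagged straight and
torsion is reported as 0 — torsion is geometrically undefined on straight
segments. For a planar curve the estimated mean torsion is validated to
stay below 0.02 /mm, an order of magnitude under the helix's true
0.069 /mm, rather than against a meaningless relative tolerance on zero.

## Cross-sections and the nine features

At each station the mesh is cut by the plane normal to the local tangent;
of the resulting closed polylines, the one enclosing the station is the
lumen contour, ordered counterclockwise. Area is the shoelace sum,
perimeter the edge-length sum, minimal/maximal diameter the min/max Feret
(caliper) widths of the contour's convex hull — rotationally stable, and
the convention matching manual caliper measurements — and circularity the
isoperimetric ratio $4\pi A/P^2 \le 1$. Stations whose contour extraction
fails (typically at a bifurcation apex, where no loop encloses the point)
are recorded as missing rather than dropped; a branch with more than 20%
failures raises a quality error instead of silently degrading.

## Territories, chunks and exclusions

The published description of the territory scheme names the 19 chunks but
not the 74-branch list or the branch-to-chunk mapping. The shipped atlas
(`inst/extdata/arterial_atlas.csv`) is therefore an editable
reconstruction: the 17 chunk names visible in the study's figures
(basilar; left/right ICA; basal and pial ACA/MCA/PCA per side; left/right
cerebellar) plus the left/right vertebral arteries to reach 19, populated
with 74 branches of standard Circle-of-Willis nomenclature. Validation
uses phantom mini-atlases, not this anatomy.

Branch labelling is semi-automatic: one user seed per anatomical branch,
propagated to every centerline point by geodesic distance along the
centerline tree (ties to the lower branch id). Chunk summaries are
unweighted means over member *points* (not branch means) — the natural
reading of averaging a bundle of fine segments — over non-missing,
non-excluded points; the symptomatic segment is excluded by branch id.
Chunks left empty are reported with missing means rather than dropped.

## Longitudinal statistics

Percent change follows the study convention
$(\mathrm{initial} - \mathrm{followup})/\mathrm{initial} \times 100$,
which is *negative* for an increase; because increases are conventionally
reported as positive percentages, both columns are emitted explicitly
(`pct_decrease`, `pct_increase`) and never silently mixed.

The paired comparison is the Wilcoxon signed-rank test: zero differences
dropped (the classic convention; Pratt's variant changes p and is not
used), ties mid-ranked. For $n \le 25$ the exact null distribution is
computed by convolution over the doubled mid-ranks — exact even under
ties — and beyond that a normal approximation with tie and continuity
corrections is used. The implementation is validated against brute-force
enumeration of all $2^n$ sign assignments and, on untied data, against
`stats::wilcox.test`.

Covariate models are ordinary least squares with intercept and
t-distribution 95% CIs, in both univariable and multivariable modes;
rank-deficient designs are rejected naming the collinear columns, and
complete cases are used per model with the n reported. `build_change_table`
assembles the chunk × feature table of mean percent changes, Wilcoxon p
values and per-covariate coefficients; a Benjamini–Hochberg column is
emitted for orientation but significance statements follow raw p < 0.05,
matching the study's analysis. No multiplicity gate is applied.

## Validation scale and design

The phantom suite runs at the study resolution (0.284 mm): a 2 mm × 40 mm
cylinder, a torus arc ($R = 10$, $r = 2$), and a 1.5-turn helix ($a = 5$,
$b = 2$, $r = 1.2$). End-to-end longitudinal recovery uses 30 simulated
subjects, each a cylinder phantom (radius ≈ 1.6 ± 0.15 mm, 12 mm long,
mild Rician noise) imaged at two "timepoints" with a +6% diameter
inflation at follow-up, pushed through the full image pipeline at both
timepoints; the injected change is recovered within one percentage point
with p well below 0.05. The type-I error of the comparison machinery is
estimated on 100 null chunk-level cohorts (no injected change) and sits at
the nominal 5%; the null replicates are simulated at the chunk-summary
level, where the statistical property lives. These sizes keep the whole
validation suite in the minutes range on a single CPU while leaving every
tolerance dominated by method error, not sampling error.

## Known limitations

* Caliper (Feret) diameters inherit the ±2.5% voxelisation ripple
  described above; at 0.284 mm this is the honest noise floor for
  millimetre-calibre vessels, and min-Feret is biased low by up to ≈ 5%.
* Sub-resolution tubes (radius below ~1.5 voxels) are flagged with a
  warning; measurements there are not meaningful.
* Bifurcation apices yield missing contours by design; the junction
  neighbourhood contributes misr and Frenet values but no area/perimeter.
* The atlas ships as a plausible reconstruction, not a validated
  anatomical standard; users with their own nomenclature should edit the
  CSV.
* Torsion on near-straight segments is reported as 0 with a flag, so mean
  torsion over nearly straight chunks underestimates any true small twist.
* The regression machinery reproduces the *operations* of the clinical
  analysis; clinical coefficient values require the original patient data
  and are out of scope.
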