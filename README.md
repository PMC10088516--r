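# cvmorph — quantitative cerebrovascular morphometry

cvmorph measures intracranial artery morphology from 3D bright-blood
angiographic volumes (time-of-flight MRA) and compares two imaging
timepoints. It is aimed at stroke and neurovascular imaging researchers who
need reproducible, per-segment luminal measurements — e.g. to quantify how
arterial caliber responds to therapy — without manual caliper reads.

From a NIfTI volume the pipeline extracts the vascular lumen by
threshold-connected region growing, builds a watertight triangle surface of
the lumen, traces branch centerlines through the foreground voxel graph
(minimal cost `length / EDT^4`, which rides the ridge of the Euclidean
distance transform), resamples them at a 0.284 mm pitch, and computes nine
features at every centerline point:

| feature | definition |
|---|---|
| luminal area `A` | shoelace area of the cross-section contour |
| misr | maximal inscribed sphere radius (exact distance to background) |
| min / max diameter | min / max Feret (caliper) width of the contour hull |
| min–max ratio | min / max diameter |
| curvature κ | `|r' × r''| / |r'|^3` from local polynomial fits |
| torsion τ | `((r' × r'') · r''') / |r' × r''|^2` |
| perimeter `P` | contour edge-length sum |
| circularity | isoperimetric ratio `4πA / P²` (1 for a circle) |

Points are allocated to named arterial branches (a shipped, editable
74-branch atlas grouped into 19 territory chunks), chunk means are formed,
and two timepoints are compared with the percent-change convention
`(initial − followup) / initial × 100` (negative for an increase; a
positive-increase column is emitted alongside), paired Wilcoxon signed-rank
tests (exact for n ≤ 25, ties mid-ranked, zeros dropped) and OLS covariate
regression with 95% CIs.

A parametric phantom generator (cylinder, torus arc, helix, bifurcation)
with analytic centerline, radius, curvature and torsion makes every stage
verifiable without clinical data; see the methods vignette
(`vignettes/cvmorph-methods.Rmd`) for the models, defaults and known
resolution limits.

## Worked example

Measure a synthetic vessel of known size — a 2 mm radius, 40 mm cylinder at
the 0.284 mm study resolution — end to end:

```r
library(cvmorph)

spec <- tube_spec("cylinder", radius_mm = 2, length_mm = 40)
ph   <- make_tube_phantom(spec, spacing_mm = 0.284)

mask <- largest_connected_component(
  region_grow(ph$volume, seeds = c(12, 12, 83), lower = 50))
mesh <- extract_surface(mask)
cl   <- resample_centerline(
  compute_centerline(mask, rbind(c(0, 0, 4), c(0, 0, 36))))
feats <- point_features(mesh, cl)
round(colMeans(feats[, c("area_mm2", "misr_mm", "min_diameter_mm",
                         "max_diameter_mm", "circularity")]), 3)
```

```
       area_mm2         misr_mm min_diameter_mm max_diameter_mm     circularity
         12.378           2.017           3.816           4.082           0.982
```

The true values are area `π·2² = 12.566 mm²`, misr `2.0 mm`, diameters
`4.0 mm`, circularity `1.0`: area and inscribed-sphere radius are recovered
within ~1.5%, caliper diameters within the ±2–5% voxelisation ripple that
is the honest noise floor at this resolution (see the vignette).

The longitudinal arithmetic and statistics work on plain numbers and
tables:

```r
abs(percent_change(186.5, 121.3))   # cohort cholesterol 186.5 -> 121.3 mg/dL
#> 35.0                             # printed as 35.0% reduction
percent_increase(2.66, 2.92)        # basilar diameter 2.66 -> 2.92 mm
#> 9.8                              # ~9.7% increase
paired_wilcoxon(c(5.1, 4.8, 5.6, 5.0, 5.3, 4.9, 5.2),
                c(5.5, 5.0, 5.9, 5.4, 5.6, 5.2, 5.3))
#> V = 28, p = 0.01562 (n = 7; exact signed-rank (convolution over mid-ranks))
```

`run_pipeline(pipeline_config(...))` chains all stages on one volume and
writes `mask.nii.gz`, `surface.vtk`, `centerline.vtk/.csv`, `features.csv`
and `chunks.csv`, each stamped with the package version and the resolved
configuration so identical reruns are byte-identical. A thin command-line
interface over the same functions lives at `inst/cli/cvmorph.R`
(subcommands `phantom`, `segment`, `surface`, `centerline`, `features`,
`label`, `summarize`, `compare`, `run`).

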