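---
title: "Delineating trees and measuring canopies from UAV orthomosaic + DSM pairs"
author: "canopyOBIA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating trees and measuring canopies from UAV orthomosaic + DSM pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyOBIA)
```

## The problem and the data model

Photogrammetric processing of overlapping UAV photographs yields two
co-registered rasters: an orthomosaic (RGB from a visible-light camera, or
a multi-band stack with a near-infrared channel from a multispectral
camera) and a digital surface model (DSM) whose elevations include the
canopy tops. `canopyOBIA` consumes this pair — as two files or as one
combined multi-layer file with the DSM as an extra band — and returns one
record per tree or tree-row: position, canopy axes, projected area, apex
height and pixel-integrated crown volume.

A `SceneStack` holds the named band matrices, the DSM (metres), an
axis-aligned affine georeference in a planar metric CRS and a union nodata
mask. Geographic (degree-unit) CRSs are refused outright: every downstream
quantity is metric. Orthomosaic and DSM must agree to within half a pixel;
nothing is silently resampled, misregistration is an error. The ground
sample distance follows from the flight geometry as
`GSD = pixel pitch (mm) x altitude (m) / focal length (mm)`. Some camera
spec sheets round the pixel pitch; when a sensor width and pixel count are
available, their ratio is the more faithful pitch (a 17.3 mm / 4032 px
sensor at 14 mm focal length and 50 m altitude gives 1.53 cm, whereas the
commonly quoted rounded pitch of 0.0043 mm would give 1.54 cm).

## Segmentation

The scene is partitioned by bottom-up pairwise region merging from
single-pixel seeds. Merging regions 1 and 2 into m is charged

```
f = w_color * sum_l w_l * (n_m sd_m - n_1 sd_1 - n_2 sd_2)
  + w_shape * [ w_smooth * (n_m s_m - n_1 s_1 - n_2 s_2)
              + w_cmpct  * (p_m sqrt(n_m) - p_1 sqrt(n_1) - p_2 sqrt(n_2)) ]
```

with `sd` the population standard deviation per weighted layer, `p` the
perimeter in pixel edges, and `s = p / bounding-box perimeter` the
smoothness deviation. Merges are accepted while `f < scale^2`. Candidates
are selected by local mutual best fitting — an object merges only with its
cheapest neighbour and only when the choice is reciprocal — scanning in
ascending object id with ties broken towards the smaller id, which makes
the result fully deterministic. The merge neighbourhood is 4-connected to
avoid diagonal leakage between adjacent crowns.

Defaults: colour/shape 0.6/0.4, smoothness 0.5 and compactness 0.05. The
last two are used exactly as stated, not renormalised to sum to one: they
act as relative weights inside the shape term, and we deliberately do not
second-guess the convention. Layer weights default to DSM = 1 together
with Green = 1 (visible) or NIR = 1 (multispectral), everything else 0 —
the layers in which crowns are most prominent. A layer with weight zero
provably never influences the labels (a property the test suite exercises
by injecting noise into zero-weight layers).

The scale parameter is expressed in weighted-layer units; since bands are
8-bit digital numbers, the default of 20 suits orchard scenes around 2-4 cm
GSD, where it leaves crowns as a handful of objects and soil as large
regions. It is deliberately exposed in the configuration: coarser scenes
or low-contrast sensors warrant smaller scales. Per-layer standard
deviations use population (n) normalisation, matching the additive form of
the heterogeneity term.

## Classification and heights

Vegetation is isolated from bare soil on object means of a vegetation
index: Excess Green (`2g - r - b` on chromatic coordinates, which makes
the index invariant to positive band rescaling, so DN versus calibrated
reflectance is immaterial) for RGB sensors, NDVI where a NIR band exists.
The threshold is Otsu's, adapted to the object framework: a 256-bin
histogram of object mean indices, each object weighted by its pixel count,
maximising between-class variance; the returned value is the upper edge of
the winning bin. Pixels whose index denominator vanishes become nodata
rather than zero — dropouts should not fabricate index values. A scene
with a single spectral class (all soil) has no threshold; that condition
is surfaced as a degenerate-distribution error, not guessed around.

Object heights come from the DSM relative to a *local* bare-soil baseline:
the median elevation of bare-soil pixels within a ring of `ring_px`
(default 5) pixels around each vegetation object. The median resists stray
vegetation in the ring; the locality cancels terrain slope — on a 10 %
plane the apex height moves by less than `ring_px * gsd * slope`. An empty
ring is widened to 2x then 4x; objects buried deep inside a large canopy
(whose widened ring still finds no soil) inherit the baseline of their
whole connected vegetation region, whose ring does reach the surrounding
soil. Only objects that still lack a baseline after that fallback are
flagged and conservatively relabelled herbaceous. Pixel heights are
clamped at zero — a vegetation pixel below its baseline is measurement
noise, not negative canopy — and the object height is the maximum pixel
height, i.e. the crown apex; a p99 option exists for noisy surface models.
All heights are invariant to adding a constant to the DSM.

Vegetation lower than `min_tree_height` (default 0.5 m, configurable)
is relabelled herbaceous. The cut is a fixed height rather than a second
automatic threshold: grass and cover crops in tree plantations sit well
below half a metre while the shortest crowns worth inventorying do not.

## Entities and features

Tree-class objects are merged into entities by 8-connected components of
their pixels — diagonal crown pixels belong together, and within-row
touching crowns correctly fuse into one entity per row. (Segmentation used
4-connectivity; the two serve different purposes.) The merged level sits
above the base segmentation as a strict refinement hierarchy: every base
object lies wholly inside one upper object, and both levels partition the
valid pixels exactly.

Per entity: projected area is `n_px * gsd^2`; height the maximum pixel
height; volume the sum of `pixel height * gsd^2` over its pixels —
integrating the real crown surface above the local soil baseline rather
than fitting a solid. Canopy length/width axes are the side lengths of the
minimum-area oriented bounding rectangle of the footprint (computed by
rotating calipers over the convex hull of the pixel outlines; length >=
width by convention), with best-fit-ellipse axes as an option. For
tree-rows the entity height is the row maximum; a row-mean is a one-line
change via the per-object heights if preferred. Entities below
`min_entity_area` (default 0.1 m^2) are dropped as noise — a real crown at
these GSDs covers thousands of pixels, and a handful of pixels is below
any sensible detectability limit. Volume is exactly additive under
arbitrary splits of an entity's pixels, and `volume <= area * height`
always.

Results export as GeoJSON (one feature per entity, footprint traced by
marching squares, attributes carried on the feature) plus a CSV in the
per-tree schema, and a field-level summary (tree count, height/volume
moments, mean nearest-neighbour spacing).

## Validation statistics

`overallAccuracy` is the percentage of valid pixels whose predicted
tree/non-tree class matches a reference delineation — agreement over the
full scene, which is symmetric in the two masks; per-class rates can be
derived from the masks directly if needed. `averageFeatureError` is the
mean absolute paired difference, reported with its sample standard
deviation both in feature units and as a percentage of the observed mean
(the deviation's natural scale is ambiguous in common field reports, so
both are given). `regressionFit` is OLS of estimated on observed with the
fit's R^2 and residual RMSE. `ellipsoidVolume` implements the classical
field formula `pi/6 ((L+W)/2)^2 H` used to turn manual tape measurements
into volumes; pixel-integrated volumes legitimately differ from it for
irregular crowns, so regressions of one on the other measure agreement of
magnitude, not error.

## The synthetic orchard generator

No public orthomosaic/DSM pair accompanies this problem domain at the
needed resolutions, so the package carries a first-class scene generator
with analytic truth. It emulates: planar-to-gently-sloping terrain with a
smooth sinusoidal undulation; half-ellipsoid crowns
(`DSM = terrain + h * sqrt(1 - (dx/rx)^2 - (dy/ry)^2)`) on single-tree
grids or rows, giving closed-form truth `area = pi rx ry` and
`volume = (2/3) pi rx ry h` — the very quantities the pipeline estimates;
optional random crown gaps; low grass patches (<= 0.3 m) with intermediate
vegetation-like spectra; and a two-class (+grass) per-band mean model with
additive Gaussian sensor noise quantised to 8-bit DN. Defaults: 2 % slope,
0.15 m undulation over 40 m, crown semi-axes 1.5-2.5 m, heights 2-4 m,
5 % grass cover, noise sigma 5 DN — plausible values for a mature olive
plantation. Presets mirror four field layouts: single trees at 7 x 7 m
(visible, 1.53 cm GSD) and 8 x 8 m (multispectral, 2.71 cm), rows at
3.75 x 1.3 m and 8 x 4 m. Generation is bit-identical under a fixed seed
and leaves the caller's RNG state untouched.

What the generator does *not* emulate — and therefore what green tests do
not certify about field data: photogrammetric reconstruction failure
(blurry DSM regions over low-contrast crowns, a real failure mode of
structure-from-motion on visible imagery), shadows, radiative transfer,
within-crown spectral texture, or co-registration error between ortho and
DSM. On these synthetic scenes the spectral and height contrasts are
clean, so near-perfect classification accuracies are expected and mainly
certify the machinery (segmentation boundaries, thresholding, baselines,
bookkeeping), not field performance.

## Numerical choices and problem sizes

Rasters are stored as TIFF planes (one directory per layer) with an ESRI
world file and a JSON sidecar recording CRS, layer names and per-layer
scaling; float layers are encoded as 32-bit scaled samples, keeping
round-trip error below 1e-6 for any realistic elevation range, and 8-bit
bands round-trip exactly. Otsu uses 256 bins over the observed range.
Transform agreement is enforced at half a pixel. The segmentation core is
C++ (union-find with sorted aggregated edge lists); a 10-million-pixel
scene segments in about half a minute on one CPU.

The test suite runs reduced planting grids (2 x 2 to 3 x 3 trees) of the
standard presets so the whole suite stays in the tens of seconds; the
acceptance script runs the full-size presets (five 100-tree multispectral
scenes at 2.71 cm GSD, three visible scenes at 1.53 cm with the preset's
5 x 5 grid). These sizes are the package's chosen study conditions, stated
here so results are reproducible.

## Known limitations

eCognition-style commercial segmenters will draw different object
boundaries; the package reproduces the algorithmic idea, not a specific
implementation's output. Tree-row plantations report row-level entities;
individual trees inside a row are only separable through the per-tree
apex-height reader used in validation. The herbaceous cut is global and
height-based; sparse tall weeds would pass it. And segmentation scale has
no auto-tuning — scenes far from the 2-4 cm GSD regime need an adjusted
scale parameter.
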