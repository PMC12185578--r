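---
title: "Quantifying Langerhans-cell depth in the epidermis: methods and design notes"
author: "skinDepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Langerhans-cell depth in the epidermis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinDepth)
```

## The measurement problem

Langerhans cells (LCs) are the resident antigen-presenting cells of the
epidermis. When skin is exposed to a sensitizer, activated LCs migrate
downward, toward the basal lamina and eventually into the dermis - a key
event of the skin-sensitization adverse outcome pathway. In brightfield
immunohistochemistry, LCs are visualized with an anti-CD1a antibody and a
brown DAB chromogen over a fast-red nuclear counterstain. The biological
question is therefore a *positional* one: not how many cells are stained
(cell counts are unreliable for a dendritic morphology in thin 2-D
sections), but *where in the depth of the epidermis* the DAB-positive
signal sits, and whether an exposure shifts that distribution.

skinDepth answers it with a two-stage, segment-then-measure pipeline:

1. **Segment** - classify every pixel of an analysis region into
   squamous layer (stratum corneum), epidermis, dermis, or outside;
   optionally refine with file-based polygon edits; then validate that
   the epidermis forms a sealed band.
2. **Measure** - build a relative-depth coordinate across the epidermis
   from two Euclidean distance maps, detect DAB-positive areas on the
   optical-density-sum channel, pool the depths of their pixels, and
   compare conditions with rank-based tests.

The stages are deliberately separable: a tissue classifier is
dataset-specific and will drift on new staining batches, so its output
must be inspectable and correctable before any measurement is trusted.
For the same reason the package never ships pretrained weights - users
train on scribbles from their own material.

## The relative-depth coordinate

Analysis regions are axis-aligned squares (typically 3-5 per section,
500 x 500 um). For a validated label mask, two binary masks are built:

* the **inner mask**: the epidermis plus a 4-connected flood fill seeded
  at the dermis centroid (or, for concave dermis shapes, the dermis pixel
  nearest the centroid). The fill - not the raw dermis labels - defines
  the dermis side, which makes the construction robust to isolated
  misclassified pixels inside the dermis: a single stray non-dermis pixel
  would otherwise corrupt the distance map;
* the **outer mask**: the complement of the inner mask with the
  epidermis re-added, i.e. outside + squamous + epidermis.

The two masks overlap exactly on the epidermis and jointly cover the
region. Exact Euclidean distance maps of both give, for every epidermis
pixel, the distance from the squamous/epidermis interface
($D_\mathrm{top\,epi}$, from the inner mask) and the distance from the
epidermis/dermis interface ($D_\mathrm{top\,derm}$, from the outer
mask). The relative depth is

$$ d_\mathrm{rel} \;=\; \frac{D_\mathrm{top\,epi}}
      {D_\mathrm{top\,epi} + D_\mathrm{top\,derm}} $$

with $d_\mathrm{rel} = 0$ assigned to outside/squamous pixels and
$d_\mathrm{rel} = 1$ to dermis pixels. A DAB-positive pixel at the
squamous interface approaches 0, one at the basal lamina approaches 1.

Numerical conventions, chosen so that every one of these quantities has
an unambiguous oracle:

* pixel centres sit at integer coordinates, origin top-left, x = column,
  y = row; micrometre coordinates are 0-based pixel centres times the
  calibration;
* distances are measured between pixel centres by an *exact* Euclidean
  transform (no chamfer approximation), so a brute-force
  nearest-background search is an equality test, and on the epidermis
  both maps are at least one pixel - the denominator never vanishes. On
  a flat band of thickness $T$ px the depth of the $k$-th epidermis row
  is exactly $k/(T+1)$, the closed form the test suite checks;
* micrometre-to-pixel conversions round half-up;
* the partition check uses 8-connected components of the non-epidermis
  pixels; the flood fill is 4-connected. This is the strictest
  combination: any 8-connected leak through the band is caught before
  the 4-connected fill could escape through it. A region fails when the
  dermis-seed component reaches an outside pixel (or a border squamous
  pixel), or when dermis pixels are stranded outside that component;
  enclosed misclassified islands *inside* the dermis pass, because the
  fill absorbs them harmlessly.

## Tissue classification

Any reasonable machine-learning pixel classifier could fill this role;
the concrete family here is a seed-fixed random forest (ranger, 50 trees by default) over a multiscale feature stack -
per-channel intensities, per-channel optical densities and the OD sum,
each Gaussian-smoothed at every requested scale (defaults 1 um and
4 um; 7 features per scale). These features separate the three tissue
colours (grayish keratin, strongly pink epidermis, pale pink dermis)
without any architecture heavier than a forest, and a fixed seed makes
retraining bit-reproducible.

The outside class is never trained. It is derived from a whiteness rule
(OD sum below 0.05), applied *before* the majority smoothing so that
the outside class takes part in the vote: isolated noise specks in the
background are then outvoted rather than surviving as stray tissue
pixels that would trip the partition check. Majority smoothing uses a
disk of radius 2 px; ties resolve to the lowest class code. Radius 0
disables smoothing entirely.

Manual brush correction of a GUI workflow is replaced by file-based
refinement: GeoJSON polygons (micrometre coordinates, even-odd
rasterisation at pixel centres) overwrite their pixels in file order,
so the last-listed polygon wins where edits overlap.

## DAB area detection

Detection runs on the OD-sum channel ($-\log_{10}(I_c/I_0)$ summed over
RGB, with a one-count floor guarding saturated pixels) at a working
pixel size of 0.6892 um, with this parameter block as the optimized
default set:

| parameter | default | role |
|---|---|---|
| pixelSize | 0.6892 um | working grid (bilinear resampling) |
| backgroundRadius | 20 um | disk radius of the grayscale opening |
| medianRadius | 0 um | optional median pre-filter (off) |
| gaussianSigma | 2 um | blur before thresholding |
| threshold | 0.20 OD | fixed cut on the corrected OD sum |
| minArea, maxArea | 5, 40000 um^2 | component size filter |
| maxBackground | 2.0 OD | exclusion of heavy-background pixels |
| splitByShape | FALSE | plain connected components, no watershed |
| smoothBoundaries | TRUE | per-component closing + polygon simplification |

The area bounds are read as um^2 (dimensional consistency with area
semantics). The background estimator is a grayscale morphological
opening with a disk element - a standard, monotone stand-in for
rolling-ball-style estimates; because flat-structuring-element openings
are scale-equivariant, the image is normalised to [0, 1] around the
operation so the backend's intensity clamp cannot truncate OD values
above 1. Components are 8-connected; blobs are ordered by the (row,
column) of their topmost-leftmost pixel, which fixes identities across
reruns. Boundary smoothing is a radius-1 closing per component followed
by Douglas-Peucker simplification of the traced contour at 0.5 px;
pixels under the exclusion mask are never re-added. Cell-expansion and
nucleus-related options of cell-detection tools map to no-ops here:
detected areas themselves are the objects.

One consequence worth knowing: thresholding a blurred disk at a level
well below its peak moves the detected boundary *outward* by roughly
$\sigma\,\Phi^{-1}(1 - t/A)$ (about 2.3 um at the defaults, for a blob
of unit DAB concentration), so detected areas systematically exceed
geometric areas. Depth measurements are unaffected - the dilation is
isotropic, so the added rim is depth-balanced - and the test suite
checks detected areas against the blur-corrected expectation, not the
bare disk area.

## Depth pooling and statistics

Each blob carries its pixel set, its per-pixel relative depths and the
per-pixel absolute distances (um) from both interfaces. Two poolings are
kept side by side: **per-pixel** (a value per DAB-positive pixel - large
areas weigh in proportion to size; this is what histograms and violins
show) and **per-blob** (one mean per detected area - the area-bias-free
reading). When all blobs have equal area the two agree exactly, a
property the tests exercise.

Histograms use 50 equal bins on [0, 1] with masses summing to one;
violin densities are renormalized to unit area on [0, 1] because shapes,
not pixel counts, are compared across conditions. The plotting
convention puts depth 0 (stratum corneum) at the top of the y axis and
1 (basal lamina) at the bottom, so downward migration reads downward.

Comparisons use the unpaired Wilcoxon rank-sum (Mann-Whitney) test -
pixel populations from different sections are independent, so a paired
variant is not meaningful. The implementation defers to
`stats::wilcox.test`: exact when both groups have at most 50 values and
no ties, otherwise the tie-corrected normal approximation with
continuity correction. The one-sided alternative tests whether the
exposed distribution is stochastically *deeper*. The "three equal
parts" analysis is taken as three depth *bands* - [0, 1/3), [1/3, 2/3),
[2/3, 1] - rather than equal-count terciles: bands ask the biologically
posed question (did signal accumulate near the basal lamina?) and stay
comparable across conditions with different sample sizes; a band left
empty by either group is flagged `insufficient data` instead of
erroring. Normality screening uses a one-sample Kolmogorov-Smirnov test
against a moment-matched normal; because the parameters are estimated
from the sample the p-value is conservative, which is acceptable for
its only role here - justifying rank-based tests. Constant samples get
a standard-deviation floor and are declared non-normal.

Replicates: pixels are pooled across replicate sections for testing,
and per-replicate histograms are also emitted so the bin-wise mean
curve (the quantity usually plotted) can be reconstructed; provenance
travels with every value.

## The synthetic skin phantom

Every stage is validated against phantoms with known ground truth,
since no slide material travels with the package. A phantom is a
layered cross-section - outside, squamous band, epidermis, dermis, top
to bottom, with optionally sinusoidal interfaces - rendered in OD space:
each tissue class gets a counterstain concentration and a small neutral
gray component, DAB blobs are disks added along the published DAB
vector, and the image is exponentiated through Beer-Lambert
($I = I_0\,10^{-\mathrm{OD}}$), so stain unmixing is analytically
invertible in the noise-free limit. Gaussian intensity noise (sd 5 on
the 0-255 scale by default) is added last.

Defaults describe one 500 x 500 um analysis square at 0.6892 um/px with
a 40 um squamous band, a 120 um epidermis and 25 blobs of radius
4-7 um - layer thicknesses and LC densities in the range seen in
abdominal skin cross-sections. The default planted depth distribution
is a two-component beta mixture centred mid-epidermis, the "double
peak" shape reported for unexposed skin; point-mass, uniform and single
beta alternatives support targeted tests.

Blob placement samples a target depth and inverts the closed-form depth
of the local column, so the planted depth is exact up to pixel
rounding. Two placement details matter for validation: centres keep a
separation of the two radii plus 7 px so that blur-dilated boundaries
do not coalesce into single components; and the depth is drawn afresh
on every rejected placement attempt, which keeps dense configurations
placeable (with a fixed depth the row is pinned and placement becomes
one-dimensional) without distorting the marginal depth distribution.
The generator is deterministic given its seed and restores the caller's
RNG state.

What the phantom does *not* emulate: dendritic LC morphology (disks
suffice because the pipeline is shape-agnostic), rete-ridge geometry
beyond a single sinusoid, chromatic noise correlations, uneven
illumination, folds, tears and staining artifacts. Passing phantom
tests therefore demonstrates correctness of the measurement chain, not
robustness to every histological artifact - which is exactly why the
segment stage remains inspectable and correctable.

## Dosimetry

A small helper reproduces the exposure arithmetic for occluded-insert
experiments: for aqueous solutions ppm equals mg/L, the applied mass in
ug is volume (uL) times concentration (g/L), and the areal dose in
g/m^2 divides the mass by the circular insert area (20 uL in an 8 mm
insert by default). Full precision is kept alongside a
2-significant-figure display, since published tables round (sometimes
down: 0.19894 shown as 0.19).

## Problem sizes and determinism

The shipped tests validate the distance transform against a brute-force
oracle on 200 random masks up to 64 x 64, depth anchors and closed
forms on flat-band phantoms with epidermis thicknesses of 100-200 px,
detection and depth recovery on 500 x 500 um phantoms with up to 50
planted blobs, the rank-sum test's size on 500 null simulations of
n = 20-25 per group, and byte-identical pipeline reruns. These sizes
were chosen so each check has an independently computable expectation;
scaling any of them up changes cost, not logic.

All randomness is seed-controlled: the phantom generator, scribble
sampler and classifier take explicit seeds; pipeline outputs (CSV,
GeoJSON, JSON) contain no timestamps, and the manifest records the
package version, seed and a hash of the configuration.

## Known limitations

* The depth coordinate is 2-D and sectional; it is not a geodesic or
  3-D tissue distance, and oblique sectioning compresses or stretches
  apparent depths.
* Only one sealed epidermis band per region is supported; multi-fragment
  regions fail the partition check by design (choose regions that avoid
  folds and cut edges).
* LC quantification inside the dermis is out of scope - ex vivo models
  lack circulation, so dermal migration is not interpretable there.
* The classifier is per-dataset by design; no transfer across staining
  protocols is attempted.
* Stain vectors are configurable constants, not estimated from the
  image (no Macenko-style estimation); the defaults are the standard
  published DAB vector and a fast-red-type vector.
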