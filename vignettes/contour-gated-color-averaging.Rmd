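---
title: "Contour-gated color averaging: model, stimuli and simulated experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour-gated color averaging: model, stimuli and simulated experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 5)
library(contourfill)
```

## The phenomenon and the model

When a smoothly varying, near-isoluminant color gradient is overlaid with
thin black outlines, the percept changes qualitatively: instead of a blurry
gradient one sees steps of roughly uniform color, one per outlined region,
and moving the outlines moves the perceived colors. The working model of
this effect — isomorphic filling-in — is that color signals spread in all
directions like a diffusing substance until they meet a strong luminance
contour, which blocks them. At steady state, each contour-bounded region
is filled with a single color.

`contourfill` implements this account as computation, in two equivalent
forms:

* **Region means** (`region_mean_percept()`): segment the image into
  contour-bounded regions and paint each region with the arithmetic mean
  of its pixels' tristimulus values. This is the closed-form steady state.
* **Diffusion** (`diffuse_fill()`): iterate 4-neighbor averaging with
  no-flux boundaries at barrier pixels and image edges until the largest
  per-pixel update falls below a tolerance. Conservation of the channel
  totals forces the steady state within each region to the region mean, so
  the two routes must agree; the test suite checks this equivalence on
  randomized stimuli.

Averaging is done in linear tristimulus space (XYZ, equivalently linear
display RGB): the mean of physical lights is the physically correct
superposition. Averaging CIE xy chromaticities directly would weight all
pixels equally regardless of their luminance and differs in the third
decimal on these stimuli; the choice is switchable by averaging the
columns you prefer from the tidy pixel table.

## Colorimetry and the display model

All colors are specified as CIE xyY (chromaticity plus absolute luminance
in cd/m²) and converted with the standard relations
`X = xY/y`, `Z = (1 − x − y)Y/y`. The display model is sRGB primaries with
a D65 white, linear-light encoding internally; the display white maps to
RGB (1, 1, 1) at a configurable white luminance (340 cd/m², the stimulus
background). Gamma encoding is applied only on PNG export. No monitor
model is dictated by the stimuli themselves; a published standard keeps every
conversion auditable, and an independent sRGB implementation (farver)
cross-checks the matrix in the test suite.

Out-of-gamut colors are clipped per channel and flagged. The shipped
stimulus builders pre-validate their colors so that no rendered pixel is
ever clipped (the plaid's *component* layers may be virtual out-of-gamut
lights, but only their in-gamut mixtures are rendered; see below).

The 16-color palette (`teufel_palette()`) approximates a published set of
approximately isoluminant, equally detectable, perceptually equidistant
colors by an isoluminant circle in CIE xy around a gray point
(default (1/3, 1/3), radius 0.08, 126 cd/m²). The original coordinates are
not republished here, so equal perceptual spacing is
approximated by equal angular spacing — an acknowledged approximation.
Entries `i` and `i + 8` are opponent pairs (reflections through gray);
entries `i` and `i + 4` are orthogonal axes.

```{r palette}
pal <- teufel_palette()
pal[1:4, ]
```

## Stimuli

Three stimulus classes are rendered from declarative specs
(`stimulus_spec()`), all geometry in visual degrees at a configurable
pixels-per-degree scale (default 32 px/deg, which keeps the 10.8-degree
disk at 346 px and the whole pipeline in seconds).

**Gradient disk** (`exp1_disk_raster()`): three concentric square-wave
ring gratings, one per opponent pair, phase-shifted by thirds of a cycle,
averaged in linear light and Gaussian-blurred. One cycle holds both pair
members; the study reports neither the pairs, the period nor the blur, so
the disk is reproduced structurally: palette pairs (1, 9), (3, 11),
(5, 13), period 2.4°, blur sigma = period/6.

**Octagon plaid** (`exp1_plaid_raster()`): two octagon-tiling images
(truncated-square tiling, regular octagons plus corner diamonds) in
spatial counter phase both horizontally and vertically, superimposed
50/50 in linear light and blurred (sigma = tile period/6); 9.5 cycles
across 10.8°. The printed extremes — green (0.329, 0.412) and purple
(0.310, 0.306), both 126 cd/m² — are realized *exactly*: the two
construction pairs are symmetric about the green/purple mean in
tristimulus space and mutually orthogonal in the isoluminant plane, and
the geometry is such that green appears where octagons of one layer cover
interstices of the other, purple at the reverse overlap. (A counter-phase
truncated-square tiling never overlaps interstice on interstice, which
dictates this assignment.) The component colors sit slightly outside the
sRGB gamut at these luminances; they are mixed before clipping, and every
rendered pixel is in gamut.

```{r plaid, eval = FALSE}
autoplot(exp1_plaid_raster(ppd = 16))
```

**Anchored gradient** (`exp2_gradient_raster()`): the matching experiment
reports the exact colors at six equidistant probe locations but not the
disk's construction, so the 19.8° disk is rebuilt as a periodic radial
profile that passes exactly through the six printed xyY anchors
(periodic cosine interpolation of XYZ between consecutive anchors, period
= six spacings). Cosine interpolation has zero slope at the anchors, which
makes small-annulus sampling around an anchor unbiased to first order.

### Geometry of the six probe locations

The study states that the six dot locations are equidistant, not where
they are. Here they sit at radii 2.4° to 6.9° (spacing 0.9°, one 5.4°
period) with contour circles every half period (2.7°); contour setting
*s* shifts the circles outward by (s − 1) spacings. This placement was
chosen so that **every** location under **every** setting lies inside a
complete inter-contour annulus. The wrapped member of a triplet (e.g.
location 1 grouped with 5 and 6 under setting 2) then sits in a full
annulus exactly one period inward, whose profile is identical; the region
means differ only through the area weighting of an annulus (weight ∝ r),
about 0.008 in xy here — well inside the 0.02 cluster cutoff. Placements
that let the wrapped member fall into the truncated central disk instead
produce a spurious ~0.04 xy offset and break the two-triplet cluster
structure that the human data show.

### Contours

Contour overlays (`contour_spec()`, `overlay_contours()`) are hard,
non-anti-aliased lines of a near-black display gray (0.5 cd/m²), at least
1 px wide (`ceil(arcmin/60 × ppd)`), so that segmentation barriers are
unambiguous — segmentation correctness is preferred over cosmetics.
Families: concentric circles for disks; octagon, square, diamond and
small/large circle grids for plaids. Grid phases shift both axes by the
given cycle fraction, except the diamond grid, whose lattice is invariant
under a joint half-period shift of both axes; its counter-phase placement
shifts one axis only.

## Segmentation and prediction

`barrier_mask()` thresholds luminance at 5 cd/m² by default — far below
the darkest stimulus color (90.2 cd/m²) and far above the 0.5 cd/m²
lines; thresholds that mask more than half the stimulus area raise an
over-masking error. `label_regions()` labels 4-connected barrier-free
components (4-connectivity so that color cannot leak through diagonal
line joints), deterministically numbered in raster-scan order; the area
outside a disk stimulus becomes a separate background region excluded
from percept statistics.

`predict_match()` returns the model's match at a probe point: the region
mean with contours, or the mean over a small annulus (inner 0.05°, outer
0.15°) without contours. The study specifies only that observers matched
the color immediately around the probe dot, with no size; 0.15° keeps the
sample local — at the 0.9° anchor spacing used
here a 0.25° annulus would blend a quarter of the way to the neighboring
anchors and bias the sampled anchor color by ~1e-3 in x (the interpolant's
curvature), while 0.15° keeps the bias near 4e-4. Both radii are
arguments.

## The simulated experiments

**Comparison battery** (`run_exp1_battery()`): thirteen contoured
stimuli (disk at three contour phases; five plaid outline families at two
counter-phase placements), compared same-vs-different by a noise-free
ideal observer — the human judgments were unanimous, so no observer noise
model is needed. Two arrangements count as "same" when the largest
chromaticity difference between their percept maps, probed over every
region of the partition induced by both contour sets together, is at most
`tol_xy` = 0.005 (an order of magnitude below the anchor spacing of the
printed colors). Each comparison is repeated four times to mirror the
design; repeats are identical by construction.

**Matching experiment** (`run_exp2()`): the 4 conditions × 6 locations
model table; `cluster_matches()` groups one condition's per-location
matches by single-linkage agglomeration on xy distances, cut at 0.02 —
chosen to separate the printed anchor triplets (their means differ by
~0.06 in x) while merging within-region predictions; ties cannot arise
with single linkage on distinct merge heights, and cluster ids are
renumbered by lowest location for determinism. `dispersion_report()`
compares within-cluster spread against the same locations' no-contour
spread. All outputs are descriptive; no hypothesis tests are performed,
so no multiplicity correction applies.

```{r exp2}
records <- run_exp2(ppd = 16)
glance(cluster_matches(records[records$condition == "1", ], cutoff = 0.02))
dispersion_report(records)
```

## Synthetic observers

No per-observer human matches are published, so `simulate_matches()`
generates them around the model predictions: per-trial isotropic Gaussian
noise in xy (SD 0.005 per axis) and luminance (SD 2 cd/m²), plus a
per-observer bias drawn once (SD 0.002), in the study's 5-observer ×
3-repeat design. The noise SDs are placeholders chosen so the simulated
scatter resembles the published error-bar scale; they are documented as
such and exposed in `observer_model()`. Chromaticities are clipped to the
valid domain with a clip count recorded. `recover_region_colors()`
estimates per-condition/location means with standard errors and, given
the truth table, the recovery error; recovery tests check the
√n-consistency of the estimator and that clustering of recovered means
reproduces the truth clustering at realistic noise and fails at noise far
above the cluster separation. The consistency bound 4σ/√15 concerns the
trial noise, so those checks disable the bias term.

## What the simulations do and do not show

The generator emulates the *structure* of the study: printed stimulus
parameters, printed anchor colors, design sizes, and an idealized
observer. It does not emulate human adjustment dynamics, adaptation,
response times, RGB keyboard step quantization, or the residual
within-region gradients that real percepts retain — the model idealizes
the roughly uniform perceived steps to exact uniformity.
Numeric agreement with individual human matches is therefore out of
reach by construction; the reproducible surface is the all-or-none
comparison outcome, the two-triplet cluster structure, and the dispersion
ordering.

## Numerical choices

* Diffusion uses a conservative flux-form update: each open neighbor pair
  exchanges a fraction λ = 0.2 of its difference per iteration. This
  conserves the channel totals exactly at every iteration (the property
  that pins the steady state to the region mean) and, unlike pure
  neighbor averaging (λ = 1/4), leaves every pixel a positive self-weight
  so the bipartite checkerboard mode cannot oscillate. Tolerance 1e-6
  (linear channel fraction), iteration cap 100 000; non-convergence is an
  error carrying the last residual, never a silent result.
* Default rendering scales: 32 px/deg for the acceptance-scale runs,
  16 px/deg in structural tests, small synthetic rasters (22–40 px) for
  the diffusion-equivalence properties. These sizes keep the full test
  suite under a minute on one core while leaving every check at least an
  order of magnitude of headroom to its tolerance.
* Probes landing on a barrier pixel fall back to the nearest region pixel
  and are flagged (`on_barrier`).
* Degenerate inputs: uniform rasters are fixed points of both percept
  routes; an all-clear mask yields one region; `family = "none"` overlays
  are exact no-ops.

## Known limitations

Perceptual equidistance of the palette is approximated geometrically; the
diffusion is isotropic with binary barriers (no edge-strength weighting,
no temporal dynamics); contours must be closed luminance-defined curves —
illusory or texture-defined contours are out of scope; and the Exp-2
geometry, while constrained by the printed equidistance and the cluster
structure, remains a reconstruction, not the original stimulus.
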