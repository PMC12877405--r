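---
title: "Quantifying stretch-induced remodeling from fluorescence images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stretch-induced remodeling from fluorescence images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stretchquant)
```

## Scope and conventions

`stretchquant` implements the image-quantification layer of uniaxial
cyclic-stretch experiments on adherent cell monolayers: five independent
fluorescence readouts (actin-fiber orientation, LC3B autophagosome puncta,
paxillin/vinculin focal-adhesion colocalization, Tomm20 mitochondrial
morphology, and MitoTracker / JC-1 intensity readouts), the angular
statistics used to compare stretched against unstretched conditions, and a
synthetic-scene generator that provides ground truth for all of them.

All rasters are `[y, x]` matrices with the origin at the top-left;
multi-plane channels are `[y, x, z]` arrays. Orientations are axial angles
in degrees in $[0^\circ, 180^\circ)$ measured from the image x axis toward
increasing y; for analysis they are folded to the acute angle against the
stretch axis, so $0^\circ$ means parallel and $90^\circ$ perpendicular to
strain. Physical pixel sizes differ per assay (0.071 µm for LC3B, 0.183 µm
for adhesions and Tomm20, 0.18 µm for MitoTracker, 0.721 µm for JC-1) and
enter only through area conversions; all algorithmic parameters are in
pixels.

## Actin-fiber orientation

Fiber orientation is estimated from gray-value gradients: the image is
pre-smoothed with a Gaussian ($\sigma = 1$ px), Sobel gradients are taken,
and each pixel's fiber orientation is the direction orthogonal to its
intensity gradient, weighted by the squared gradient magnitude. The
operator pair (Sobel + $\sigma = 1$ Gaussian) is the minimal standard
choice for a gradient-orientation estimator; both are configurable.

A monolayer image is then partitioned into a grid of *cell equivalents*
(default $5 \times 3$, matching the mean number of cells per field at the
acquisition magnification). Within each square a weight-weighted histogram
of orientations is built in $1^\circ$ bins, circularly smoothed with a
5-bin moving average, and the histogram maximum is that square's main
orientation (ties break toward the smaller angle; the smoothing makes the
argmax stable under bin-quantization noise). Squares whose total gradient
energy falls below 5% of the mean per-square energy are omitted — real
monolayers are confluent, but synthetic or sparse fields may contain empty
squares that carry no orientation signal.

The per-image statistic is the mean of per-square main orientations after
folding; because cells within one image communicate mechanically, the
image (not the square) is the independent unit for condition-level
statistics. Under a uniform orientation distribution the folded mean
converges to $45^\circ$, which is the unstretched-baseline value the
pipeline must reproduce (`scripts/acceptance.R` recomputes it on 30
generated scenes of 200 fibers each).

## LC3B puncta

Puncta are segmented by a global threshold (Otsu by default; any numeric
threshold can be supplied and the value actually used is recorded in the
output for audit), followed by rejection of components smaller than 70
pixels — the boundary is inclusive on the keep side, i.e. a 70-px spot
survives. Touching spots are split by a marker-based watershed on the
Euclidean distance transform: distance-map maxima seed the basins, maxima
closer than 5 px share one marker (one marker per connected plateau), and
a sub-pixel merge tolerance (0.5) is used because two touching
diffraction-limited spots leave a saddle less than one pixel below the
peaks. Components with a single maximum are returned unchanged, and
splitting never merges pixels nor changes the union of foreground.

Counts are normalized per cell by dividing by the number of nuclei. Nuclei
counts are taken verbatim when supplied manually (the reference procedure
counted DAPI nuclei by hand); otherwise a standard automatic chain
(Gaussian smoothing, Otsu, distance-transform watershed, minimum-area
filter) is applied. The whole frame is analyzed without a cell mask, since
the monolayer covers the full field.

## Focal adhesions

The two-channel adhesion algorithm follows a fixed sequence:

1. **Cell mask** from the paxillin channel: CLAHE (2% clip), disk median
   filter (radius 5 px), Gaussian smoothing ($\sigma = 5$ px), then a
   threshold placed 0.2 FWHM to the right of the first local maximum of
   the Savitzky–Golay-smoothed (21-bin window, cubic) 256-bin gray-value
   histogram. The FWHM is measured by linear interpolation of the
   half-maximum crossings; if the right flank never reaches half maximum,
   twice the measurable left half-width stands in and a machine-readable
   warning is raised. This threshold sits deliberately close to the
   background peak: the mask is a generous region of interest that never
   clips cell area but includes a smoothing halo around sharp edges. A
   constant bright frame is treated as fully cell-covered (single
   population); an all-zero frame is an error.
2. **Spot detection** per channel: Gaussian smoothing ($\sigma = 3$ px),
   CLAHE (2% clip), per-pixel z-score over a centred 35 × 35 px window
   (mirror-padded at borders; windows with zero variance give z = 0),
   binarization at $z > 1$ inside the cell mask, and retention of
   8-connected components whose area *strictly exceeds* 100 px.
3. **Mutual overlap filter**: a spot survives only if it shares at least 5
   px with a *single* partner spot in the other channel — overlap is
   counted per partner, never pooled across partners.
4. **Assembly**: 8-connected components of the union of surviving
   foreground become focal adhesions; components containing only one
   channel are dropped. Each FA is measured by per-channel pixel areas,
   union area (px and µm²), centroid, and the second-moment ellipse
   orientation folded to the stretch axis. When one spot overlaps several
   partners the union component merges them; such FAs are flagged
   `multi_partner` in the output.

Per-image summaries are per-FA means (mean pxn/vcl spot area, coverage
fractions as total channel area over total union area, mean FA area, FAs
per cell), and the FA orientation list feeds the same angular statistics
as the fiber pipeline.

## Mitochondria

**Tomm20 morphology.** Each z-plane passes through: disk median filter
(radius 2 px), white top-hat (disk radius 5 px, isolating tubule-scale
bright features), CLAHE (2% clip, tiles 1/8 of each image dimension),
Sauvola local threshold (radius 15 px, $k = 0.2$, window $= 2r + 1 = 31$
px), a binary opening with a two-pixel disk that separates touching
objects while preserving the 2–4 px wide tubules themselves, and
skeletonization. Two readings of the cited building blocks required a
decision. First, Sauvola's rule $t = m(1 + k(s/R - 1))$ was designed for
dark ink on bright paper and marks entire flat regions as foreground when
applied directly to bright-feature images; it is therefore applied to the
inverted image under the document convention, which is the behavior the
method's own derivation intends. Second, skeletonization uses Guo–Hall
thinning rather than the more common Zhang–Suen variant because the
latter leaves two-pixel staircase residue on oblique tubules that
corrupts length estimates. Object *number* is counted on the skeleton
(connected components), object *area* on the pre-skeleton binary mask —
skeleton pixels carry no area; both are reported. Skeleton length sums
graph links (1 for orthogonal, $\sqrt{2}$ for diagonal neighbours,
excluding diagonal chords of two orthogonal links); residual digitization
bias is angle-dependent and below ±5% for straight tubules.

**MitoTracker intensity.** Maximum-intensity projection, background
correction by subtracting the morphological opening with a 251 × 251
square structuring element, subtraction of the minimum, Otsu threshold
divided by three (to pull dimmer cytoplasmic pixels into the cell mask),
opening/closing cleanup (disk radius 3 — the operations are named but not
sized in the reference description), and removal of objects below 1,000
px (a 1,000-px object is retained). The readout, mean intensity inside
the mask minus mean intensity outside, is invariant to any global
additive offset by construction, and is normalized by scaling the
unstretched-control mean to 1.

**JC-1 ratio.** MIPs of both channels are summed, smoothed
($\sigma = 3$ px), globally z-scored, and a grayscale opening (disk
radius 15, large enough to act as a local background estimate) is
subtracted before segmenting at the fixed threshold 0.6. The readout is
the red/green mean-intensity ratio inside the resulting bright-region
mask; it is exactly invariant to a common positive scaling of both
channels and strictly increasing in the true ratio. Global (not per-tile)
z-scoring is used, as the fixed 0.6 threshold is only meaningful on a
globally standardized image.

## Statistics

Condition comparisons use the two-sample Kolmogorov–Smirnov test for
angular distributions (exact p-values for $n_1 n_2 \le 10^4$ without ties,
asymptotic otherwise) and the Mann–Whitney test for per-cell counts
(exact for small untied samples, tie-corrected normal approximation
otherwise; completely tied samples return $p = 1$). Both are called
through the standard R implementations and verified in the test-suite
against brute-force permutation enumeration at $n = 5$ per group.
Confidence bands are percentile bootstraps over the independent unit
(image or cell — the unit is a parameter because study designs switch
between them), pointwise along the cumulative curve for angular
distributions. No multiple-testing correction is applied by default,
matching the pairwise reporting convention of the readouts; a
Benjamini–Hochberg adjustment can be applied downstream via
`stats::p.adjust`. Control normalization divides by the unstretched-group
mean.

## Synthetic scenes and what they do (not) show

Each generator renders the geometry its assay measures, records exact
per-object truth, and is deterministic under a fixed seed:

* fibers: anti-aliased line segments (length 40 px, width 3 px by
  default) with uniform, fixed, or axial von Mises orientation laws (the
  von Mises law uses the doubled-angle construction standard for axial
  data);
* puncta: 2-D Gaussian profiles truncated at $3\sigma$, with the pixel
  area above the rendering threshold recorded per spot so area-filter
  boundaries are testable exactly; cluster pairs are placed at 1.8 spot
  radii so their supports merge but leave a watershed-resolvable waist;
* adhesion pairs: rotated aspect-3 super-ellipses whose ellipse-fit
  orientation has a well-defined truth; the second channel is a shifted
  copy trimmed pixel-by-pixel so each pair shares *exactly* the requested
  overlap;
* mitochondrial branches: random-walk polylines dilated to 3 px, placed
  with an exclusion margin so the truth object count is unambiguous;
  endpoint insets make the rendered extent match the nominal length;
* JC-1 fields: identical cell supports in both channels with the red
  channel scaled, so the pre-noise foreground ratio is exact.

Noise follows a photon-limited camera model: Poisson shot noise at a
configurable photon budget, Gaussian read noise, constant background
offset, clipped at zero. The default conditions (photon scale 100, read
noise 0.01, offset 0.02) emulate well-exposed confocal acquisitions;
robustness checks run at a photon scale of 25 (signal-to-noise ≈ 5).
Packing uses rejection sampling with a bounded retry count and fails
loudly rather than silently overlapping objects.

What passing these tests shows is that the *algorithms* implement their
stated contracts and recover known geometry under controlled noise. The
scenes deliberately omit optical point-spread blurring, uneven
illumination, autofluorescent debris, out-of-focus light and biological
shape variability, so performance on real micrographs depends on
acquisition quality in ways the synthetic suite cannot certify.

## Problem sizes and numerical choices

Test and acceptance runs use 256–384 px square scenes, 30-scene
orientation ensembles, 2,000 null simulations for test calibration and
200 for power — sizes chosen so the whole suite completes in a few
minutes on one CPU while keeping Monte-Carlo standard errors well inside
the asserted tolerances. Degenerate inputs follow explicit rules:
constant images yield zero-weight orientation fields, empty masks, or
errors where a downstream division would be undefined (zero nuclei, empty
control samples, flat JC-1 composites); all boundary comparisons
(`< 70 px`, `> 100 px`, `>= 5 px`, `< 1000 px`) are implemented with the
exact strictness stated, and the tests probe each boundary at ±1 pixel.

## Known limitations

* The cell mask is a generous ROI: its threshold hugs the background
  peak, so masks include a halo around sharp bright boundaries. This does
  not affect the adhesion metrics (which are spot-based) but the mask
  itself should not be used as a precise cell-area estimate.
* Orientation recovery degrades for fibers shorter than about three times
  the smoothing scale, and the grid argmax is only defined to the 1°
  histogram resolution.
* The watershed split assumes roughly convex puncta; long curved chains
  of more than two merged spots may be under-split.
* Tomm20 "average area" is reported from binary objects and "number" from
  the skeleton; when objects are heavily curved these two countings can
  diverge, and both are exposed.
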