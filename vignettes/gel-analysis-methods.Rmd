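---
title: "Methods: 2DE gel image analysis in gelmap2d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2DE gel image analysis in gelmap2d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelmap2d)
```

## The problem

Two-dimensional gel electrophoresis (2DE) separates a protein mixture by
isoelectric point (pI, horizontal axis) and molecular mass (kDa, vertical
axis). A Coomassie-stained gel scanned in transmission mode is a 16-bit
grayscale raster in which each protein appears as a dark, roughly
Gaussian pit on a bright, smoothly varying background. Comparative
proteomics asks, for two such gels (say, a control sample G1 and a
pathological sample G2): which spots correspond, and how much did each
protein's quantity change?

`gelmap2d` implements the full chain — preprocessing, master-gel
selection, spot detection and segmentation, neural region
classification, landmark-based registration, spot pairing, and
normalized quantification with signed fold changes — together with a
synthetic gel generator that provides ground truth for every stage.

## Coordinate and intensity conventions

Pixels are addressed `[row, col]`, 1-based, as in R matrices; regions of
interest are half-open, `c(r0, r1, c0, c1)` meaning rows `r0 .. r1 - 1`.
(An equivalent 0-based convention is common in other ecosystems; in R a
1-based convention removes a permanent off-by-one translation against
every matrix subscript, `which()` result and plotting call, so this
package adopts it and keeps the half-open interval arithmetic.)

Intensities are stored as scanned: high values are bright background,
protein spots are pits. Stages that need "spot = positive signal"
(background subtraction, volume quantification) invert explicitly;
detection is run on the dark-polarity smoothed scan.

Molecular-mass calibration interpolates `log10(kDa)` piecewise-linearly
against row — the standard SDS-PAGE migration law — and pI linearly
against column. Extrapolation is permitted up to 10% of the marker span
(experimental masses above the heaviest ladder point are routine in gel
tables) and refused beyond that.

## The synthetic gel generator

Real scans for this kind of study are rarely deposited, so the generator
is a first-class module, not a test shim. It emulates:

* a bright background (`bg_base`, default 52,000 on the 16-bit scale)
  with a low-order polynomial drift (defaults of a few thousand counts
  across the frame, matching the gentle staining gradients of real
  scans);
* dark anisotropic Gaussian pits with amplitudes of roughly 4,000–28,000
  counts and radii `sigma` of 2.5–5 px — at 300 dpi this corresponds to
  spot diameters near 0.5–1.5 mm, the typical Coomassie spot size — with
  the closed-form pit volume `2 * pi * A * sigma_r * sigma_c`;
* a smooth column-dependent vertical shift of iso-molecular-mass rows
  (quadratic polynomial, a few px), the migration artefact that
  straightening corrects: real gels distort most near their vertical
  edges;
* additive Gaussian scanner noise (default a few hundred counts; the
  "SNR 10" test condition uses amplitude 5,000 against noise sd 500) and
  salt/pepper impulses from dust and stain particles (default rate
  around 1%, strictly below 20% — beyond that a 3x3 median no longer
  guarantees impulse removal and the preprocessing contract would be
  void);
* rendering order distort-then-noise, so denoising faces realistic
  input, and quantization to the integer scanner scale, so TIFF round
  trips are exact.

Everything is a pure function of `(spec, seed)`; the caller's RNG stream
is saved and restored.

What the generator does *not* emulate: streaks and smears, saturated
spot plateaus, dust fibers, spatially correlated stain texture, and
non-Gaussian spot tails. Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not performance
on arbitrary real scans; on real data the interactive repair surface
(`edit_segments`, `edit_matches`, `flag_uncertain`) exists precisely
because segmentation and matching degrade.

The paired generator (`render_pair`) shares a spot layout between two
gels, scales amplitudes by per-spot ratios, and applies independent
distortion and noise. Its truth records both the raw amplitude ratio
and the signed fold change of the *normalized* quantities — the latter
is what the pipeline estimates, and the two differ by the gels'
total-volume ratio whenever the ratios do not cancel.

## Preprocessing

**Median smoothing** replaces each pixel by the exact median of its
odd-sized window (default 3), with mirror-reflected borders. A single
impulse in a 3x3 window can never be the median, so isolated dust
pixels vanish exactly while spots (tens of pixels wide) are barely
moved.

**Background removal** is a morphological top-hat: the image is
inverted so spots are peaks, a grayscale opening with a disk
structuring element (default radius 20 px, chosen above the largest
expected spot radius) estimates the background, and the difference is
the non-negative spot signal. The implementation replicate-pads before
the opening — erosion against an implicit zero border would otherwise
fabricate signal along the frame — and rescales to the unit range the
morphology engine expects. Constant and smooth-ramp backgrounds map to
(numerically) zero; pit depth is preserved to well under 2% when the
spot diameter is below twice the disk radius.

**Distortion scoring** quantifies how far iso-molecular-mass structure
departs from horizontal. The pipeline: a wide 1x9 horizontal median
(suppresses point features, keeps ridges), strong horizontal Gaussian
smoothing (links the spots of one mass row into a continuous ridge),
per-column vertical non-maximum suppression above an intensity quantile
(the near-horizontal-edge specialization of an edge detector), greedy
column-to-column linking into contours with a small jump gate, removal
of contours shorter than 30% of the width, quadratic `row(col)` fits,
robust rejection of outlier tilt coefficients (median ± 3 MAD), and the
scalar score

> `D` = length-weighted RMS over retained contours of
> (fitted row − contour median row), in px.

`D` is zero exactly when every fitted contour is horizontal and is
invariant to a whole-image vertical shift. No unique aggregate is
canonical here; RMS was chosen once for smooth behavior under the
monotonicity properties the tests enforce (`D` strictly increases with
applied distortion amplitude on the generator's distortion family).

**Master-gel selection** is `argmin D` with ties to the first gel;
**straightening** estimates the per-column shift field as the
length-weighted mean of contour deviations, lightly smoothed, and
resamples each column with linear interpolation (marker rows are
remapped consistently). On generator fixtures the re-scored `D` drops
to a few percent of its pre-warp value, far below the 25% contract.

## Spot detection and segmentation

**Rotational symmetry map.** The gradient orientation field in
double-angle representation, `z = (g_c + i g_r)^2` normalized to unit
magnitude, is correlated with the conjugate second-order rotational
basis `((x + iy)/|x + iy|)^2` on a Gaussian annulus at the requested
scale. At the center of any rotationally symmetric blob the double-angle
field matches the basis phase exactly, so the real part `S_R` peaks
there — independent of contrast sign and nearly independent of
amplitude, which is what makes the subsequent watershed threshold-free.
The kernel is symmetric under point reflection, so FFT convolution and
correlation coincide.

**Multi-scale handling.** Gel spots vary several-fold in radius. The
maps at the configured scales (default 4 and 8 px) are *averaged* and a
single watershed is run on the aggregate. The alternative — merging
candidate sets from per-scale watersheds by non-maximum suppression —
cannot keep the region masks a partition of the image, and the
partition invariant is what makes volumes additive and edits
well-defined; averaging preserves it by construction.

**Watershed.** The transform is 8-connected steepest ascent: every
pixel follows its largest neighbor uphill to a regional maximum, one
region per maximum, no flooding tolerance. Plateaus (exact ties — the
symmetry map is exactly zero over featureless background) are broken by
an infinitesimal ramp in linear pixel index, far below the smallest
real intensity gap, so a flat background drains to a single
well-defined pixel and the result is deterministic. The test suite
checks the partition property on every fixture and compares the labels
pixel-for-pixel against an independently written per-pixel hill-climb
oracle.

Before flooding, the aggregated surface is Gaussian-smoothed with
sigma equal to half the mean detection scale (region maxima are still
read from the unsmoothed map). The regularization matters
quantitatively: noise and background gradients leave shallow spurious
maxima in the symmetry surface near faint spots, and without smoothing
those maxima truncate a faint spot's basin at about 2.5 sigma — the
measured volume then captures an amplitude-dependent fraction of the
true volume (about 0.67 at pit depth 2,000 versus 0.92 at 32,000 in
generator experiments), which biases fold-change ratios precisely for
the spots whose ratios are most extreme. With the smoothed surface,
basins extend to the true ridges between spots and end-to-end
fold-change recovery lands within 10% everywhere on the validation
pairs.

**Curvature filter.** Rotational symmetry cannot tell a dark pit from a
bright bump, so candidates whose Laplacian-of-Gaussian response at the
core is negative (bright blobs) are removed; a dark pit has positive
smoothed curvature at its minimum. The LoG kernel is zero-sum (constant
images map to exactly 0) with 3-sigma support.

**Region features.** Five per region, in fixed order: (1) the 256-bin
histogram mode of the region's intensities; (2) the max–min intensity
difference over the region's contour pixels, weighted by the inverse
equivalent diameter `2 sqrt(area / pi)` — the weighting makes contour
contrast comparable across region sizes, since no canonical weighting
exists; (3) the same weighted contour range on the symmetry map; (4)
the per-region maximum of a phase-symmetry detector over a log-Gabor
bank (3 scales from wavelength 3 px at multiplier 2.1, 4 orientations,
radial bandwidth 0.55, dark polarity, with the noise floor taken as
twice the mean amplitude of the smallest scale); (5) the per-region
maximum LoG response. Features are z-scored with training-set
statistics before classification.

**Region classifier.** A feedforward network with layer widths
5–10–3–2 and tangent-sigmoid transfer everywhere, trained by full-batch
BFGS on the squared error of a 2-unit class code: C1 = (+1, −1) "one
spot in the region", C2 = (−1, +1) "only part of a spot",
C3 = (−1, −1) "no spot". Decoding is nearest-code; exact ties resolve
to C2 so ambiguity surfaces for review. Two output units cannot encode
three classes one-hot, so the 2-bit code is a declared convention of
this package. Training data come from `labeled_regions()`: the
generator renders patches and hands the classifier *watershed-shaped*
masks — the cell around a whole spot (C1), that cell cut through the
spot center (C2, emulating over-segmentation), or a cell of a
noise-only patch (C3) — passed through the same median smoothing the
detector input receives. Matching the training distribution to the
deployment distribution in mask shape and preprocessing is what makes
the classifier transfer; the shipped default is 500 patches per class
at a fixed seed, retrainable via `train_region_classifier()` or the CLI.

Detection then reads: C1 regions become accepted spots, with sub-pixel
centers from a separable quadratic refinement of the symmetry peak
(offsets clamped to half a pixel) and calibrated (Mw, pI) coordinates
when a calibration is attached. C2 regions plus low-confidence C1
regions are returned by `flag_uncertain()` for interactive repair.

## Registration and pairing

**Landmarks.** Keypoints are maxima of the dark-polarity LoG response.
Each is described by a 4x4-cell x 8-orientation gradient histogram over
a radius-24 window, Gaussian-weighted, contrast-normalized with the
usual 0.3 clipping. The window is deliberately wide: individual gel
spots are nearly identical Gaussian pits, so a descriptor must capture
the surrounding spot *constellation* to be distinctive. Matching is
mutual nearest-neighbor with a best/second-best ratio test, then
geometric consensus: a Hough vote over the candidate displacement
field finds the dominant translation, pairs within 10 px of it are
kept, and a robust IRLS-Procrustes fit over those inliers refines the
final set. The consensus step is what makes matching survive per-spot
fold changes — when neighbor intensities change several-fold the
descriptors of correct pairs drift, wrong matches can become the
majority, and any estimator fit to *all* candidates (including a
robust one) breaks; the dominant-translation vote does not. For the
same reason the ratio-test default is a permissive 0.95: the test's
job here is only to drop hopelessly ambiguous candidates before the
vote. Fewer than 3 surviving non-collinear pairs (or under 30% of
candidates) raises "insufficient reliable landmarks" — a pure-noise
image fails here rather than registering garbage. The 10 px gate is
loose on purpose: the smooth non-rigid row distortion is several px
and must survive to the spline stage, while genuinely wrong matches
sit tens of px away. The consensus assumes the inter-gel pose is
dominated by translation plus mild rotation, which holds for gels
scanned on the same instrument.

**Rigid fit.** Closed-form weighted Procrustes (SVD, reflection
excluded), made robust by iteratively reweighted least squares with
Huber weights; isotropic scale is available behind a flag but off by
default, since gels are scanned at a fixed, known resolution.

**Thin-plate spline.** The standard kernel `U(r) = r^2 log r`, affine
part plus kernel weights from the bordered system, with `lambda` on the
kernel block; source coordinates are normalized to the unit box for
conditioning, which is what holds landmark residuals below 1e-9 at
`lambda = 0`. Zero regularization (exact interpolation) is the default,
matching the overlay use where landmarks are trusted; `lambda > 0` is
exposed for noisy landmark sets. Bending energy is reported. Mapping
direction is fixed A → B with the master gel as B; residuals are
measured in B's frame.

**Pairing.** A-spot centers are mapped through the spline and assigned
one-to-one to B spots greedily by ascending residual among candidates
within the gate (default 6 px). Greedy assignment on gate-limited
candidates almost always coincides with the optimal assignment while
keeping an auditable order; no Hungarian solver is shipped (none of the
installed dependency set provides one, and the gate-limited problem
does not need it). Unmatched spots on either side are reported, and
`edit_matches()` preserves the one-to-one invariant under manual
repairs, logging every edit.

## Quantification

Spot quantity is the summed spot-signal intensity over the region mask,
measured **above the region's local baseline** (the median signal on
its contour pixels). The global top-hat removes the smooth background,
but under dense spot clusters the disk opening leaves a residual
pedestal, and its background estimate bridges across each pit using
values up to a disk diameter away, where a curved background differs by
tens of counts; integrated over a watershed cell of ~1,000 px such
residuals would rival a faint spot's whole volume. Referencing each
region to its own boundary removes the pedestal. The baseline is
subtracted from the sum, never per pixel — per-pixel clipping at zero
would rectify noise over the cell area and bias faint spots upward.
Volumes are computed on background-subtracted (not raw) intensities so
that the exposure invariance of normalized quantities actually holds.

Normalized quantity is the volume divided by the summed volume of all
accepted (C1 or user-edited) spots in the same gel — not whole-image
intensity — so quantities sum to 1 and loading/exposure differences
cancel. Unmatched spots stay in the denominator (normalization is a
per-gel notion; matching is downstream).

The signed fold change of a paired spot is `q1/q2` when the first gel
is higher, `−q2/q1` otherwise, so `|FC| >= 1` always; equal quantities
return `+1` by convention (the signed scheme has no natural zero). A
spot is called *changed* when `|FC|` strictly exceeds the threshold
(default 2 — single-pair 2DE comparisons carry biological and technical
variance that a smaller ratio cannot beat; the strict inequality makes
the boundary case unchanged). Within a spot group (one protein spread
over isoforms of different pI), each spot's share is its percentage of
the group total, summing to 100.

## Numerical choices and degenerate inputs

* Interpolation nodes are exact (calibration, TPS at `lambda = 0`).
* The watershed tie-break (index ramp) is the only arbitrary choice in
  segmentation; it is deterministic and documented.
* `fold_change` refuses nonpositive quantities: a spot absent from one
  gel is reported "present-only", never as a number.
* Empty spot lists, empty matches, single-member groups, identity
  crops, and single-gel pipelines all take defined paths (tested).
* `distortion_profile` raises a diagnostic error when no horizontal
  contours are found rather than silently scoring 0.

## Problem sizes

The validation suite runs entirely on generated data: 192 x 256 px
gels with 20 well-separated spots (detection, registration,
quantification), 320 x 320 px pure-noise gels (false-positive rate),
64 x 64 px instances for the watershed oracle, and 500 labeled patches
per class for classifier training and held-out evaluation. These sizes
exercise every code path at full fidelity; nothing in the method is
size-dependent beyond linear-to-FFT filtering costs, and the CLI
handles full 300 dpi scans with the same code.

## Known limitations

* Horizontal (pI-axis) distortion is not corrected; only the vertical
  molecular-mass distortion family is modeled, scored and straightened.
* The classifier is trained on synthetic regions; on real scans its
  calibration (not its architecture) should be revisited, and the
  uncertain-region review loop is the intended safety net.
* Groupwise (>2 gels) simultaneous registration is out of scope; each
  gel registers pairwise onto the master.
* Optical-density calibration via a scanner step tablet is not applied:
  no transfer curve is available, so intensity is treated as
  proportional to absorbance. All downstream quantities are ratios, so
  a monotone mis-calibration cancels only approximately.
* Saturated spots violate the Gaussian-pit volume model; the generator
  does not produce them and the quantifier does not correct for them.
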