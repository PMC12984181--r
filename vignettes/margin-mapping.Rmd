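---
title: "Co-localized margin mapping: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-localized margin mapping: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Basal cell carcinoma (BCC) is excised with staged micrographic surgery when
margins matter; each stage costs time, tissue and patient burden.
Line-field confocal optical coherence tomography (LC-OCT) can resolve BCC
lobules at cellular resolution in vivo, but its field of view is tiny —
a 1.2 mm scan line seen through a 2.6 mm circular surface image — so the
examiner needs to know, at all times, *where on the lesion* the probe is.
`bccmap` implements the computational side of that workflow: it registers
each probe surface frame into a wide-field contact dermoscopy image (13.3 ×
8.9 mm), gates each localization by its confidence, bridges registration
dropouts with inter-frame dead reckoning, stitches dermoscopic mosaics for
lesions larger than one field, colors the recorded probe trajectory by a
per-frame BCC probability score, and reports how completely each clock
quadrant of the marked excision margin was imaged.

Everything is testable without clinical data: a phantom module synthesizes
dermoscopy-like textures, probe streams with known poses, and B-scan-like
frames whose statistics encode a known spatial probability field.

## Coordinate conventions

One set of conventions is used everywhere:

* pixels are 0-based, origin at the **center of the top-left pixel**,
  x rightward, y downward; image `[y + 1, x + 1]` in R's matrix indexing;
* angles are measured counter-clockwise in that (y-down) frame;
* a rigid pose maps source px to destination px as
  $x' = R(\theta)\,x + t$, $R = \begin{pmatrix}\cos\theta & -\sin\theta\\
  \sin\theta & \cos\theta\end{pmatrix}$;
* physical coordinates place the FOV origin at the top-left, with
  pixel pitch = FOV / pixel count per axis, so `(0,0)` mm is the center of
  pixel `(0,0)` and the FOV center maps to `shape / 2` px (the two stated
  anchor examples are jointly inconsistent by half a pixel; this is the
  convention we fixed);
* clock angles for quadrants are measured from the lesion center with
  12 o'clock along $-y$ and **clockwise** positive, partitioning the margin
  into 12–3, 3–6, 6–9, 9–12 arcs (inked black, red, green, purple).

## Registration model

The pose model is rotation + translation only — a handheld probe pressed on
skin cannot scale or mirror the scene. Because the model has no scale term,
images of different pixel pitch are first resampled (bicubic) to a common
µm/px using the known calibration ratio (`scale_factor()`); for the default
device constants the surface image (6.5 µm/px) is brought to the dermoscope
pitch (≈2.4 µm/px).

Per frame:

1. **Keypoints.** A difference-of-Gaussian scale-space pyramid
   (σ₀ = 1.6, 3 scales/octave) with 3-D subpixel refinement, contrast and
   edge-response rejection, dominant-orientation assignment from a smoothed
   36-bin gradient histogram, and 4×4×8 = 128-dimensional gradient-histogram
   descriptors (normalize → clip 0.2 → renormalize). Detection runs on
   Rec. 601 luminance; surface frames are masked to their inscribed circle
   and detections riding the mask boundary are discarded.
2. **Matching.** Plain one-way nearest neighbor by Euclidean descriptor
   distance, ties broken by lowest reference index. No ratio test — the
   device algorithm matches every descriptor and lets the robust estimator
   sort them out. A symmetric cross-check exists behind
   `match_cross_check`, default off.
3. **RANSAC.** Minimal samples of two point pairs give a hypothesis
   ($\theta$ from the angle between the pair difference vectors, $t$ in
   closed form); 2000 seeded hypotheses; inliers are matches with residual
   < 3 px at reference scale. The best hypothesis is refined by the
   closed-form least-squares rotation + translation (2-D Procrustes,
   atan2 of cross/dot sums — reflection excluded by construction), inliers
   re-selected, and refined once more.
4. **Gate.** The localization is accepted only when the final inlier count
   is **strictly above 6** (i.e. ≥ 7). "Exactly 6" is rejected: of the two
   sentences defining the device threshold, "above 6 … reliable" is the
   stronger and is the one implemented.

Failures that would kill a live stream (blank frame, no matches, degenerate
geometry) become rejected results, never exceptions.

## Tracking fallback

`step_tracker()` runs a three-state machine:

* **LOCKED** — global registration accepted; its pose is emitted; all
  accumulated inter-frame drift is discarded.
* **COASTING** — registration rejected but inter-frame motion (same
  keypoint machinery between consecutive raw frames) is confident:
  confidence is the inter-frame inlier count with the same strict > 6 gate,
  one reliability semantics for both gates. The emitted pose is
  $P_\mathrm{lock}\circ \mathrm{conj}_s(D_k\circ\cdots\circ D_1)^{-1}$,
  deltas accumulated oldest-first and conjugated by the surface→reference
  scale $s$ (rotation unchanged, translation scaled).
* **LOST** — confidence collapsed too, or coasting exceeded 25 consecutive
  frames (an explicit cap on unobservable drift; the device behavior beyond
  "temporal tracking is reset" is unspecified). The last reliable pose is
  cleared; only a fresh registration can re-lock, and re-locking snaps to
  the registered pose with no blending.

## Mosaicking

Each new dermoscopic frame registers against the **current composite**
(matching the device description of stitching to the previously recombined
images), not pairwise against the previous frame; there is no global bundle
adjustment. Accepted frames are blended with linear distance-to-edge
feathering into weighted accumulators; the canvas is the union bounding box
of the transformed frame rectangles, and poses are stored in first-frame
coordinates. Composite keypoints are recomputed after each insertion —
simpler than incremental updates and exact. The cap is 40 frames;
insertion 41 raises `bccmap_mosaic_full`. A live frame can be positioned
against the composite at any time; the reported overlap fraction of its
FOV with already-covered canvas is operator guidance, not a gate — the
only admission criterion is the inlier gate itself.

## Scoring, heatmaps, colormap

The clinical device scores each vertical LC-OCT frame with a proprietary
neural model; that model is deliberately out of scope. The scorer here is a
*contract* — any pure function from a grayscale region to a percent in
[0, 100] — with a deterministic reference implementation,
`reference_density_scorer()`: 100 × the fraction of pixels in a sub-surface
row band (15–85 % of the height) at or above an intensity cutoff (0.5).
The synthetic B-scan generator calibrates exactly that statistic against
the phantom's ground-truth field, which is what makes end-to-end color
checks possible.

Heatmaps apply the scorer to a sliding patch grid (128 px patches, 64 px
stride by default — chosen to tile the 2048-px-wide vertical raster with
2× overlap; both configurable), suppress patches below the 50 % retention
threshold (the device threshold value is unpublished; 50 % is the package
default), and color every retained patch by the **global** frame score —
literally as described for the device, where a 78 %-score frame shows its
retained patches in yellowish tones. Per-patch coloring exists as a
diagnostic flag. Thresholding acts on patch scores, not on any
model-internal activation.

The colormap is linear in RGB from pure blue (0, 0, 255) at 0 % to pure
yellow (255, 255, 0) at 100 %, endpoints exact, out-of-range clipped.
Only the endpoints are specified anywhere, so the simplest interpolation
space (linear RGB) is used and documented; R and G rise monotonically with
the score while B falls, which the tests assert.

## Margin mapping

Samples (pose + marker geometry + score) are appended in acquisition
order; frames with no effective pose are skipped with a warning. The
marker is a line segment (vertical scans: the 1.2 mm scan line through the
FOV center) or a rectangle (horizontal/3-D). Rendering strokes each marker
in its score color; consecutive samples closer than two FOV radii are
joined by short segments with linearly interpolated color (larger jumps are
left unconnected rather than inventing coverage); coasting samples are
dashed, with the dash phase anchored at the segment center so a marker's
centroid always carries its exact score color; the newest sample gets the
FOV circle and an orientation arrow whose shaft starts off-center for the
same reason. Revisited positions simply draw later over earlier.

`coverage_report()` densifies the closed margin polyline (sample spacing
≈ tolerance/5), assigns each point a clock quadrant, and marks it covered
when within `gap_tol_mm` of any recorded marker segment; per-quadrant
coverage is the covered arc-length fraction and maximal uncovered runs are
reported as gaps (merged across the 12 o'clock wrap).

## The phantom generator

What it emulates: a dermoscopy-like RGB texture (multi-octave band-pass
noise plus scattered darker elliptical blobs as a pigment-network proxy —
enough structure for a dense, stable keypoint field), four colored ink
arcs on the margin circle, a radially sigmoid probability field
$p(r) = \mathrm{plateau}\cdot\sigma\!\big((\mathrm{edge}-r)/\mathrm{slope}\big)$
(plateau at the center, exactly half the plateau at the edge radius, with
an optional angular lobe to make only some quadrants positive), simulated
probe streams (bicubic resampling through ground-truth poses at surface
pitch, circular mask, optional Gaussian noise / illumination gain / defocus
blur), and B-scan-like frames (bright entrance line, speckled dermal band,
dark basaloid-lobule ellipses) whose in-band bright-pixel fraction is
calibrated to the local field value.

Default study conditions: a 960 × 642 px canvas spanning the 13.3 × 8.9 mm
dermoscope FOV and 192 px surface frames spanning 2.6 mm, preserving the
clinical pitch ratio at a quarter of the full raster — simulation and
detection at full 5536 × 3692 px would add nothing but time. The margin
circle has radius 3.0 mm around a 0.9 mm lesion (safety distance ≈ 2.1 mm,
within the 2–3 mm marking convention); this is the largest margin sweep
that keeps the whole probe FOV inside a single dermoscopy field, which is
precisely the regime where the single-image workflow applies (larger
lesions are the mosaicking use case). Sweeps of 50 frames (8 for the
cached unit fixture, 40 for the end-to-end acceptance run) cover the full
circle.

What it does **not** emulate — and therefore what green tests do not show
about clinical data: real pigment-network morphology and its descriptor
statistics, specular glints, hair, ink smudging and bleeding, probe
pressure deformation (non-rigid), wet-coupling optics, speckle physics of
real LC-OCT, or any property of the proprietary scorer. Passing tests
demonstrate that the *machinery* is correct under known ground truth, not
that clinical localization accuracy equals the phantom numbers.

## Numerical choices and degenerate inputs

* RANSAC: tolerance 3 px, 2000 iterations, minimal sample 2, seeded PRNG;
  every randomized routine takes an explicit seed and restores the caller's
  RNG state, so identical inputs + seed give bit-identical results.
* Matching ties break to the lowest reference index; RANSAC hypothesis ties
  break to the first-sampled hypothesis.
* Coincident sampled pairs yield no hypothesis; if all are coincident the
  estimator raises `bccmap_degenerate_geometry` (callers in the streaming
  path convert this to a rejected frame).
* Bicubic interpolation is Catmull-Rom (a = −0.5) with clamped borders;
  Gaussian blur uses reflect-101 borders; keypoint counts under a 180°
  flip agree to ~2 % rather than exactly, because the 2× downsampling
  lattice of the pyramid is not flip-invariant on even-sized images.
* The gate comparison is strict (`>`), integer, and shared between global
  and inter-frame reliability.
* Session JSON is written at 17 significant digits and canonicalized
  through one parse so save → load → save is byte-identical.

## Known limitations

* No lens-distortion or non-rigid deformation model; the pose is strictly
  rigid at a fixed scale ratio.
* Mosaics have no loop closure or exposure compensation; long chains drift
  by accumulated registration error.
* The reference scorer is a density statistic, not a lesion classifier;
  it exists to validate the surrounding machinery exactly.
* Coasting error is unobservable while it grows; the 25-frame cap bounds
  duration, not magnitude.
* Detector hyperparameters (contrast 0.03, edge 10, σ₀ 1.6) are exposed in
  the config; the device's actual values are unpublished.
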