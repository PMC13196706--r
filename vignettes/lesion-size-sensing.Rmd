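---
title: "Lesion-size sensing from B-mode stacks of a conformal hyperechoic shell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-size sensing from B-mode stacks of a conformal hyperechoic shell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echowrap)
```

## The sensing problem

A soft microrobotic patch that wraps itself around a protruding lesion can
double as a size sensor: its air-cavity body reflects ultrasound far more
strongly than the surrounding tissue, so in B-mode imaging the wrap appears
as a thin bright (hyperechoic) band conforming to the lesion surface. If a
probe sweeps a series of parallel cross-sections, the band can be segmented
in every slice, lifted into a 3D point cloud, and the radius of the sphere
that locally osculates the wrapped surface becomes a non-invasive proxy for
lesion size. Tracking that curvature radius across imaging sessions turns
the implant into a longitudinal monitor of therapy response.

`echowrap` implements this chain end to end, together with a synthetic
B-mode generator with exact geometric ground truth, so every stage — and the
whole pipeline — is testable without any scanner data.

## The synthetic world

The generator renders a hemispherical lesion of radius $r$ protruding from a
flat tissue plane into the lumen, wrapped by a shell occupying the spherical
annulus $[r,\, r + t]$ above the plane, restricted to a cap fraction
measured from the apex. Each slice samples the scene at pixel centers; a
noise model then applies, in order: Gaussian point-spread blur,
multiplicative mean-one gamma speckle, exponential depth attenuation,
additive Gaussian noise, and clipping to $[0, 1]$. Truth masks are kept
noise-free, and identical `(phantom, geometry, noise)` triples give
bit-identical stacks.

Defaults, fixed once and used by every test:

| parameter | default | why |
|---|---|---|
| pixel pitch | 0.05 mm, 256×256 | high-frequency linear probe resolving 2–3.5 mm lesions |
| slice spacing | 0.25 mm, ≥ 15 slices spanning the wrap | a dense robotic sweep |
| shell thickness $t$ | 0.1 mm | the band B-mode resolves is the reflection at the tissue/air-cavity interface, not the full elastomer substrate; its apparent width is resolution-limited |
| echo levels | lumen 0.05, tissue 0.30, shell 0.90 | strong shell/tissue contrast with non-trivial tissue texture |
| speckle scale | 0.30 | point SNR ≈ 3.3, typical of lightly compounded B-mode |
| PSF σ | 0.05 mm | FWHM ≈ 0.12 mm, consistent with the axial resolution of a 15–20 MHz probe |
| attenuation | 0.03 /mm | residual slope after time-gain compensation |
| additive noise σ | 0.02 | electronic noise floor |

A zero-thickness shell still renders: the membrane's half-width is floored
at half a pixel, the discrete analogue of a specular reflector whose
apparent width is set by the imaging resolution.

What the generator does **not** emulate: coherent reverberation and
shadowing behind the air cavity, refraction, curved/fan probe geometries,
probe-pressure deformation, the microneedle arms of the physical device
(below the default resolution), and slice-to-slice registration error — the
robotic sweep is assumed rigid. A green recovery test therefore establishes
correctness of the *reconstruction and estimation chain*, not robustness to
every artifact of real scans.

## Segmentation

Each slice is denoised with a **hybrid median** (the median of the
plus-window median, the X-window median and the center pixel). The plain
square median would erase the one-pixel band of a resolution-limited thin
shell — on noise-free zero-thickness renders it deletes entire central
slices — while the hybrid variant removes speckle impulses and preserves
thin bright lines.

Thresholding raw intensities cannot work here: the band is roughly 0.4% of
a slice, so any global histogram split — two- or three-class Otsu, a fixed
quantile — lands inside the large lumen/tissue populations. The slice is
first flattened with a **white top-hat** (grayscale opening with a square
window of half-width 5 px, wider than the band), which suppresses extended
structures and depth-dependent gain while retaining the thin band. The
top-hat response is then thresholded with a three-class Otsu whose decision
rule keeps the bright object: the upper threshold, unless the middle
class's mean is closer to the bright class than to the dim class — the
flattened response of a noise-free shell is itself bimodal (band over tumor
vs. band over lumen), and this rule keeps both halves. A quantile mode is
available as a simpler alternative.

Binary closing (disk, 1 px) bridges speckle gaps, components under 10 px
are dropped, and a final **hyperechoic acceptance test** requires the mask
to be at least `min_contrast = 0.30` brighter (mean intensity) than the
rest of the slice; slices with no shell then correctly return empty masks
instead of their brightest texture.

Extraction for reconstruction defaults to the **centerline** — the ridge of
the Euclidean distance transform — which tracks the band midline and halves
the thickness bias of the radius estimate. The outer boundary and the full
mask are available alternatives. Because the centerline sits at
$r + t/2$, estimates carry a small positive bias (≈ 0.05 mm at the
defaults); a `shell_correction` config entry can subtract a known
half-band, but it is **off by default** so that the reported radius is the
shell-band radius, the quantity the imaging actually resolves.

## Reconstruction and outlier handling

Pixels map to millimetres by one affine convention (0-based `(row, col)`
indices; columns → x, slice axis → y, rows/depth → z), so clouds translate
exactly with the scan origin and every point maps back to a segmented
pixel. The statistical outlier filter drops points whose mean distance to
their `k = 8` nearest neighbours exceeds the global mean by 2 SD, with two
guards: the threshold is floored at twice the median neighbour distance
(regular but inhomogeneous sampling — cap edges, grid corners — must not be
trimmed), and at most 20% of the cloud may be removed.

## Curvature estimation

The global reference is the algebraic (Coope/Kasa) sphere fit: linear least
squares in $(c, r^2 - \lVert c\rVert^2)$, exact on noise-free sphere
samples, with degenerate configurations (fewer than 4 points, coplanarity)
rejected.

The primary estimator is **local PCA curvature**: for each point, the
principal components of its `k`-nearest-neighbour patch give the local
tangent plane and normal; an osculating sphere is fitted with its center
constrained to the normal line (the same linear formulation, two unknowns),
then refined by damped Gauss–Newton on the geometric distance with
backtracking, each step accepted only if the RMS residual drops. The
refinement makes the local fit exact on noise-free spheres regardless of
the PCA normal's sampling error, and inherits rigid-motion invariance and
scale equivariance. Patches with no measurable height above the tangent
plane are flagged flat (infinite radius); local radii above ten times the
cloud's bounding-box diagonal are likewise excluded so tissue remnants
cannot inflate the aggregate. The reported radius is the **median** of the
valid local radii — robust to residual artifacts and to the heavy upper
tail local fits produce on shallow patches.

The neighbourhood default is `k = 150`. At the default sampling anisotropy
(0.05 mm in-plane, 0.25 mm between slices) a 30-point patch spans only
~0.6 mm, whose spherical sagitta (~15 µm) is *below* the half-pixel
quantization noise: local radii are then dominated by noise (measured
median 3.08 mm on a noise-free 3.5 mm phantom, interquartile range
2.2–3.8). A 150-point patch spans about five slices, its sagitta comfortably
exceeds the noise, and the same phantom is recovered to 0.05%. Users
scanning at other resolutions should scale `k` so the patch stays several
slices wide yet well under the cap size.

## Error metric and longitudinal trends

Recovery accuracy is summarised as the arithmetic mean of per-phantom
relative errors $\lvert \hat r - r \rvert / r$, in percent: applied to the
four reference pairs (2.0, 2.13), (2.5, 2.52), (3.0, 3.03), (3.5, 3.42) mm
it gives 2.6% at one decimal, which is the acceptance bound the synthetic
pipeline must meet or beat. (The alternative reading — mean absolute error
over the mean radius — gives 2.4% and is not used.)

Longitudinal series of estimates are reduced to total change, per-interval
deltas, and a direction call with a ±0.1 mm stability band, the scale of
the pipeline's own noise floor; changes within the band are "stable"
rather than over-interpreted.

## Numerical choices and degenerate inputs

* Seeded determinism everywhere: the renderer uses a private RNG stream and
  restores the caller's; the analysis pipeline is RNG-free.
* Empty masks, empty clouds and shell-free stacks are valid states with
  defined behavior (empty results or a "no hyperechoic object" error at
  the pipeline level).
* Sphere-fit degeneracy raises errors rather than returning NaN radii.
* Intensity I/O quantizes to 16-bit PGM; round-trip error is below
  $10^{-5}$ per pixel and propagates to well under 1% in the estimate.
* Ties in the distance-transform ridge keep both plateau pixels, so an
  even-width band contributes its two central rows symmetrically — the
  midline is preserved in expectation.

## Known limitations

* The speckle is spatially white; real B-mode speckle is correlated at the
  resolution-cell scale, which would lower the effective number of
  independent samples and widen the estimate spread somewhat.
* Accuracy below ~2 mm radius degrades as the band circumference shrinks
  relative to the pixel pitch.
* Partial wraps much smaller than ~30% of the hemisphere leave the local
  and global estimators poorly constrained along the missing directions.
* Real scans must be pre-registered (rigid probe path); no slice-to-slice
  registration is attempted.
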