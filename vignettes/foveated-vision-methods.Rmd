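---
title: "Foveated log-polar preprocessing: model, protocols and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foveated log-polar preprocessing: model, protocols and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(FoveatedVision)
```

## The retinotopic model

Foveated visual systems sample the visual field densely at the center of
gaze and coarsely in the periphery, and early visual cortex preserves this
layout as a roughly log-polar map: position is represented by the azimuth
angle around the fixation point and by the *logarithm* of eccentricity.
This package implements that mapping as a fixed, non-learned preprocessing
layer for image classifiers, together with the evaluation machinery that
makes its consequences measurable.

With normalized image coordinates $x, y \in [-1, 1]$ and a fixation point
$(x_0, y_0)$, each sample of the retinotopic raster corresponds to the
Cartesian location

$$(x, y) = (x_0 + \rho\cos\theta,\; y_0 + \rho\sin\theta),$$

where the azimuths $\theta_j = 2\pi j / N_\theta$ are uniform on
$[0, 2\pi)$ and the eccentricities form a geometric progression:
$\log_2\rho$ is uniform on $[\log_2 r_\min, \log_2 r_\max]$. The defaults
are $N_\theta = N_\rho = 224$, $r_\min = 2^{-5}$ and $r_\max = 1$, the
outer ring being tangent to the image box. Pixel values on this irregular
Cartesian grid are obtained by bilinear interpolation.

The geometric spacing is not a detail but the point of the construction:

* a rotation by $\alpha$ about the fixation point becomes a *circular
  column shift* by $\alpha N_\theta / 2\pi$ cells;
* a uniform zoom by $s$ becomes a *row shift* by
  $\log_2(s)\,(N_\rho - 1)/(\log_2 r_\max - \log_2 r_\min)$ cells;
* a translation becomes no shift at all — it deforms the representation
  nonlinearly.

A convolutional network that is (approximately) translation invariant over
the log-polar raster therefore inherits rotation and scale invariance in
image space, at the price of acute sensitivity to the placement of the
fixation point. The package treats both sides of this trade-off as
first-class measurable quantities.

```{r}
cfg <- FoveationConfig()
predictedLogPolarShift("zoom", 2, cfg)       # 44.6 rows, 0 columns
predictedLogPolarShift("rotation", 2 * pi / 224, cfg)
```

## Conventions and numerical choices

* **Coordinates.** $x$ grows rightward with columns, $y$ grows downward
  with rows; pixel centers sit at $((2c+1)/W - 1, (2r+1)/H - 1)$ for
  0-based row $r$ and column $c$. Non-square rasters are supported with
  per-axis normalization (anisotropic pixels).
* **Interpolation.** One bilinear rule is used everywhere (forward and
  inverse transform, rotation, zoom, cropping, resizing): coordinates
  strictly outside $[-1,1]^2$ receive the configured fill value (default
  0); in-frame coordinates are clamped to border pixel centers, so a
  constant image stays exactly constant under any in-frame resampling.
* **Inverse transform.** The azimuth axis is interpolated circularly
  (columns near $2\pi$ blend with columns near 0); radii beyond
  $r_\max$ take the fill value and radii inside $r_\min$ sample the
  innermost ring, so the center of the fovea is not a hole. The mapping is
  undefined exactly at the fixation point, but the grid never contains
  $\rho = 0$ because $\rho_1 = r_\min > 0$.
* **Identity transforms.** `rotateImage(img, 0)`, `zoomImage(img, 1)` and
  zero rolls return their input bit-exactly rather than resampling.
* **Roll translation.** `translateRoll()` quantizes to whole pixels so the
  operation is an exact permutation of pixel values; sub-pixel wraparound
  would blend opposite image edges.
* **Anti-aliasing.** None is applied when the log-polar grid samples finer
  than the source pixels; the foveal rings simply oversample, which is why
  equivariance measurements exclude the innermost rings (below).
* **Tie-breaking.** Every arg-max in the package (attack grids, map peaks,
  IoU thresholds) takes the *first* maximizer in a documented order
  (grid order or row-major), so all results are deterministic.

## Measuring equivariance

`equivarianceError()` compares the log-polar image of a transformed input
with the predicted shift of the log-polar image of the original, as a
Pearson correlation over the jointly valid region. Two practical choices:

* The innermost 5 rings are excluded by default. The fovea maps a handful
  of source pixels onto many grid cells; interpolation error dominates
  there and carries no information about equivariance.
* The outermost ring is excluded as well. With $r_\max = 1$ it lies
  exactly on the frame border, where bilinear samples are clamped to
  border pixel centers; the clamp is frame-aligned, not
  transform-equivariant, and would contribute an artifact unrelated to the
  mapping.
* For zooms, rows whose shifted source falls off the raster are excluded
  (the overlap region); for rotations the column shift is circular and
  every cell is valid.

On band-limited textures (`generateTexture()`) rotation correlations
exceed 0.99 and zoom-by-2 correlations exceed 0.95. The translation
*non*-equivariance is witnessed by brute force: after a half-frame roll,
no integer (row, column) shift of the 32×32 log-polar raster reaches a
correlation of 0.9. Shifts that would leave fewer than 8 overlapping rings
are excluded from that search: correlations over a handful of values are
noise, not evidence of equivariance.

## The worst-case attack protocol

Given a classifier that returns a probability vector, an attack evaluates
a grid of transform parameters, picks — per image — the parameter that
maximizes the cross-entropy loss of the true label, and scores the arg-max
prediction at that worst parameter. Defaults follow the study conditions:
rotation angles from −180° to +180° in 15° steps; zoom factors on the
zoom-out branch only, 11 geometric steps from ×1 to ×0.1 (zoom-in attacks
degenerate to maximal magnification); translation via an 11×11 grid of
fixation points rolled to the frame center. Probabilities are floored at
$10^{-12}$ before the logarithm so confidently wrong classifiers yield
finite losses. Perturbations are always applied in image space *before*
foveation: perturb → foveate → classify.

Classifier inference in the bundled harness processes images strictly one
at a time through identical operations, so batched attack results are
bit-for-bit equal to a scalar loop over the grid — a property the test
suite checks exhaustively.

## The visual-search protocol

For a cued label, `likelihoodMap()` sweeps a linear $G \times G$ grid of
fixation points (default $G = 11$, center cell at the image center). At
each fixation the largest possible sample is cropped: the crop radius is
the distance to the nearest border, floored at a 1:10 ratio, so the
central fixation sees the whole image and border fixations see small
peripheral samples. The crop is resized to the classifier's input
resolution, preprocessed according to the classifier's mode (circular mask
or log-polar transform), and the probability assigned to the cued label is
recorded. The map is a saliency surface; `saccadeAndClassify()` moves the
"eye" to its peak and re-classifies there.

Aggregation across images recenters each map on its peak on a
$(2G-1)\times(2G-1)$ canvas; cells never covered stay undefined and are
excluded from means (not zero-filled). Difference and log-odds-ratio maps
compare two aggregates cellwise, with probabilities clamped to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$.

Localization is scored against ground truth on the same grid: the pointing
game (peak inside the mask; an energy variant reports the fraction of map
mass inside), mean activation inside/outside the mask and their ratio
(reported both as ratio-of-means and mean-of-ratios, since either
convention is found in practice), and IoU curves over a threshold sweep
with their peak. Bounding boxes rasterize to the grid by
fixation-in-box membership (boundary inclusive; a fractional-coverage
variant is available behind a flag), and keypoint annotations become
max-combined Gaussian heat maps with peak 1, $\sigma$ proportional to
object size (factor 0.25 by default), thresholded at 0.2 for the contour
mask after area-averaged downsampling.

## The synthetic-scene module

Real photographic benchmarks are deliberately out of scope; the package
ships a generator that emulates their statistical structure at desk scale
so that every pipeline stage is testable in minutes on one CPU:

* **Scenes.** One bright object per scene — disk, square, cross or ring —
  rendered analytically from signed-distance functions with a one-pixel
  soft edge, on a band-limited noise background (Gaussian noise on a
  coarse 9×9 node grid, interpolated with a normalized Gaussian kernel so
  the texture is smooth everywhere). Bounding boxes are the analytic
  extents of the rendered contour; keypoints are the object's landmarks.
* **Conditions.** Working resolution 64×64 (the 224 configuration remains
  the library default for real use); object half-sizes uniform on
  [0.25, 0.45] of the half-frame, mirroring the proportionally large
  annotation boxes of curated photographic datasets; positions uniform on
  ±0.35 per axis (an optional photographer's-bias knob draws them
  triangularly toward the center, off by default); orientations uniform
  within ±15° of the upright pose. The orientation regularity matters: it
  is what makes a rotation attack an out-of-distribution perturbation, as
  it is for photographs, rather than a resampling of the training
  distribution.
* **Variants.** The `regular` variant is the full frame; the `focus`
  variant recrops each scene to the smallest square containing its
  bounding box (clamped to the frame) and recenters all annotations — the
  object-centered regime that foveated processing favors.

What the generator does **not** emulate: texture detail at multiple
scales, clutter and occlusion, multiple objects, class-dependent context.
Passing tests therefore demonstrate the correctness and the qualitative
behaviour of the protocols, not photographic-scale accuracy numbers.

## The toy classifier harness

No deep-learning framework is involved: the harness is a small
convolutional network written in base R. Architecture: a 7×7, 24-channel,
stride-4 convolution stem and a 5×5, 48-channel, stride-2 convolution,
each followed by ReLU; global average pooling; a linear softmax head.
Convolutions are evaluated by precomputed im2col gathers and one matrix
product per layer. In retinotopic mode the column (azimuth) axis is padded
circularly, matching the periodic topology of the log-polar raster;
padding is zero otherwise. We settled on this two-block shape after a
three-block stride-2 stack proved slow and erratic to optimize with plain
SGD at this scale; the wide stride-4 stem trains reliably in under a
minute per model.

Training uses stochastic gradient descent with momentum 0.9 on the
cross-entropy loss (learning rate 0.08, batch 40, 18 epochs with step
decay to 0.3× and 0.1× of the rate at 60% and 85% of the run; the rate is
higher than typical fine-tuning rates because the net trains from
scratch). Inputs are centered to $[-1, 1]$. Two robustness devices are
part of the harness contract:

* **Background class.** By default an extra `"background"` output class is
  trained on object-free crops taken from the same scenes (border
  fixations whose crop square misses the bounding box). The photographic
  datasets this harness emulates are full of object-free views; without
  them the net assigns confident object labels to featureless patches and
  the likelihood maps develop spurious peaks at small border crops.
* **Deterministic restarts.** Plain SGD from a random initialization
  occasionally lands in a poor basin. If the final training-set accuracy
  falls below 0.9 the harness restarts from a deterministically shifted
  seed (at most twice), keeping the best attempt. Training remains a pure
  function of the seed.

The recipe used by the test battery trains on the regular views once plus
the focus views three times (echoing the practice of fine-tuning on
object-centered crops before the localization study), 300 scenes per
variant, evaluated on 50 held-out scenes.

## What the battery shows

At these conditions the package reproduces, at toy scale, the qualitative
signature of foveated preprocessing. The retinotopic classifier's accuracy
is nearly flat across rotation angles while the Cartesian classifier's
oscillates; under the rolled-fixation protocol the picture inverts, the
Cartesian placement-accuracy map staying broad while the retinotopic one
collapses to a sharp central peak. One caveat discovered at this scale:
the *per-image worst case* over all 121 placements floors at zero for both
modes — a 64×64 shape scene offers no redundancy once the roll wraps the
object across the frame border — so the translation comparison is made on
the placement-averaged accuracy drop, where the ordering is unambiguous.
Likelihood maps recover planted object positions within one grid cell in
at least 90% of held-out scenes for the retinotopic classifier, saccading
to the map peak beats central-fixation classification, and the retinotopic
pointing rate exceeds the Cartesian one.

## Known limitations

* The toy harness is a demonstration instrument: its absolute accuracies
  have no photographic-scale meaning, only the Cartesian/retinotopic
  contrasts do.
* The forward transform has no anti-aliasing; heavily aliased inputs will
  degrade peripheral fidelity faster than the equivariance bounds suggest.
* Only single-saccade selection is implemented; sequential scan-path
  planning is out of scope.
* The inverse transform is a visualization aid, not an exact inverse: the
  periphery is reconstructed from far fewer samples than it had pixels.
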