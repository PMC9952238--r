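---
title: "Simulating tagged cardiac MR from cine images: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tagged cardiac MR from cine images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cine2tag)
```

## Why simulate tagged images

Myocardial tagging imprints a dark grid of saturated longitudinal
magnetization on the heart; the grid deforms with the muscle and encodes
strain. Tagged images are, however, rarely annotated, while cine
(bSSFP) images come with large public expert-labelled datasets. If a
transformation turns a cine image into a tagged-appearing one *without
moving any anatomy*, the cine segmentation mask remains valid for the
transformed image, and annotated pseudo-tagged training data can be
produced at scale. `cine2tag` implements such a transformation from MR
physics, together with the boundary-aware loss and the evaluation
metrics one would use to train and assess a segmentation model on the
resulting data.

## The physics-driven transformation

The transformation has two independent parts.

**Contrast conversion.** Cine bSSFP contrast (very bright blood) is
converted toward gradient-echo contrast by an element-wise square root
of the min-max-normalized image. This is a gross but monotone
approximation: it compresses bright blood toward the myocardium while
fixing the endpoints 0 and 1.

**Tagging preparation.** A SPAMM preparation is a train of RF sub-pulses
interleaved with gradient lobes. We simulate it with the Bloch equations
in the rotating frame, neglecting relaxation during the (few-ms)
preparation. For a pixel at position $u$ along the tagging axis the
gradient advances the phase by $\psi = 2\pi u / s$ between consecutive
sub-pulses, where $s$ is the tag spacing in pixels. Starting from
$M = (0,0,1)$, the simulation alternates a rotation about the x-axis by
$w_i/\sum w \cdot \alpha$ (sub-pulse $i$ of total flip $\alpha$) with a
rotation about z by $\psi$; after the train the transverse components
are spoiled and the surviving $M_z(\psi)$ is the tag profile. Two
closed forms anchor the implementation: at $\psi = 0$ all sub-rotations
add coherently, so $M_z = \cos\alpha$ for *any* positive weight vector;
and the two-pulse equal-weight preparation at $90^\circ$ gives
$M_z(\psi) = (1 - \cos\psi)/2$. Both are verified to $10^{-9}$ in the
test suite against an independent explicit rotation-matrix composition.

Defaults follow the clinical-looking regime: **1-3-3-1** binomial
weights, **5-px** tag spacing, **70°** total flip (chosen to mimic
somewhat faded tag lines), and a **45°** grid rotation. The source
material leaves the grid construction and rotation angle open; we chose
two sequential orthogonal 1D preparations with spoiling in between,
whose profiles multiply into the grid, and 45° as the typical clinical
grid-tag orientation. Both are configurable (`tag_config`).

**Composition.** Magnitude imaging renders saturated magnetization as
dark lines, so the tagged image is the sqrt-contrast image multiplied by
$|M_z|$, renormalized to $[0,1]$. The composition rule is a package
choice (the source describes contrast modification and tag addition but
not the algebra). Pixel (1,1) is a phase-zero point, tying the grid to
a reproducible origin.

**Fading.** Tag contrast decays with longitudinal relaxation,
$M_z(t) = 1 + (M_z(0)-1)e^{-t/T_1}$, with $t$ the frame index times the
frame interval. Because the transformation's stated limitation is that
tag lines do *not* evolve with acquisition time, fading is **off by
default**; when enabled it uses placeholder defaults $T_1 = 850$ ms and
40 ms per frame (a nominal 1.5 T myocardium and cine temporal
resolution), both exposed in the config because the original contrast
dynamics parameters are not published.

**Mask transfer.** `transform_cine_to_tagged` returns the input mask
bit-identical. This is the property that makes the whole exercise
useful, and it is asserted, not assumed, in the tests.

**Degenerate images.** Min-max normalization of a constant image is
ill-defined; we clip constants to $[0,1]$ and pass them through rather
than collapsing them to zero, so a uniform bright image still shows the
tag grid — which is also how the tag-period check on a uniform image is
possible at all.

## The boundary-aware shape loss

With $H(x) = 1/(1+e^{-x/k})$ and $\phi$ a signed normalized Euclidean
distance map, the shape information of a binary mask $m$ is

$$SI(m) = \begin{cases} H(1-\phi(m)) & \phi(m) \ge 0 \\ 0 & \text{otherwise,}\end{cases}$$

and the loss averages the normalized absolute difference to the soft
prediction over channels:

$$L_S(g,p) = \frac{1}{C}\sum_c \frac{1}{\sum_i g_{ci}} \sum_{i\in\Omega} |p_{ci} - SI(g_c)_i|.$$

Conventions the source leaves open, fixed here:

- **Sign of $\phi$: positive on the foreground.** Only this convention
  makes $SI$ a boundary-peaked interior map (near $H(1)\approx0.993$ at
  the boundary for $k=0.2$, decaying to $H(0)=0.5$ deep inside, zero
  outside), consistent with a loss that emphasizes ground-truth
  boundaries.
- **Normalization of $\phi$:** per channel, by the maximum absolute raw
  distance over the image, giving range $[-1,1]$ exactly.
- **Pixel-centre distances:** a foreground pixel adjacent to background
  has raw distance 1; sub-pixel boundary geometry is not modelled.
- **Integrals over $\Omega$** are pixel sums.
- The Dice term is soft Dice over pixel sums with smoothing
  $\varepsilon = 10^{-6}$; cross-entropy uses only the printed
  $g\log p$ term (no $(1-g)\log(1-p)$ complement), with $p$ clamped to
  $[\varepsilon, 1]$.

The combined objective is $L = (1 - \text{Dice term}) + CE + \gamma L_S$
with defaults $k = 0.2$ and $\gamma = 0.05$ (the empirically optimal
shape-loss weight). The losses are evaluable functions; no training
loop or gradients are provided.

The distance transform itself is the exact two-pass Felzenszwalb–
Huttenlocher algorithm; its oracle in the tests is an exhaustive
all-pairs distance computation on random small masks ($10^{-9}$
agreement).

## Evaluation metrics

Dice is $2|G\cap P| / (|G|+|P|)$; by convention two empty masks score 1
and exactly one empty mask scores 0. HD-95 is
$\max(d_{0.95}(X,Y), d_{0.95}(Y,X))$ where $d_q$ is the $q$-quantile
over one contour of nearest-neighbour distances to the other, in mm.
Open details fixed here: contours are foreground pixels with a
4-connected background neighbour (the image border counts as
background); the quantile estimator is linear interpolation between
order statistics (R type 7), so $q=1$ recovers the directed Hausdorff
maximum; empty-mask pairs yield `NA` HD-95 and are excluded from
aggregates with a warning rather than scored 0; anisotropic pixel
spacing `(row_mm, col_mm)` is supported, and spacing must be given
explicitly — there is no safe default for clinical data.

## The phantom: a stated world

The phantom generates what the rest of the package assumes: a 25-frame
short-axis cine of a contracting annulus with bSSFP-like contrast
ordering. Defaults are fixed once and not tuned: 256-px frames, 30/45 px
end-diastolic endo/epicardial radii (a plausible adult LV at ~1.4 mm/px),
intensities 0.9/0.5/0.1 for blood/myocardium/background, Gaussian noise
sd 0.02, 25 frames, peak radial contraction 25% — mid-range for a
healthy ventricle. The contraction law
$r(t) = r_{ED}\,(1 - c\,\sin^2(\pi t/(T-1)))$ is any smooth
ED→ES→ED curve; it was chosen for testability, not physiological
fidelity. Masks are hard-thresholded at pixel centres so mask
invariants are exactly checkable; image edges may optionally be
softened. What a green test on phantom data does **not** establish:
realism of torso anatomy, papillary muscles, through-plane motion, MR
noise statistics, or the contrast diversity of multi-vendor clinical
data.

## Augmentation and preprocessing

Preprocessing is a bilinear resize to 256×256 (half-pixel aligned;
identity at 256×256; borders replicated) followed by
$(x - 0.456)/0.224$. The augmentation stack applies, in the fixed order
flips → noise → blur → affine → elastic, each transform with its own
probability (defaults 0.5; magnitudes are package choices since none
are published). Geometric transforms use bilinear interpolation for
images and nearest-neighbour for masks, which therefore stay binary;
displacement fields are shared between image and mask. All randomness
derives from `(seed, draw_index)` through a private RNG stream that
leaves the caller's RNG state untouched, making every draw reproducible
bit-exactly.

## Numerical and interface choices

- NIfTI-1 support is a minimal purpose-built reader/writer (uncompressed
  `.nii` and gzipped `.nii.gz`; datatypes uint8/int16/int32/float32/
  float64; endianness detected; slope/intercept scaling applied on
  read), because no NIfTI package is available in the target R stack.
  ACDC layout (`<id>.nii` + `<id>_gt.nii`, myocardium label 2) is the
  reference dialect; PNG pairs (`<id>.png` + `<id>_mask.png`) are the
  fallback.
- The tag-period measurement samples a bilinear profile along the
  grid-normal direction and reports the first off-origin maximum of its
  autocorrelation — robust to interpolation and noise, integer-valued
  by construction.
- Dataset runs are deterministic: identical configurations rewrite
  bit-identical files, and the manifest stamps a hash of the transform
  parameters.

## Known limitations

Tag lines do not deform with myocardial motion (the transformation is
static per frame by design); no k-space/readout simulation, slice
profile, or through-plane motion; the square-root contrast conversion
leaves blood/lung contrast less realistic than a learned style
transfer; metrics are 2D per-slice, not volumetric.
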