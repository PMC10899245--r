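---
title: "Kidney ultrasound morphometry with renalus: models, measurements, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kidney ultrasound morphometry with renalus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(renalus)
```

## The problem

Kidney length, width, thickness, parenchymal thickness, and volume are
routine clinical biomarkers: a shrunken kidney or thinned parenchyma flags
chronic disease, an enlarged one polycystic disease or cardiovascular risk.
Ultrasound is the modality of choice for measuring them, but manual caliper
placement is operator-dependent. `renalus` implements a fully automated
pipeline: a convolutional network segments the kidney capsule (and sinus) in
2-D sagittal and axial scans, and deterministic geometric post-processing
converts the masks into the five biomarkers.

The package is organised so that every stage is verifiable at desk scale: a
synthetic phantom generator produces images and masks whose biomarkers are
known analytically, and every geometric primitive has an independent
brute-force oracle in the test suite.

## The segmentation network

The architecture is a nested U-Net that replaces every resolution change
with a learned convolution:

* **Encoder.** A full-resolution stem (5x5 convolution, stride 1) followed
  by strided 5x5 convolutions (stride 2) — one per level — so the network
  contains *no pooling layers*. Each encoder block is convolution, batch
  normalization, leaky ReLU (negative slope 0.2).
* **Nested decoder grid.** Node $X_{i,j}$ (level $i$, column $j \ge 1$)
  up-convolves $X_{i+1,j-1}$ with a stride-2 transposed convolution, applies
  ReLU and batch normalization, concatenates its same-level inputs, and
  fuses channels with a 1x1 convolution + ReLU. Column-1 nodes have two
  inputs (the encoder feature plus the upsampled deeper feature); later
  columns have three (upsampled deeper node, previous same-level node,
  encoder feature).
* **Deep supervision.** All full-resolution nodes $X_{0,1..J}$ are
  concatenated and fused by a 1x1 convolution and a sigmoid into a
  single-channel probability map the size of the input.
* **Plain baseline.** With `nested = FALSE` the model reduces to the
  encoder plus a transposed-convolution decoder with batch normalization,
  ReLU, dropout (0.5), and skip concatenations.

Two merge details are not fixed by the architecture's public description and
are therefore package design choices, recorded here: (1) multi-input nested
nodes merge by channel concatenation followed by a 1x1 convolution — the
cheapest learnable fusion that keeps per-node channel counts constant; (2)
deep supervision fuses by concatenation + 1x1 convolution + sigmoid.

### Channel widths and the FLOPs budget

The per-layer cost of a convolution is counted analytically as
$\mathrm{FLOPs} = 2K^2 C_{in} C_{out} N$ with $N$ the number of *output*
spatial positions (a multiply-accumulate is two operations). The default
depth-5 configuration doubles filters per level from a base width; the base
width (9, giving 9/18/36/72/144) was calibrated once so the analytic total
at 320x480x1 lands on the architecture's nominal budget of roughly
$1.5\times10^{10}$ FLOPs, and is frozen:

```{r flops}
fr <- count_flops(network_config())
fr$total
```

Whether $N$ should count input or output positions is ambiguous in the
formula's usual statement; output positions is the standard convention and
is what `count_flops()` uses for both plain and transposed convolutions.

### Training

Training follows the reference recipe: Adam, batch size 32, at most 47
epochs, learning rate 1e-4 (the printed form "10e-4" is read as the
conventional 1e-4), weights drawn from $N(0, 0.02^2)$, soft Dice loss by
default (model selection is by validation Dice, so the loss matches the
selection metric; binary cross-entropy is available). One "step" is one pass
over the training split; the best-validation-Dice weights are checkpointed
and restored. All randomness (split, shuffling, dropout) flows through one
seed, so runs are bit-reproducible.

The package trains networks on the CPU through its own im2col/GEMM
convolution kernels, so desk-scale verification uses a scaled-down problem:
64x64 phantoms, depth 3, filters 4/8/16, kernel 3, learning rate 1e-3,
batch 16, 30 epochs, 200 image/mask pairs. Under these conditions the
nested model reaches validation Dice above 0.95 in about two minutes per
seed; the test suite asserts a mean of at least 0.9 over three seeds. This
demonstrates that the architecture and optimizer are wired correctly; it
says nothing about performance on clinical images, which require the full
configuration and a real dataset.

### Inference post-processing

Probability maps are thresholded at 0.5; the largest 8-connected component
is kept and interior holes are filled, since a kidney capsule is a single
simply connected region. Images of any size are resized bilinearly to the
network frame and the probability map is mapped back, so masks and
measurements are reported in the original frame.

## Mask-to-biomarker measurement

All distances are Euclidean between pixel centres, scaled by the isotropic
pixel spacing (mm/pixel); angles are degrees counterclockwise on screen.

**Sagittal chain.** Kidney length (KL) is the farthest pair of capsule
contour points, found by exhaustive $O(n^2)$ search over the contour —
contours hold a few thousand points at most, so no rotating-calipers
optimization is needed and the result is exactly checkable against a
brute-force oracle. The KL line's angle rotates the mask to horizontal
(canvas enlarged, nearest-neighbour for masks, bilinear for images, exact
affine record kept for inversion). Kidney thickness (KT) is the vertical
span at the topmost point's column: topmost foreground pixel (ties to the
smallest column) paired with the downmost pixel in the same column — the
figure evidence shows a vertical caliper, which is why "corresponding
downmost" is read as same-column rather than global-bottom. Parenchymal
thickness takes the capsule's upper contour (per-column minimum-row contour
pixel) against the sinus contour; the default `maxmin` strategy returns the
pair maximizing the *nearest*-sinus distance, i.e. the thickest stretch of
tissue. A literal `maxmax` (farthest pair between the contours) is kept
behind a flag: it measures a diameter-like quantity, not a tissue
thickness, and always dominates `maxmin`.

**Axial chain.** The orientation comes from PCA on the foreground pixel
coordinates; the dominant eigenvector's angle (mapped to $(-90, 90]$)
rotates the mask horizontal. Near-isotropic masks (eigenvalue ratio below
1.05) get angle 0 and a warning. The hilum side is detected by scanning
columns inward from both ends for the first vertical line crossing the
contour at four or more points — the concavity signature of the hilum
notch; detection is overridable. Axial kidney thickness runs from the
middle of that first four-intersection column (mean contour row) to the
extreme pixel on the opposite side (ties to the median row). Kidney width
splits the contour into upper and lower chains at the leftmost and
rightmost contour points and maximizes, over upper points, the distance to
the *nearest* lower point. All landmarks are mapped back to the original
frame through the exact inverse rotation.

One documented discrepancy: the textual description of the axial
nearest-pair maximum calls it a thickness while the accompanying figure
labels it the kidney width; the package adopts the figure's label (KW),
since the major-axis measurement already provides the axial thickness. A
consequence worth knowing: for the nearest-pair rule to recover an
ellipse's minor diameter $2b$ exactly, the cross-section must be elongated
enough ($a \ge \sqrt{3}\,b$, otherwise the nearest point to the top of the
ellipse is a pole rather than the bottom); the axial phantom generator
stays inside that regime.

**Volume.** The ellipsoid approximation $V = KL \times KW \times KT \times
0.523$ (0.523 being $\pi/6$ to three decimals) with KL and KT from the
sagittal view and KW from the axial view; lengths are in mm and the product
is divided by 1000 to report millilitres:

```{r volume}
kidney_volume(10, 10, 10)   # ml, the coefficient itself
```

## The phantom generator

Phantoms stand in for clinical data everywhere in the package's tests. A
phantom is an ellipse capsule (semi-axes in pixels, arbitrary rotation)
with, for sagittal views, a sinus that is the capsule scaled by
`sinus_scale` about the centre, and for axial views a circular hilum notch
of radius `hilum_notch_depth` times the semi-minor axis carved from one end
of the major axis. The image is a smooth three-level template (background
0.12, parenchyma 0.45, sinus 0.8, Gaussian-smoothed) multiplied by a
speckle-like field: two low-pass-filtered Gaussian fields, squared and
summed (Rayleigh-like), standardized to mean 1 and standard deviation
`speckle_sigma`, floored at 0.05. The noise is strictly multiplicative:
`speckle_sigma = 0` reproduces the template bit-exactly. The exact noise
law of clinical speckle is not modelled — no beamforming, attenuation,
shadowing, or pathology — so passing tests certify the geometry and the
learning machinery, not clinical robustness.

Ground truth is computed from the generating geometry, never from the
rasterized mask: KL $= 2a$, sagittal KT $= 2b$, KW $= 2b_{ax}$, parenchymal
thickness $= a(1 - s)$ (the max-min distance is attained at the poles), and
axial KT $= 2a - u^*$ where $u^*$ solves ellipse-half-height =
notch-half-height — the analytic onset of the notch's two-arm signature.
Rasterization uses a coverage convention (a pixel is foreground when its
unit square overlaps the continuous region, approximated by a half-pixel
dilation), which keeps pixel-centre distances aligned with the continuous
geometry instead of systematically half a pixel short on each side.

Default study conditions were chosen once as plausible adult values:
320x480 images, spacing uniform in 0.23–0.36 mm/pixel, kidney length
95–120 mm, sagittal thickness 38–52 mm, sinus scale 0.5–0.62, speckle 0.15,
rotations up to ±30°. Axial cross-sections use width fractions 0.42–0.52 of
the thickness so that the width rule's elongation condition above holds;
this is the one place where measurability, not anatomy, dictated the range.

`generate_phantom_study()` draws one kidney and emits geometrically
consistent sagittal and axial views (the sagittal minor axis and the axial
notch-to-pole distance both equal the drawn thickness), giving each study a
single analytic volume for end-to-end checks:

```{r study}
st <- generate_phantom_study(seed = 1)
st$truth
```

## Numerical choices and degenerate inputs

* Distances between pixel centres; 1-based (row, col) coordinates; spacing
  isotropic.
* Rotation canvases are enlarged so nothing clips; transform records invert
  exactly (round-trip error below 0.5 px).
* Single-pixel or single-row masks yield zero-length measurements with a
  degeneracy warning rather than errors; empty masks error.
* Two empty masks compare as Dice 1 with a warning so a blank fold cannot
  crash an evaluation sweep.
* Ties: topmost point ties break to the smallest column; extreme-point ties
  to the median row; grid-search ties to the first combination in
  `expand.grid` order.
* The biomarker agreement evaluator (accuracy/AUC/sensitivity/specificity/
  precision/F1 against a reference modality) requires binarizing continuous
  agreement; no canonical construction exists for the tables it mirrors, so
  the package's construction — relative error vs a tolerance (default 10%),
  reference labels all-positive unless supplied, rank AUC when both classes
  exist and the sensitivity-sweep area otherwise — is explicitly
  non-canonical and configurable.

## Known limitations

* The phantom is an ellipse, not a bean: no cortical lobulation, cysts, or
  tumours; self-consistency results bound discretization error only.
* A sagittal-view kidney width is not implemented: the axial view is the
  width's only defined source here; volume therefore needs both views.
* CPU training at full 320x480 scale is impractical; the default
  configuration is exercised analytically (FLOPs, shapes, parameter counts)
  and the learning dynamics at 64x64.
* `biomarker_agreement` reproduces the *form* of a CT-agreement evaluation,
  not any published operating point.
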