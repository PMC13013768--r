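---
title: "Specular-reflection augmentation for colonoscopy CADx: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specular-reflection augmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(specaug)
```

## Motivation and model

Specular reflections (SR) are saturated highlights created where the
endoscope's light reflects off wet mucosa. For optical diagnosis of colon
polyps — distinguishing adenomatous (AD) from hyperplastic (HP) lesions on
narrow-band imaging — these artifacts overlay exactly the surface and
vascular patterns that carry the diagnostic signal. Rather than discarding
SR-laden frames, this package manipulates the SR content directly, in both
directions, as a data-augmentation strategy:

* **SR generation** plants realistic new highlights, teaching a classifier
  that the same lesion can appear under many reflection patterns;
* **SR inpainting** removes existing highlights and reconstructs the
  occluded tissue, producing a second, artifact-reduced view of each image.

Both routes share one primitive, the binary SR mask

$$M_S = \{(x, y) : Y(x, y) > 245\}, \qquad
  Y = \mathrm{round}(0.299R + 0.587G + 0.114B),$$

a strict luma threshold. The threshold is deliberately simple; no
morphological area or shape filtering is applied by default, so fragmented
bright pixels that are not true SR can enter the mask. This is a known
limitation of threshold-based extraction; an optional minimum-area filter
(`filter_mask_area()`) is shipped but off by default so that default
behaviour remains the plain thresholding rule.

### SR generation

Given a donor image with mask $M_S$:

1. **Refinement.** The 0/1 mask is blurred with two Gaussians
   (`refine_mask()`): a fixed `k1 = 5` kernel whose sigma follows the
   standard size-to-sigma rule $\sigma = 0.3((k-1)/2 - 1) + 0.8$, producing
   the *highlight* soft mask; and a kernel auto-sized from `sigma2`
   (default 3.0, width = nearest odd integer $\ge 6\sigma + 1$),
   producing the *halo* soft mask. The "kernel size 0" convention — derive
   the size from sigma — is how the halo filter is specified. Neither sigma
   is canonical; both are configuration parameters.
2. **Diversity.** One rigid transform (rotation in {0°, 90°, 180°, 270°},
   horizontal/vertical flips each with probability ½) is applied
   consistently to both soft masks and the binary mask. Rotations are
   restricted to grid-exact multiples of 90° so the mask geometry is
   conserved; free-angle rotation of masks would require resampling and
   blur the planted ground truth.
3. **Colour.** The halo carries the donor's mean RGB colour over $M_S$,
   perturbed per channel by an integer from
   $\{-\delta, \dots, +\delta\}$ (default $\delta = 10$), emulating the
   colour blotches observed around real SR. The highlight layer is pure
   saturation (255): extracted SR cores are near-saturated by construction,
   so perturbation belongs on the halo, not the core.
4. **Compositing.** Two alpha blends, halo first, highlight second:
   $$I' = (1 - h)\,\bigl[(1 - g)\,I + g\,c\bigr] + h \cdot 255,$$
   with $g$ the halo weight, $h$ the highlight weight, $c$ the perturbed
   halo colour. The layer order — colour spreading below, smooth highlight
   on top — realises "smooth highlights with localised colour spreading";
   blending with soft masks avoids hard seams that a binary paste would
   leave. Where both weights are zero the target pixel is bit-identical,
   which the tests assert exactly.

Donors are drawn uniformly from same-class samples whose mask area fraction
exceeds `min_mask_fraction` (default 0.001); a target with no eligible
donor passes through unchanged with a warning, so dataset-level class
proportions are conserved exactly.

### SR inpainting

`inpaint_sr()` extracts $M_S$ from the image itself, dilates it with an
all-true rectangular `10 × 10` element (anchor at
$(\lfloor h/2\rfloor, \lfloor w/2\rfloor)$ for even sizes), and hands the
dilated mask to an inpainting backend. Two contracts are enforced
*outside* the backend:

* pixels outside the dilated mask are restored bit-identically from the
  input (tested with an adversarial backend that returns noise);
* the backend must be a pure function, so the whole route is deterministic
  and emits exactly one image per input.

The default backend is a classical harmonic (diffusion) fill: masked
pixels, initialised to the mean of the mask's boundary values, are Jacobi-
iterated toward the mean of their available 4-neighbours until the largest
per-iteration change falls below `tol` or `max_iter` is reached. This is
the discrete Laplace equation with Dirichlet boundary, so the fill obeys
the maximum principle — filled values never leave the range of the boundary
values, hence a filled image can never contain new saturated pixels. The
default `tol = 0.001` (intensity units) with `max_iter = 2000` keeps the
iteration residual far below the 8-bit quantisation step; on small masked
blocks the fill agrees with a dense linear-system solve of the same
equation to within rounding (≤ 0.5 intensity), which the test suite checks
against an independent dense solver. A looser tolerance near 0.1 would
leave a visible Jacobi residual of the same order as the quantisation step
itself, so the tighter default was adopted. Learned inpainters (e.g.
high-resolution large-mask models) can be registered by name through
`register_backend()` without adding dependencies; the outside-mask
composite contract applies to them unchanged.

### Preprocessing and baseline augmentations

Polyp boxes come from the annotating colonoscopist. Preprocessing is crop →
pad-to-square → bilinear resize: padding before resizing preserves the
polyp's aspect ratio, which direct resizing of variable-aspect boxes would
distort. "Coordination noise" jitters the crop centre by
$(\delta_x w, \delta_y h)$ with $\delta_{x,y} \sim U(-\alpha, \alpha)$; the
noisy crop keeps the annotated box's size and is clamped back inside the
frame (clamping, rather than padding, keeps pixel provenance trivial). The
amplitude α is not canonical; the default 0.1 is a mild jitter consistent
with the intent of diversifying crops. Padding uses intensity 0 — endoscopy
backgrounds are dark. When the total padding is odd, the extra pixel goes
toward bottom/right.

The baseline stack (rotation, flip, colour jitter, Gaussian noise, Gaussian
blur) applies each enabled op independently with probability
`apply_prob = 0.5` in a fixed order. Magnitudes (rotation ±30°, jitter
strength 0.2, noise σ = 5, blur σ = 1) are conventional mild defaults and
all configuration-exposed; a grid over them can be run through
`base_aug_config()` rather than hard-coding any winner. Fourier domain
adaptation (`fda_transfer()`) swaps the centred low-frequency amplitude
window (half-width $\lfloor \beta \min(H, W) \rfloor$) of the source for
the target's while keeping the source phase; at the DC-only limit it
transfers the target's per-channel mean. MixStyle and generative
augmentation are excluded: the former operates on network feature maps and
cannot exist without a model, the latter requires trained generators.

## The phantom generator

Clinical NBI images are private, so every pipeline stage is exercised on
seeded phantoms (`generate_phantom_set()`) that reproduce the *structure*
the algorithms depend on, not the visual appearance of mucosa:

* dark reddish background, channel means (bg+25, bg, bg−25) around
  `background_mean = 90`, with a 25 % centre-lit radial falloff — the
  endoscope illuminates a dark lumen from the lens;
* one elliptical polyp, elevated by `polyp_contrast = 40`, with a soft rim
  (elevation tapered over the outer 20 % of the ellipse radius) and a
  sinusoidal surface texture of amplitude 15 whose frequency encodes the
  class (AD 18 cycles/image — fine; HP 6 — coarse), a stand-in for the
  surface/vascular patterns that separate the classes clinically. The soft
  rim matters: with a hard step edge, the rim's broadband harmonics drown
  the texture peak and the class signal stops being recoverable by a simple
  spectral statistic;
* additive Gaussian sensor noise (σ = 4), with all tissue intensities
  clamped at 245 — a sensor-saturation analogue that, combined with the
  config invariant `background + contrast + texture + 3σ < 246`, guarantees
  no false SR pixels;
* 1–6 saturated elliptical SR blobs (intensities 246–255, semi-axes
  2–10 px) placed in and around the polyp, with the exact planted mask
  returned alongside the image.

Because tissue stays ≤ 245 and blobs start at ≥ 246, threshold extraction
recovers the planted mask pixel-for-pixel — the generator's core oracle.
Each phantom's random stream is derived from `(seed, index)`, so any single
image is reproducible in isolation and dataset generation is
order-independent. Class counts follow a deterministic floor-plus-remainder
rule. What the phantoms do *not* emulate — real mucosal texture, NBI
optics, soft SR rims above threshold, three-dimensional shading — bounds
what passing tests show: they validate the mask algebra, compositing,
filling, statistics and determinism of the pipeline, not the clinical
realism of its outputs.

## Splits and statistics

`stratified_holdout()` draws an exact per-class holdout;
`stratified_kfold()` balances per-class fold sizes to within one sample.
Split balance across covariates (diagnosis, location, size, morphology) is
tested with Pearson's chi-square *without* continuity correction — the
convention that reproduces the reported balance p-values for cohorts of
this size — with cell percentages per column printed to one decimal. AUC
uses the Mann–Whitney formulation (ties ½), equal to trapezoidal ROC
integration; paired classifiers are compared with DeLong's placement-value
test (via pROC), cross-checked in the suite against a 10⁴-resample
bootstrap of the AUC difference. Stress-test subsets are *nested* across
fractions (10 %, …, 100 %): nesting is a variance-reduction choice, not a
statistical necessity, and is seed-exposed. Soft voting is the unweighted
mean of frame probabilities per group.

## Numerical choices and degenerate inputs

* Borders: blurs use symmetric reflection; dilation treats out-of-image as
  background (the morphology convention; reflecting would conjure phantom
  blobs at frame edges).
* Even structuring elements anchor at (⌊h/2⌋, ⌊w/2⌋); binary masks resize
  nearest-neighbour, soft masks bilinear.
* Manifest CSVs store paths relative to their own directory, making dataset
  folders relocatable and regenerated trees byte-identical under one seed.
* Degenerate cases: empty masks short-circuit inpainting to the identity;
  donors below the minimum mask fraction raise a typed "no SR donor"
  condition that bulk augmentation converts into a logged pass-through;
  single-class prediction sets are rejected by the metric functions; zero
  chi-square margins are rejected before the test statistic is formed.
* All randomness flows through explicit `seeded_rng()` streams; no function
  reads or mutates the caller's global RNG state.

## Problem sizes used by the tests

The test and acceptance runs use 48–96 px phantoms and 100-image property
sweeps; these sizes were chosen so the whole suite exercises every contract
(including the 10⁴-resample bootstrap and two full pipeline runs) in a few
minutes on one core while leaving the probability of missing a
property violation negligible — every oracle comparison is exact, not
sampled at tolerance.
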