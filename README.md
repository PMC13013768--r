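# specaug

Specular-reflection (SR) aware data augmentation for colonoscopy
computer-aided diagnosis (CADx).

## The problem

During colonoscopy the endoscope's light source illuminates wet mucosa and
inevitably produces specular reflections: saturated, near-white artifacts
that sit on top of exactly the surface and vascular patterns a polyp
classifier (adenomatous, AD, vs hyperplastic, HP) needs to see. Classical
pipelines discard frames with prominent SR as non-informative, wasting
scarce labelled data. The alternative implemented here treats SR as a
first-class augmentation signal, in two complementary directions:

* **SR generation** — extract the SR mask `M_S` from a donor image by
  grayscale conversion and a strict intensity threshold (`Y > 245`), refine
  it with two Gaussian filters (a small `k1 = 5` kernel for the smooth
  highlight core and a sigma-sized kernel for the colour-spreading halo,
  the `k2 = 0` convention), apply a random rigid transform and an RGB
  perturbation of the halo colour, and alpha-composite the result onto a
  randomly chosen target image *of the same class*. Each epoch can draw new
  donors, so one labelled image yields many SR variants.
* **SR inpainting** — extract `M_S` from the image itself, dilate it with a
  rectangular `10 × 10` structuring element to cover the soft rims, isolate
  the unaffected region, and fill the dilated mask from surrounding tissue
  through a pluggable inpainting backend. The built-in backend is a
  classical harmonic (diffusion) fill — masked pixels converge to the
  solution of the discrete Laplace equation with the surrounding pixels as
  Dirichlet boundary; learned high-resolution inpainters can be registered
  through the same interface (`register_backend()`), and pixels outside the
  dilated mask are guaranteed bit-identical to the input regardless of the
  backend.

Around this core the package provides the rest of a reproducible
experimental harness: bounding-box-guided preprocessing (crop with
"coordination noise" `δ ~ U(−α, α)` of the box centre, pad-to-square,
bilinear resize to 150 or 224 px), the baseline natural-image augmentations
(rotation, flip, colour jitter, Gaussian noise/blur), Fourier domain
adaptation (low-frequency amplitude swap, source phase kept), stratified
holdout/k-fold splitting with Pearson chi-square balance reporting, ROC/AUC
metrics with DeLong's paired test, nested stress-test subsampling, and
frame-level soft voting. A seeded endoscopy-phantom generator with exact
ground-truth SR masks makes every stage testable without clinical data.

## Worked example

```r
library(specaug)

dir <- file.path(tempdir(), "demo")
m <- generate_phantom_set(phantom_config(n_images = 8, image_size = 96, seed = 7), dir)
manifest_counts(m)
#> AD HP
#>  4  4

img  <- read_image(m$image_path[1])
mask <- extract_sr_mask(img, 245)
sum(mask); mask_area_fraction(mask)
#> SR pixels in phantom 1: 363 (3.94% of frame)

# transplant the donor's highlights onto the first image (same class)
gen <- generate_sr(img, read_image(m$image_path[2]), sr_gen_config(), seeded_rng(1))
sum(extract_sr_mask(gen$image))
#> 381          # the planted highlight is itself re-detectable

# remove and fill this image's own highlights
inp <- inpaint_sr(img, sr_inp_config())
max(to_grayscale(inp$image)); sum(inp$mask)
#> 154, 1119    # no saturated pixel survives; 1119 dilated-mask pixels filled

# split-balance check on published cohort counts (training vs holdout)
chi_square_independence(matrix(c(1249, 120, 1127, 120), 2, 2, byrow = TRUE))
#> X2 = 0.576, df = 1, p = 0.448
```

The same operations are scriptable from a shell through `exec/specaug`:

```sh
specaug make-phantoms --n 100 --size 224 --seed 7 --out phantoms
specaug preprocess    --manifest phantoms/manifest.csv --out prep --size 224 --alpha 0.1 --seed 7
specaug augment-gen   --manifest prep/manifest.csv --out gen --n-per-image 1 --seed 7
specaug augment-inp   --manifest gen/manifest.csv  --out inp
```

Model training itself (ResNet/ViT) is out of scope: the manifests and
prediction-CSV interfaces (`read_predictions()`, `classification_metrics()`,
`delong_test()`, `soft_vote()`) connect the augmented datasets to any
external trainer.

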