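Package: specaug
Title: Specular-Reflection Data Augmentation for Colonoscopy Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for specular-reflection (SR) aware data augmentation of
    colonoscopy still images used in computer-aided polyp diagnosis.
    Implements SR mask extraction by luma thresholding, SR generation
    (transplanting refined, transformed, colour-perturbed highlight masks
    between same-class images), SR inpainting (mask dilation, removal and
    fill through a pluggable inpainting backend with a built-in harmonic
    diffusion fill), bounding-box guided preprocessing with coordination
    noise, classical baseline augmentations plus Fourier domain adaptation,
    stratified data splitting with chi-square balance reporting, ROC/AUC
    metrics with DeLong comparison of paired classifiers, and a seeded
    endoscopy-phantom generator with exact ground-truth SR masks for
    testing every stage without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    pROC,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
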