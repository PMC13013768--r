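#' specaug: specular-reflection data augmentation for colonoscopy CADx
#'
#' Implements the two specular-reflection (SR) augmentation routes used to
#' train polyp classifiers on narrow-band-imaging stills — SR generation
#' (transplanting highlight masks between same-class images) and SR
#' inpainting (detecting, dilating, removing and filling highlights) —
#' together with bounding-box guided preprocessing, baseline augmentations,
#' Fourier domain adaptation, stratified splitting with chi-square balance
#' reporting, ROC/AUC and DeLong statistics, and a seeded phantom generator
#' with exact ground-truth SR masks.
#'
#' @keywords internal
"_PACKAGE"

.onLoad <- function(libname, pkgname) {
  if (!exists("diffusion", envir = .specaug_backends, inherits = FALSE))
    register_backend("diffusion", builtin_diffusion_fill)
}
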