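# Shared fixtures: a small zero-noise phantom is reused across test files
# (classification, volumetrics, pipeline). Built once per test run.
.fixtures <- new.env(parent = emptyenv())

tiny_spec <- function(...) phantom_spec(dim = c(40, 40, 40), spacing = c(2, 2, 2), ...)

tiny_phantom <- function() {
  if (is.null(.fixtures$tiny)) .fixtures$tiny <- generate_phantom(tiny_spec())
  .fixtures$tiny
}

tiny_stack <- function() {
  if (is.null(.fixtures$tiny_stack))
    .fixtures$tiny_stack <- phantom_stack(tiny_phantom())
  .fixtures$tiny_stack
}

tiny_labels <- function() {
  if (is.null(.fixtures$tiny_labels))
    .fixtures$tiny_labels <- classify(tiny_stack())
  .fixtures$tiny_labels
}

dice_per_class <- function(labels, truth) {
  vapply(setdiff(names(TISSUE_CODES), "Background"), function(t) {
    a <- labels == TISSUE_CODES[[t]]
    b <- truth == TISSUE_CODES[[t]]
    if (sum(a) + sum(b) == 0) return(NA_real_)
    2 * sum(a & b) / (sum(a) + sum(b))
  }, numeric(1))
}

# A volume with constant value per region, for calibration arithmetic tests
flat_volume <- function(value, dim = c(8, 8, 8), modality = "T1w") {
  mri_volume(array(value, dim = dim), spacing = c(1, 1, 1), modality = modality)
}
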