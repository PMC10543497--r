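#' In-memory MRI volume
#'
#' A light container for a 3-D scalar field on a regular voxel grid:
#' the voxel data, the voxel spacing in mm, a 4x4 voxel-to-world affine and
#' the acquisition modality. Calibrated volumes additionally carry a
#' `calibration` record (see [calibrate()]); ADC maps carry the marker
#' `"physical-units"` because they are in micrometer^2/s and are never
#' intensity-calibrated.
#'
#' @param data 3-D numeric array.
#' @param spacing Numeric length-3, voxel spacing (dx, dy, dz) in mm; all > 0.
#' @param modality One of `"T1w"`, `"T1wCE"`, `"T2w"`, `"FLAIR"`,
#'   `"DWI_b0"`, `"DWI_b1000"`, `"ADC"`.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   affine built from `spacing`.
#' @param calibration `NULL` (raw), the string `"physical-units"` (ADC), or a
#'   calibration record list as produced by [calibrate()].
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(data, spacing, modality,
                       affine = NULL, calibration = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)")
  modality <- match.arg(modality, MODALITIES)
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(
    list(data = data, spacing = spacing, affine = affine,
         modality = modality, calibration = calibration),
    class = "mri_volume"
  )
}

MODALITIES <- c("T1w", "T1wCE", "T2w", "FLAIR", "DWI_b0", "DWI_b1000", "ADC")

#' @export
print.mri_volume <- function(x, ...) {
  cal <- if (is.null(x$calibration)) "raw"
         else if (identical(x$calibration, "physical-units")) "physical-units"
         else "calibrated"
  cat(sprintf("<mri_volume> %s  %s  spacing %s mm  [%s]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), cal))
  invisible(x)
}

#' Voxel volume in mm^3
#' @param x An `mri_volume`, `mpmri_stack` or `tissue_labels` object.
#' @return Scalar, dx*dy*dz in mm^3.
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' Load a NIfTI volume from disk
#'
#' Reads a 3-D NIfTI volume, taking spacing and affine from the header.
#' Files containing NaN voxels are rejected by default (the count is
#' reported); `nan = "zero"` replaces them with 0 and emits a warning.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param modality Modality tag recorded on the volume.
#' @param nan Policy for NaN voxels: `"error"` (default) or `"zero"`.
#' @return An [mri_volume()].
#' @export
load_volume <- function(path, modality, nan = c("error", "zero")) {
  nan <- match.arg(nan)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3-D volume, got %d-D: %s", length(d), path))
  data <- array(as.numeric(img[]), dim = d)
  n_nan <- sum(is.nan(data))
  if (n_nan > 0L) {
    if (nan == "error")
      stop(sprintf("%d NaN voxel(s) in %s; pass nan = \"zero\" to zero-fill",
                   n_nan, path))
    warning(sprintf("zero-filled %d NaN voxel(s) in %s", n_nan, path))
    data[is.nan(data)] <- 0
  }
  sp <- as.numeric(RNifti::pixdim(img))[1:3]
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  mri_volume(data, spacing = abs(sp), modality = modality, affine = aff)
}

#' Save a volume or mask as NIfTI
#'
#' Label maps and masks are written with an integer datatype so that a
#' save-load cycle is bit-identical; continuous volumes are written as
#' double.
#'
#' @param x An `mri_volume`, or a plain 3-D array (needs `spacing`).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param spacing Required when `x` is a bare array.
#' @param datatype NIfTI datatype; `"auto"` picks `"int32"` for integer or
#'   logical data and `"double"` otherwise.
#' @return `path`, invisibly.
#' @export
save_volume <- function(x, path, spacing = NULL, datatype = "auto") {
  if (inherits(x, "mri_volume")) {
    data <- x$data; spacing <- x$spacing
  } else {
    stopifnot(is.array(x), !is.null(spacing))
    data <- x
  }
  if (is.logical(data)) storage.mode(data) <- "integer"
  if (datatype == "auto")
    datatype <- if (is.integer(data)) "int32" else "double"
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Check that two volumes share a grid
#'
#' Grids agree when the array shapes match and spacing and affine agree
#' within an absolute tolerance. No resampling is ever performed: mismatched
#' inputs are the caller's problem by design, since silent resampling would
#' hide registration errors.
#'
#' @param a,b `mri_volume` objects (or lists with `data`, `spacing`, `affine`).
#' @param tol Absolute tolerance on spacing and affine entries.
#' @return `TRUE` or `FALSE`.
#' @export
grids_compatible <- function(a, b, tol = 1e-3) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$affine - b$affine)) <= tol
}

#' Assemble a co-registered multiparametric stack
#'
#' Verifies that every modality lives on the same voxel grid and bundles
#' them with the brain mask. ADC is optional; when absent the stack is
#' flagged so that classification runs in no-ADC mode. Inputs must already
#' be co-registered and resampled to a common grid (typically the T2w
#' grid); this function refuses mismatches rather than resampling.
#'
#' @param volumes Named list with elements `t1w`, `t1wce`, `t2w`, `flair`
#'   and optionally `adc`, each an [mri_volume()].
#' @param brain_mask Logical 3-D array on the same grid, or `NULL` to derive
#'   a fallback mask from the T2w volume (positive voxels, largest connected
#'   component, holes filled).
#' @param tol Absolute grid tolerance passed to [grids_compatible()].
#' @return An object of class `mpmri_stack` with fields `t1w`, `t1wce`,
#'   `t2w`, `flair`, `adc` (or `NULL`), `brain_mask`, `spacing`,
#'   `adc_present`.
#' @export
assemble_stack <- function(volumes, brain_mask = NULL, tol = 1e-3) {
  req <- c("t1w", "t1wce", "t2w", "flair")
  missing <- setdiff(req, names(volumes))
  if (length(missing))
    stop("missing required modalit(ies): ", paste(missing, collapse = ", "))
  ref <- volumes$t2w
  for (nm in intersect(c(req, "adc"), names(volumes))) {
    v <- volumes[[nm]]
    if (!inherits(v, "mri_volume")) stop(nm, " is not an mri_volume")
    if (!grids_compatible(ref, v, tol = tol))
      stop("grid mismatch: ", nm,
           " does not share the T2w grid (shape/spacing/affine beyond tolerance)")
  }
  if (is.null(brain_mask)) brain_mask <- default_brain_mask(ref)
  stopifnot(is.logical(brain_mask) || all(brain_mask %in% c(0, 1)))
  brain_mask <- array(as.logical(brain_mask), dim = dim(ref$data))
  if (!identical(dim(brain_mask), dim(ref$data)))
    stop("brain_mask shape does not match the stack grid")
  for (nm in intersect(c(req, "adc"), names(volumes))) {
    if (any(!is.finite(volumes[[nm]]$data[brain_mask])))
      stop("non-finite voxels inside brain_mask in ", nm)
  }
  structure(
    list(t1w = volumes$t1w, t1wce = volumes$t1wce, t2w = volumes$t2w,
         flair = volumes$flair, adc = volumes$adc %||% NULL,
         brain_mask = brain_mask, spacing = ref$spacing,
         adc_present = !is.null(volumes$adc)),
    class = "mpmri_stack"
  )
}

#' @export
print.mpmri_stack <- function(x, ...) {
  cat(sprintf("<mpmri_stack> %s  spacing %s mm  ADC %s  brain voxels %d\n",
              paste(dim(x$t2w$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              if (x$adc_present) "present" else "absent",
              sum(x$brain_mask)))
  invisible(x)
}

# Fallback brain mask: positive T2w voxels, largest 6-connected component,
# then interior zero-pockets filled by complementing the background component.
default_brain_mask <- function(t2w) {
  pos <- t2w$data > 0
  comp <- label_components(pos)
  if (max(comp) == 0L) stop("cannot derive a brain mask: no positive T2w voxels")
  sizes <- tabulate(comp[comp > 0L])
  main <- comp == which.max(sizes)
  bg <- label_components(!main)
  # background component touching the array corner is 'outside'; other
  # components are interior holes
  outside_id <- bg[1L, 1L, 1L]
  main | (bg > 0L & bg != outside_id)
}

# 6-connectivity connected components via BFS on a logical array.
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  idx_all <- which(mask)
  if (!length(idx_all)) return(lab)
  nxt <- 0L
  strides <- c(1L, d[1L], d[1L] * d[2L])
  coord <- arrayInd(idx_all, d)
  pos <- integer(prod(d)); pos[idx_all] <- seq_along(idx_all)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start; lab[start] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ci <- arrayInd(cur, d)
      for (ax in 1:3) {
        for (dir in c(-1L, 1L)) {
          ok <- ci[, ax] + dir >= 1L & ci[, ax] + dir <= d[ax]
          nb <- cur[ok] + dir * strides[ax]
          nb <- nb[mask[nb] & lab[nb] == 0L]
          if (length(nb)) {
            lab[nb] <- nxt
            queue <- c(queue, nb)
          }
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
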