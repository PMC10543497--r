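ABNORMAL_TISSUES <- c("BV", "CE", "Edema1", "Edema2", "Fluid")

#' Build the abnormal VOI and reclassify vessels within it
#'
#' Within a loose, manually drawn tumor contour, the abnormal VOI (abVOI)
#' is the set of voxels labeled BV, CE, Edema1, Edema2 or Fluid. Enhancing
#' voxels inside the tumor region are overwhelmingly tumor rather than
#' vessel, so every BV voxel inside the abVOI is reclassified to CE;
#' labels outside the abVOI are untouched. Hemorrhage inside the manual
#' contour is deliberately not part of the abVOI and is reported
#' separately.
#'
#' @param labels A [tissue_labels()] map.
#' @param manual_voi Logical 3-D mask on the same grid (loose contour
#'   encompassing the pathologic region).
#' @return An object of class `abnormal_voi`: list with `abvoi` (logical
#'   mask), `reclassified` (a [tissue_labels()] with BV inside the abVOI
#'   relabeled CE), `manual_voi`, `n_reclassified`, and
#'   `hemorrhage_in_voi` (voxel count, recorded but excluded from the
#'   abVOI).
#' @export
build_abvoi <- function(labels, manual_voi) {
  stopifnot(inherits(labels, "tissue_labels"))
  manual_voi <- as_mask(manual_voi)
  if (!identical(dim(manual_voi), dim(labels$labels)))
    stop("manual_voi is not on the label map's grid")
  ab_codes <- TISSUE_CODES[ABNORMAL_TISSUES]
  lab <- labels$labels
  abvoi <- manual_voi & array(lab %in% ab_codes, dim = dim(lab))
  if (!any(abvoi))
    warning("manual VOI contains no abnormal tissue: empty abVOI")
  bv_in <- abvoi & (lab == TISSUE_CODES[["BV"]])
  out <- labels
  out$labels[bv_in] <- TISSUE_CODES[["CE"]]
  structure(
    list(abvoi = abvoi, reclassified = out, manual_voi = manual_voi,
         n_reclassified = sum(bv_in),
         hemorrhage_in_voi = sum(manual_voi &
                                   lab == TISSUE_CODES[["Hemorrhage"]])),
    class = "abnormal_voi"
  )
}

#' Per-tissuetype volumes
#'
#' Counts voxels per tissuetype (optionally restricted to a scope mask such
#' as the abVOI) and converts to cm^3. The derived "High FLAIR" volume is
#' Edema1 + Edema2 exactly.
#'
#' @param labels A [tissue_labels()] map.
#' @param scope_mask Optional logical mask restricting the tally (e.g. the
#'   abVOI); `NULL` tallies the whole volume.
#' @param voxel_volume_mm3 Voxel volume; defaults to the label map's.
#' @return A tibble with columns `tissue`, `voxels`, `volume_cm3` and
#'   `scope` (`"whole-brain"` or `"scoped"`), one row per tissuetype plus a
#'   `HighFLAIR` row.
#' @export
compute_volumes <- function(labels, scope_mask = NULL,
                            voxel_volume_mm3 = NULL) {
  stopifnot(inherits(labels, "tissue_labels"))
  if (is.null(voxel_volume_mm3)) voxel_volume_mm3 <- prod(labels$spacing)
  lab <- labels$labels
  scope <- "whole-brain"
  if (!is.null(scope_mask)) {
    scope_mask <- as_mask(scope_mask)
    if (!identical(dim(scope_mask), dim(lab)))
      stop("scope_mask is not on the label map's grid")
    lab <- lab[scope_mask]
    scope <- "scoped"
  }
  tissues <- setdiff(names(TISSUE_CODES), "Background")
  counts <- vapply(tissues, function(t) sum(lab == TISSUE_CODES[[t]]),
                   integer(1))
  out <- tibble::tibble(
    tissue = tissues,
    voxels = unname(counts),
    volume_cm3 = unname(counts) * voxel_volume_mm3 / 1000,
    scope = scope
  )
  hf <- out$tissue %in% c("Edema1", "Edema2")
  dplyr::bind_rows(out, tibble::tibble(
    tissue = "HighFLAIR",
    voxels = sum(out$voxels[hf]),
    volume_cm3 = sum(out$volume_cm3[hf]),
    scope = scope
  ))
}

#' Union abnormal VOI from reference segmentation labels
#'
#' For validation against an external reference segmentation (enhancing
#' tumor ET, peritumoral edema ED, necrotic / non-enhancing core NCR-NET),
#' the abnormal VOI is the union of the three contours. Overlapping
#' reference labels are tolerated; for per-class use the precedence
#' ET > NCR/NET > ED applies and overlaps are reported via a message.
#'
#' @param et,ncr,ed Logical 3-D masks on a common grid (any may be empty;
#'   `NULL` counts as empty).
#' @return Logical union mask, with attribute `overlap_voxels` giving the
#'   number of voxels claimed by more than one reference label.
#' @export
build_abvoi_from_reference <- function(et, ncr = NULL, ed = NULL) {
  et <- as_mask(et)
  empty <- array(FALSE, dim = dim(et))
  ncr <- if (is.null(ncr)) empty else as_mask(ncr)
  ed <- if (is.null(ed)) empty else as_mask(ed)
  stopifnot(identical(dim(et), dim(ncr)), identical(dim(et), dim(ed)))
  overlap <- sum((et & ncr) | (et & ed) | (ncr & ed))
  if (overlap > 0L)
    message(overlap, " overlapping reference voxel(s); precedence ET > NCR/NET > ED")
  out <- et | ncr | ed
  attr(out, "overlap_voxels") <- overlap
  out
}

#' Tissuetype composition of a reference region
#'
#' Percentage of a reference mask's voxels carrying each tissuetype label;
#' percentages sum to 100.
#'
#' @param labels A [tissue_labels()] map.
#' @param reference_mask Non-empty logical mask on the same grid.
#' @return Tibble with columns `tissue`, `voxels`, `percent`.
#' @export
composition <- function(labels, reference_mask) {
  stopifnot(inherits(labels, "tissue_labels"))
  reference_mask <- as_mask(reference_mask)
  if (!identical(dim(reference_mask), dim(labels$labels)))
    stop("reference_mask is not on the label map's grid")
  n <- sum(reference_mask)
  if (n == 0L) stop("empty reference mask")
  lab <- labels$labels[reference_mask]
  counts <- vapply(names(TISSUE_CODES),
                   function(t) sum(lab == TISSUE_CODES[[t]]), integer(1))
  tibble::tibble(
    tissue = names(TISSUE_CODES),
    voxels = unname(counts),
    percent = unname(counts) / n * 100
  )
}
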