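#' Two-reference-tissue calibration pair
#'
#' Intensity calibration maps the arbitrary scanner units of a structural
#' sequence onto a standard scale on which fixed thresholds are meaningful
#' across scan dates and scanners. Two reference tissues (typically
#' ventricular CSF and normal-appearing white matter) are assigned target
#' values on the calibrated scale; the observed reference statistics define
#' an affine intensity map.
#'
#' @param mask_low,mask_high Logical 3-D arrays selecting the two reference
#'   tissues; must be non-empty and disjoint.
#' @param target_low,target_high Calibrated-scale targets; `target_low <
#'   target_high`.
#' @param name_low,name_high Reference tissue names, recorded in the
#'   calibration record.
#' @param statistic Summary statistic of the reference voxels: `"median"`
#'   (default, robust to stray voxels in the mask) or `"mean"`.
#' @return An object of class `reference_pair`.
#' @export
reference_pair <- function(mask_low, mask_high, target_low, target_high,
                           name_low = "reference-low",
                           name_high = "reference-high",
                           statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  mask_low <- as_mask(mask_low); mask_high <- as_mask(mask_high)
  if (!any(mask_low) || !any(mask_high))
    stop("reference masks must be non-empty")
  if (any(mask_low & mask_high))
    stop("reference masks must be disjoint")
  if (!is.finite(target_low) || !is.finite(target_high) ||
      target_low >= target_high)
    stop("target_low must be finite and < target_high")
  structure(
    list(mask_low = mask_low, mask_high = mask_high,
         target_low = target_low, target_high = target_high,
         name_low = name_low, name_high = name_high,
         statistic = statistic),
    class = "reference_pair"
  )
}

as_mask <- function(m) {
  stopifnot(is.array(m), length(dim(m)) == 3L)
  array(as.logical(m), dim = dim(m))
}

ref_stat <- function(values, statistic) {
  if (statistic == "median") stats::median(values) else mean(values)
}

#' Calibrate a raw volume against two reference tissues
#'
#' Fits the affine intensity map `a*x + b` that sends the observed
#' reference statistics onto their targets
#' (`a = (target_high - target_low) / (m_high - m_low)`,
#' `b = target_low - a*m_low`) and applies it voxelwise. The map is
#' invariant to any prior affine distortion of the raw intensities with
#' positive gain, which is what makes downstream thresholds transferable,
#' and calibrating an already-calibrated volume with the same references is
#' the identity.
#'
#' ADC maps are in physical units and must not be passed here.
#'
#' @param raw An [mri_volume()] on the same grid as the reference masks.
#' @param refs A [reference_pair()].
#' @return A calibrated [mri_volume()] whose `calibration` field records the
#'   reference names, observed statistics, targets and affine coefficients.
#' @export
calibrate <- function(raw, refs) {
  stopifnot(inherits(raw, "mri_volume"), inherits(refs, "reference_pair"))
  if (raw$modality == "ADC")
    stop("ADC maps are in physical units and are not intensity-calibrated")
  if (!identical(dim(raw$data), dim(refs$mask_low)))
    stop("reference masks are not on the volume's grid")
  m_low <- ref_stat(raw$data[refs$mask_low], refs$statistic)
  m_high <- ref_stat(raw$data[refs$mask_high], refs$statistic)
  if (!is.finite(m_low) || !is.finite(m_high))
    stop("non-finite reference statistic")
  if (m_high == m_low)
    stop("degenerate calibration: both reference tissues have identical ",
         refs$statistic, " (", format(m_low), ")")
  a <- (refs$target_high - refs$target_low) / (m_high - m_low)
  b <- refs$target_low - a * m_low
  out <- raw
  out$data <- a * raw$data + b
  out$calibration <- list(
    ref_low = refs$name_low, ref_high = refs$name_high,
    observed_low = m_low, observed_high = m_high,
    target_low = refs$target_low, target_high = refs$target_high,
    statistic = refs$statistic, gain = a, offset = b
  )
  out
}

#' Verify a calibration
#'
#' Recomputes the reference statistics on a calibrated volume and reports
#' their residuals against the targets. Report-only: never throws on a bad
#' calibration, so it can be used as a post-hoc QC step.
#'
#' @param vol A calibrated [mri_volume()].
#' @param refs The [reference_pair()] used (or intended) for calibration.
#' @param tol Relative tolerance on each residual, as a fraction of the
#'   target span (`target_high - target_low`).
#' @return A tibble with one row per reference tissue: observed value,
#'   target, residual and an `ok` flag. For ADC volumes, a zero-row tibble
#'   with attribute `note = "physical-units, not applicable"`.
#' @export
verify_calibration <- function(vol, refs, tol = 0.02) {
  stopifnot(inherits(vol, "mri_volume"))
  if (identical(vol$calibration, "physical-units") || vol$modality == "ADC") {
    out <- tibble::tibble(reference = character(), observed = double(),
                          target = double(), residual = double(),
                          ok = logical())
    attr(out, "note") <- "physical-units, not applicable"
    return(out)
  }
  obs <- c(ref_stat(vol$data[refs$mask_low], refs$statistic),
           ref_stat(vol$data[refs$mask_high], refs$statistic))
  tgt <- c(refs$target_low, refs$target_high)
  span <- refs$target_high - refs$target_low
  tibble::tibble(
    reference = c(refs$name_low, refs$name_high),
    observed = obs, target = tgt, residual = obs - tgt,
    ok = abs(obs - tgt) <= tol * span
  )
}
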