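#' Pair of diffusion-weighted volumes
#'
#' Holds the b = 0 and b = b1 signal volumes from a two-b-value DWI
#' acquisition (clinically, b = 0 and 1000 s/mm^2).
#'
#' @param s0 [mri_volume()] of the unweighted (b = 0) signal.
#' @param sb [mri_volume()] of the diffusion-weighted signal at `b1`.
#' @param b1 b-value of `sb` in s/mm^2; must be > 0.
#' @return An object of class `dwi_pair`.
#' @export
dwi_pair <- function(s0, sb, b1 = 1000) {
  stopifnot(inherits(s0, "mri_volume"), inherits(sb, "mri_volume"))
  if (!is.finite(b1) || b1 <= 0) stop("b1 must be a positive b-value (s/mm^2)")
  if (!grids_compatible(s0, sb)) stop("s0 and sb do not share a grid")
  if (any(s0$data < 0, na.rm = TRUE) || any(sb$data < 0, na.rm = TRUE))
    stop("DWI signal values must be non-negative")
  structure(list(s0 = s0, sb = sb, b1 = b1), class = "dwi_pair")
}

#' Apparent diffusion coefficient map by monoexponential fit
#'
#' With exactly two b-values the monoexponential model
#' `S(b) = S(0) * exp(-b * ADC)` inverts in closed form:
#' `ADC = ln(S(0)/S(b1)) / b1`, reported in micrometer^2/s (1 mm^2/s =
#' 1e6 um^2/s). Signals are floored at a small positive value before taking
#' the log; voxels whose `s0` does not exceed the floor get ADC 0 and are
#' flagged as unavailable (attribute `"adc_unavailable"`), so downstream
#' ADC predicates can fall back to intensity-only rules there. This
#' handling of degenerate signals (air background, EPI edge artifacts) is
#' the package's own convention.
#'
#' @param pair A [dwi_pair()].
#' @param floor Signal floor; default `1e-6 * max(s0)`.
#' @return An [mri_volume()] with modality `"ADC"`, calibration
#'   `"physical-units"`, and a logical attribute `adc_unavailable` marking
#'   flagged voxels.
#' @export
fit_adc <- function(pair, floor = NULL) {
  stopifnot(inherits(pair, "dwi_pair"))
  s0 <- pair$s0$data; sb <- pair$sb$data
  if (is.null(floor)) floor <- 1e-6 * max(s0)
  if (!is.finite(floor) || floor <= 0)
    stop("floor must be positive (is s0 identically zero?)")
  unavailable <- s0 <= floor
  adc <- log(pmax(s0, floor) / pmax(sb, floor)) / pair$b1 * 1e6
  adc[unavailable] <- 0
  out <- mri_volume(adc, spacing = pair$s0$spacing, modality = "ADC",
                    affine = pair$s0$affine, calibration = "physical-units")
  attr(out, "adc_unavailable") <- unavailable
  out
}
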