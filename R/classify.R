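#' Decision-node thresholds for tissuetype classification
#'
#' Every cut in the voxelwise decision tree is an explicit, serializable
#' configuration value. The two ADC cutoffs are physiological literature
#' values in micrometer^2/s: free fluid has ADC >= 2130 um^2/s and
#' hemorrhage (or densely packed cells) ADC <= 550 um^2/s. The remaining
#' cuts are on the calibrated intensity scale and default to values
#' consistent with the package's canonical calibration targets (CSF and
#' white matter mapped to fixed per-modality values; see
#' [canonical_intensities()]). Users reproducing a specific scanner setup
#' should set their own cuts; the active configuration is recorded in the
#' provenance of every label map.
#'
#' Comparison conventions: the ADC rules are inclusive (`<=
#' adc_hemorrhage_max`, `>= adc_fluid_min`); all calibrated-intensity cuts
#' are strict (`>` / `<`).
#'
#' @param adc_hemorrhage_max ADC at or below which a voxel is hemorrhage
#'   (um^2/s, default 550).
#' @param adc_fluid_min ADC at or above which a VOI3 voxel is fluid
#'   (um^2/s, default 2130).
#' @param t2w_hyper_cut Calibrated T2w separating normal GM/WM (VOI2,
#'   below) from fluid/pathologic tissue (VOI3, above).
#' @param flair_bv_cut Calibrated FLAIR separating blood vessel (below)
#'   from contrast-enhancing tumor (at/above) within enhancing voxels.
#' @param flair_fluid_cut Calibrated FLAIR below which a VOI3 voxel is
#'   fluid (CSF is suppressed on FLAIR).
#' @param flair_gmwm_cut,t1w_gmwm_cut WM requires FLAIR below
#'   `flair_gmwm_cut` (WM darker than GM on FLAIR) and T1w above
#'   `t1w_gmwm_cut` (WM brighter than GM on T1w); otherwise GM.
#' @param t1w_hemorrhage_cut Calibrated T1w above which a VOI3 voxel is
#'   hemorrhage (methemoglobin is T1w-bright).
#' @param t1w_edema_cut Calibrated T1w separating tumor-associated edema
#'   (Edema1, at/below) from leukoaraiosis-like tissue (Edema2, above),
#'   which is slightly T1w-hyperintense.
#' @return An object of class `threshold_config` (a named list).
#' @export
threshold_config <- function(adc_hemorrhage_max = 550,
                             adc_fluid_min = 2130,
                             t2w_hyper_cut = 250,
                             flair_bv_cut = 300,
                             flair_fluid_cut = 150,
                             flair_gmwm_cut = 250,
                             t1w_gmwm_cut = 450,
                             t1w_hemorrhage_cut = 600,
                             t1w_edema_cut = 345) {
  cfg <- list(
    adc_hemorrhage_max = adc_hemorrhage_max,
    adc_fluid_min = adc_fluid_min,
    t2w_hyper_cut = t2w_hyper_cut,
    flair_bv_cut = flair_bv_cut,
    flair_fluid_cut = flair_fluid_cut,
    flair_gmwm_cut = flair_gmwm_cut,
    t1w_gmwm_cut = t1w_gmwm_cut,
    t1w_hemorrhage_cut = t1w_hemorrhage_cut,
    t1w_edema_cut = t1w_edema_cut
  )
  if (any(!vapply(cfg, is.finite, logical(1))))
    stop("all thresholds must be finite")
  if (cfg$adc_hemorrhage_max >= cfg$adc_fluid_min)
    stop("adc_hemorrhage_max must be < adc_fluid_min")
  structure(cfg, class = "threshold_config")
}

#' Read / write a threshold configuration as YAML
#' @param cfg A [threshold_config()].
#' @param path File path.
#' @return `read_threshold_config` returns a `threshold_config`;
#'   `write_threshold_config` returns `path` invisibly.
#' @export
write_threshold_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_threshold_config
#' @export
read_threshold_config <- function(path) {
  do.call(threshold_config, yaml::read_yaml(path))
}

#' Split a calibrated stack into enhancing and non-enhancing voxels
#'
#' Computes the enhancement difference map `D = T1wCE - T1w` within the
#' brain mask and Otsu-thresholds its in-mask values: voxels with `D`
#' above the threshold form the enhancing set VOI8 (tumor rim and vessels),
#' the rest form VOI1. Otsu is applied once over the pooled 3-D in-mask
#' sample, not per slice.
#'
#' @param stack A calibrated [assemble_stack()] result.
#' @param n_bins Histogram bins for [otsu_threshold()].
#' @return List with logical arrays `voi8`, `voi1` (partitioning the brain
#'   mask) and the scalar `otsu_threshold`.
#' @export
split_enhancement <- function(stack, n_bins = 256L) {
  stopifnot(inherits(stack, "mpmri_stack"))
  d <- stack$t1wce$data - stack$t1w$data
  thr <- otsu_threshold(d[stack$brain_mask], n_bins = n_bins)
  voi8 <- stack$brain_mask & (d > thr)
  list(voi8 = voi8, voi1 = stack$brain_mask & !voi8, otsu_threshold = thr)
}

#' Tissuetype label map
#'
#' @param labels Integer 3-D array of [TISSUE_CODES].
#' @param spacing Voxel spacing in mm.
#' @param mode `"full"` (ADC rules active) or `"no_adc"`.
#' @param provenance List recording the [threshold_config()] and the Otsu
#'   threshold actually used.
#' @return Object of class `tissue_labels`.
#' @export
tissue_labels <- function(labels, spacing, mode = c("full", "no_adc"),
                          provenance = list()) {
  mode <- match.arg(mode)
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% TISSUE_CODES))
    stop("labels contain codes outside TISSUE_CODES")
  structure(
    list(labels = labels, spacing = as.numeric(spacing), mode = mode,
         provenance = provenance),
    class = "tissue_labels"
  )
}

#' @export
print.tissue_labels <- function(x, ...) {
  tab <- table(factor(tissue_name(x$labels), levels = names(TISSUE_CODES)))
  cat(sprintf("<tissue_labels> %s  mode %s\n",
              paste(dim(x$labels), collapse = "x"), x$mode))
  print(tab)
  invisible(x)
}

#' Classify every brain voxel into a tissuetype
#'
#' The core voxelwise decision tree over calibrated multiparametric MRI:
#'
#' 1. The T1wCE - T1w difference map is Otsu-split into enhancing (VOI8)
#'    and non-enhancing (VOI1) voxels.
#' 2. VOI8 voxels are contrast-enhancing tumor (CE) when calibrated FLAIR
#'    is at or above `flair_bv_cut` (tumor is FLAIR-bright), otherwise
#'    blood vessel (BV, FLAIR-dark).
#' 3. VOI1 voxels are split on calibrated T2w: below `t2w_hyper_cut` is the
#'    normal-brain set VOI2, above is the fluid/pathologic set VOI3.
#' 4. VOI2: white matter iff FLAIR below `flair_gmwm_cut` AND T1w above
#'    `t1w_gmwm_cut`, else gray matter. In full mode, any VOI2 voxel with
#'    ADC <= `adc_hemorrhage_max` is then overridden to hemorrhage.
#' 5. VOI3: fluid iff FLAIR below `flair_fluid_cut` OR (full mode and
#'    ADC >= `adc_fluid_min`); else hemorrhage iff (full mode and ADC <=
#'    `adc_hemorrhage_max`) OR T1w above `t1w_hemorrhage_cut`; the
#'    remainder is edematous ("high FLAIR") tissue. The fluid test takes
#'    precedence over the hemorrhage test.
#' 6. Edematous voxels with T1w above `t1w_edema_cut` are Edema2
#'    (leukoaraiosis-like, slightly T1w-hyperintense); the rest are Edema1
#'    (tumor-associated edema).
#'
#' When the stack has no ADC the ADC predicates are dropped entirely
#' (`mode = "no_adc"`); voxels whose ADC is flagged unavailable (see
#' [fit_adc()]) fall through to the intensity-only predicates
#' individually.
#'
#' All four structural modalities must carry a calibration record; the
#' labels are therefore invariant to per-modality affine distortions of
#' the raw scanner intensities.
#'
#' @param stack A calibrated [assemble_stack()] result.
#' @param cfg A [threshold_config()].
#' @param n_bins Histogram bins for the Otsu split.
#' @return A [tissue_labels()] map; provenance records the configuration
#'   and the Otsu threshold used.
#' @export
classify <- function(stack, cfg = threshold_config(), n_bins = 256L) {
  classify_impl(stack, cfg, use_adc = stack$adc_present, n_bins = n_bins)
}

#' Classify without ADC rules
#'
#' The same decision tree as [classify()] with every ADC predicate
#' omitted: hemorrhage can only arise from T1w hyperintensity and fluid
#' only from FLAIR hypointensity. Used when ADC maps are unavailable
#' (e.g. BraTS-style archival data). Refuses stacks that do contain ADC:
#' dropping it must be the caller's explicit decision.
#'
#' @inheritParams classify
#' @return A [tissue_labels()] map with `mode = "no_adc"`.
#' @export
classify_no_adc <- function(stack, cfg = threshold_config(), n_bins = 256L) {
  if (stack$adc_present)
    stop("stack contains ADC; drop it explicitly (adc = NULL) to run no-ADC mode")
  classify_impl(stack, cfg, use_adc = FALSE, n_bins = n_bins)
}

classify_impl <- function(stack, cfg, use_adc, n_bins = 256L) {
  stopifnot(inherits(stack, "mpmri_stack"), inherits(cfg, "threshold_config"))
  for (nm in c("t1w", "t1wce", "t2w", "flair")) {
    if (is.null(stack[[nm]]$calibration))
      stop("missing calibration record on ", nm,
           "; calibrate all structural modalities before classification")
  }
  mask <- stack$brain_mask
  t1w <- stack$t1w$data; flair <- stack$flair$data; t2w <- stack$t2w$data
  for (nm in c("t1w", "t1wce", "t2w", "flair")) {
    if (any(is.na(stack[[nm]]$data[mask])))
      stop("NaN voxels inside brain mask in ", nm)
  }
  enh <- split_enhancement(stack, n_bins = n_bins)

  if (use_adc) {
    if (is.null(stack$adc)) stop("full mode requires an ADC volume")
    adc <- stack$adc$data
    unavailable <- attr(stack$adc, "adc_unavailable") %||%
      array(FALSE, dim = dim(adc))
    adc_ok <- !unavailable & is.finite(adc)
  } else {
    adc <- array(NA_real_, dim = dim(t1w))
    adc_ok <- array(FALSE, dim = dim(t1w))
  }

  lab <- array(TISSUE_CODES[["Background"]], dim = dim(t1w))

  # enhancing voxels: CE vs BV on calibrated FLAIR
  lab[enh$voi8] <- ifelse(flair[enh$voi8] >= cfg$flair_bv_cut,
                          TISSUE_CODES[["CE"]], TISSUE_CODES[["BV"]])

  # non-enhancing: VOI2 (normal) vs VOI3 (fluid/pathologic) on T2w
  voi2 <- enh$voi1 & (t2w < cfg$t2w_hyper_cut)
  voi3 <- enh$voi1 & !voi2

  # VOI2: GM vs WM, then ADC hemorrhage override
  wm <- voi2 & (flair < cfg$flair_gmwm_cut) & (t1w > cfg$t1w_gmwm_cut)
  lab[voi2] <- TISSUE_CODES[["GM"]]
  lab[wm] <- TISSUE_CODES[["WM"]]
  hem2 <- voi2 & adc_ok & (adc <= cfg$adc_hemorrhage_max)
  lab[hem2] <- TISSUE_CODES[["Hemorrhage"]]

  # VOI3: fluid, then hemorrhage, then edema split
  fluid <- voi3 & ((flair < cfg$flair_fluid_cut) |
                     (adc_ok & adc >= cfg$adc_fluid_min))
  hem3 <- voi3 & !fluid & ((adc_ok & adc <= cfg$adc_hemorrhage_max) |
                             (t1w > cfg$t1w_hemorrhage_cut))
  edema <- voi3 & !fluid & !hem3
  lab[fluid] <- TISSUE_CODES[["Fluid"]]
  lab[hem3] <- TISSUE_CODES[["Hemorrhage"]]
  lab[edema] <- ifelse(t1w[edema] > cfg$t1w_edema_cut,
                       TISSUE_CODES[["Edema2"]], TISSUE_CODES[["Edema1"]])

  storage.mode(lab) <- "integer"
  tissue_labels(
    lab, spacing = stack$spacing,
    mode = if (use_adc) "full" else "no_adc",
    provenance = list(config = unclass(cfg),
                      otsu_threshold = enh$otsu_threshold,
                      otsu_bins = n_bins)
  )
}

#' Save a tissue label map with its legend sidecar
#'
#' Writes the integer label volume as NIfTI plus a `<path>.legend.tsv`
#' text sidecar mapping codes to tissuetype names and display colors, and a
#' `<path>.provenance.yaml` snapshot of the thresholds used.
#'
#' @param labels A [tissue_labels()].
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
save_labels <- function(labels, path) {
  stopifnot(inherits(labels, "tissue_labels"))
  save_volume(labels$labels, path, spacing = labels$spacing,
              datatype = "uint8")
  write_label_legend(paste0(path, ".legend.tsv"))
  yaml::write_yaml(c(list(mode = labels$mode), labels$provenance),
                   paste0(path, ".provenance.yaml"))
  invisible(path)
}
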