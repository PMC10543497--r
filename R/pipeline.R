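#' End-to-end single-scan pipeline
#'
#' Orchestrates calibrate -> (optional ADC fit) -> classify -> abVOI ->
#' volumes for one scan, from file paths. The configuration is a plain
#' list (or a YAML file via [read_run_config()]) with elements:
#'
#' * `paths`: named list of NIfTI paths — `t1w`, `t1wce`, `t2w`, `flair`,
#'   optionally `adc` or (`dwi_b0` + `dwi_b1000`), `brain_mask`,
#'   `manual_voi`, `ref_low_mask`, `ref_high_mask`.
#' * `calibration`: per-modality list of
#'   `list(ref_low, ref_high, target_low, target_high, statistic)` where
#'   the two reference names refer to mask paths `ref_csf_mask` /
#'   `ref_wm_mask` style entries in `paths`; or the simplified form used
#'   by [write_phantom()].
#' * `thresholds`: a [threshold_config()] (or its plain-list form).
#' * `b_value`: DWI b-value when fitting ADC (default 1000).
#' * `out_dir`: optional; when set, labels, reports and a provenance
#'   snapshot are written there.
#'
#' Each stage failure aborts with the stage name; the pipeline output is
#' identical to composing the stage functions by hand.
#'
#' @param config Configuration list as above.
#' @return List with `labels` (whole-brain [tissue_labels()]), `abvoi`
#'   ([build_abvoi()] result or `NULL` when no manual VOI was given),
#'   `volumes` (whole-brain tibble), `abvoi_volumes` (abVOI-scoped tibble
#'   or `NULL`), `otsu_threshold`, and `log` (per-stage provenance).
#' @export
run_scan <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  paths <- config$paths
  run_log <- list()

  rawv <- stage("load", {
    req <- c("t1w", "t1wce", "t2w", "flair")
    miss <- setdiff(req, names(paths))
    if (length(miss)) stop("missing path(s): ", paste(miss, collapse = ", "))
    tags <- c(t1w = "T1w", t1wce = "T1wCE", t2w = "T2w", flair = "FLAIR")
    lapply(stats::setNames(req, req), function(m)
      load_volume(paths[[m]], tags[[m]]))
  })
  brain_mask <- stage("brain-mask", {
    if (!is.null(paths$brain_mask))
      as_mask(load_volume(paths$brain_mask, "T2w")$data > 0)
    else NULL
  })
  ref_masks <- stage("calibration-masks", {
    list(csf = as_mask(load_volume(paths$ref_csf_mask, "T2w")$data > 0),
         wm = as_mask(load_volume(paths$ref_wm_mask, "T2w")$data > 0))
  })
  cal <- stage("calibrate", {
    out <- list()
    for (mod in c("t1w", "t1wce", "t2w", "flair")) {
      cc <- config$calibration[[mod]]
      if (is.null(cc)) stop("no calibration block for ", mod)
      low_is_csf <- grepl("csf|fluid", tolower(cc$ref_low))
      refs <- reference_pair(
        if (low_is_csf) ref_masks$csf else ref_masks$wm,
        if (low_is_csf) ref_masks$wm else ref_masks$csf,
        cc$target_low, cc$target_high,
        cc$ref_low, cc$ref_high,
        statistic = cc$statistic %||% "median")
      out[[mod]] <- calibrate(rawv[[mod]], refs)
    }
    out
  })
  for (mod in names(cal))
    run_log[[paste0("calibration_", mod)]] <- cal[[mod]]$calibration
  adc <- stage("adc", {
    if (!is.null(paths$adc)) {
      v <- load_volume(paths$adc, "ADC")
      v$calibration <- "physical-units"
      v
    } else if (!is.null(paths$dwi_b0) && !is.null(paths$dwi_b1000)) {
      fit_adc(dwi_pair(load_volume(paths$dwi_b0, "DWI_b0"),
                       load_volume(paths$dwi_b1000, "DWI_b1000"),
                       b1 = config$b_value %||% 1000))
    } else NULL
  })
  stack <- stage("assemble_stack", {
    vols <- cal
    if (!is.null(adc)) vols$adc <- adc
    assemble_stack(vols, brain_mask = brain_mask)
  })
  cfg <- stage("thresholds", {
    th <- config$thresholds %||% threshold_config()
    if (!inherits(th, "threshold_config")) th <- do.call(threshold_config, th)
    th
  })
  labels <- stage("classify", classify(stack, cfg))
  run_log$mode <- labels$mode
  run_log$otsu_threshold <- labels$provenance$otsu_threshold
  run_log$voxel_counts <- as.list(table(tissue_name(labels$labels)))

  abvoi <- NULL; ab_volumes <- NULL
  if (!is.null(paths$manual_voi)) {
    abvoi <- stage("abvoi", {
      voi <- as_mask(load_volume(paths$manual_voi, "T2w")$data > 0)
      build_abvoi(labels, voi)
    })
    ab_volumes <- stage("volumes-abvoi",
                        compute_volumes(abvoi$reclassified, abvoi$abvoi))
  }
  volumes <- stage("volumes", compute_volumes(labels))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    save_labels(labels, file.path(config$out_dir, "labels.nii.gz"))
    utils::write.table(volumes, file.path(config$out_dir, "volumes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ab_volumes)) {
      save_labels(abvoi$reclassified,
                  file.path(config$out_dir, "labels_abvoi_reclassified.nii.gz"))
      utils::write.table(ab_volumes,
                         file.path(config$out_dir, "volumes_abvoi.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    yaml::write_yaml(list(thresholds = unclass(cfg), log = run_log),
                     file.path(config$out_dir, "provenance.yaml"))
  }
  list(labels = labels, abvoi = abvoi, volumes = volumes,
       abvoi_volumes = ab_volumes, otsu_threshold = run_log$otsu_threshold,
       log = run_log)
}

#' Read a pipeline run configuration from YAML
#' @param path YAML file; relative paths resolve against its directory.
#' @return Configuration list for [run_scan()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  cfg$paths <- lapply(cfg$paths, function(p)
    if (file.exists(p)) p else file.path(base, p))
  if (!is.null(cfg$thresholds))
    cfg$thresholds <- do.call(threshold_config, cfg$thresholds)
  cfg
}

#' Longitudinal analysis: model selection and horizon accuracy
#'
#' Fits the TTP model on all records with observed progression by
#' exhaustive-subset selection under cross-validated AIC, predicts TTP at
#' every usable timepoint and tabulates binary progression-within-horizon
#' accuracy for each requested horizon (by default 30/60/90 days),
#' overall and per cohort when a `cohort` column is present.
#'
#' @param records A [scan_records()] table with `ttp_days`.
#' @param horizons Horizons in days.
#' @param k_folds,seed,candidate_vars Passed to [select_model()].
#' @return List with `model` (the selected [ttp_model()]), `records` (the
#'   fitted records with a `pred_ttp_days` column), and `accuracy` (tibble
#'   `cohort` x `horizon_days` x `accuracy`).
#' @export
run_longitudinal <- function(records, horizons = c(30, 60, 90),
                             k_folds = 10, seed = 1L,
                             candidate_vars = TTP_CANDIDATES) {
  records <- scan_records(records)
  model <- select_model(records, candidate_vars = candidate_vars,
                        k_folds = k_folds, seed = seed)
  usable <- records[!is.na(records$ttp_days), , drop = FALSE]
  usable$pred_ttp_days <- predict_ttp(model, usable)
  groups <- if ("cohort" %in% names(usable))
    split(usable, usable$cohort) else list(all = usable)
  acc <- purrr::map_dfr(names(groups), function(g) {
    df <- groups[[g]]
    tibble::tibble(
      cohort = g, horizon_days = horizons,
      accuracy = vapply(horizons, function(n)
        horizon_accuracy(df$ttp_days, df$pred_ttp_days, n), numeric(1))
    )
  })
  list(model = model, records = usable, accuracy = acc)
}

#' Validation-mode volumetrics against reference segmentations
#'
#' For a set of cases each carrying a tissuetype map and reference
#' ET/ED/NCR masks (e.g. BraTS-style ground truth, or phantom-derived
#' masks), computes per-case tissuetype volumes within the union abVOI,
#' cross-case Pearson correlations of CE vs ET volume and High FLAIR vs
#' ED volume, and the mean tissuetype composition of each reference
#' contour.
#'
#' @param cases List of lists, each with `labels` (a [tissue_labels()])
#'   and `et`, `ed`, `ncr` masks.
#' @return List with `volumes` (per-case tibble), `correlations` (tibble
#'   of pairwise R and p), and `composition` (mean percentage of each
#'   tissuetype within each reference contour).
#' @export
validate_segmentation <- function(cases) {
  stopifnot(length(cases) >= 3L)
  per_case <- purrr::imap_dfr(cases, function(cs, i) {
    ab <- build_abvoi_from_reference(cs$et, cs$ncr, cs$ed)
    vv <- prod(cs$labels$spacing) / 1000
    vols <- compute_volumes(cs$labels, ab)
    tibble::tibble(
      case = as.character(i),
      ce_cm3 = vols$volume_cm3[vols$tissue == "CE"],
      high_flair_cm3 = vols$volume_cm3[vols$tissue == "HighFLAIR"],
      fluid_cm3 = vols$volume_cm3[vols$tissue == "Fluid"],
      et_cm3 = sum(cs$et) * vv, ed_cm3 = sum(cs$ed) * vv,
      ncr_cm3 = sum(cs$ncr) * vv
    )
  })
  pairs <- list(c("ce_cm3", "et_cm3"), c("high_flair_cm3", "ed_cm3"),
                c("fluid_cm3", "ncr_cm3"))
  correlations <- purrr::map_dfr(pairs, function(pr) {
    ct <- stats::cor.test(per_case[[pr[1]]], per_case[[pr[2]]])
    tibble::tibble(tissue = pr[1], reference = pr[2],
                   estimate = unname(ct$estimate), p.value = ct$p.value)
  })
  comp <- purrr::map_dfr(c("et", "ed", "ncr"), function(ref) {
    rows <- purrr::imap_dfr(cases, function(cs, i) {
      if (!any(cs[[ref]])) return(NULL)
      cc <- composition(cs$labels, cs[[ref]])
      cc$case <- as.character(i); cc$reference <- ref
      cc
    })
    dplyr::summarise(dplyr::group_by(rows, .data$reference, .data$tissue),
                     mean_percent = mean(.data$percent), .groups = "drop")
  })
  list(volumes = per_case, correlations = correlations, composition = comp)
}
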