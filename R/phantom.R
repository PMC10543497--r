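#' Canonical per-tissue intensities of the digital brain phantom
#'
#' Mean intensity of each tissuetype on each modality, on the calibrated
#' scale (structural sequences) or in um^2/s (ADC). The values encode the
#' qualitative radiological contrasts the decision tree exploits:
#' enhancing tissue is bright on the T1wCE - T1w difference; tumor is
#' FLAIR-bright while vessels are FLAIR-dark; WM is darker than GM on
#' FLAIR and brighter on T1w; fluid is FLAIR-suppressed with free-water
#' ADC; hemorrhage has very low ADC and is T1w-bright; leukoaraiosis-like
#' Edema2 is slightly T1w-brighter than tumor-associated Edema1.
#'
#' @return Numeric matrix, tissues x modalities
#'   (`t1w`, `t1wce`, `t2w`, `flair`, `adc`).
#' @export
canonical_intensities <- function() {
  m <- rbind(
    GM         = c(400, 400, 150, 300,  900),
    WM         = c(500, 500, 100, 200,  800),
    Fluid      = c(150, 150, 800,  50, 3000),
    BV         = c(350, 850, 150, 100, 1000),
    CE         = c(350, 850, 350, 500, 1000),
    Edema1     = c(290, 290, 400, 600, 1300),
    Edema2     = c(400, 400, 400, 600, 1300),
    Hemorrhage = c(700, 700, 300, 400,  400)
  )
  colnames(m) <- c("t1w", "t1wce", "t2w", "flair", "adc")
  m
}

#' Per-modality noise level as a fraction of inter-tissue contrast
#'
#' The inter-tissue contrast of a modality is the span of its tissue mean
#' intensities. For ADC the span is taken over parenchymal tissues only
#' (free fluid excluded): the free-water endpoint near 3000 um^2/s would
#' otherwise imply a noise floor far beyond what diffusion imaging
#' exhibits, while every ADC decision margin lives in the parenchymal
#' 400-1300 um^2/s band.
#'
#' @param intensities Intensity matrix as from [canonical_intensities()].
#' @param frac Fraction of the per-modality contrast span.
#' @return Named numeric vector of Gaussian sigmas per modality.
#' @export
noise_at_contrast <- function(intensities = canonical_intensities(),
                              frac = 0.05) {
  out <- apply(intensities, 2, function(v) frac * diff(range(v)))
  parenchymal <- setdiff(rownames(intensities), "Fluid")
  out[["adc"]] <- frac * diff(range(intensities[parenchymal, "adc"]))
  out
}

#' Specification of a digital brain phantom
#'
#' The phantom is schematic anatomy sufficient to exercise a purely
#' voxelwise classifier: a brain ellipsoid with a GM shell and WM
#' interior, two CSF-filled ventricles, leukoaraiosis-like Edema2 patches
#' around them, a lesion made of a fluid core, a contrast-enhancing rim
#' and an Edema1 shell, a hemorrhagic focus inside the shell, and a
#' two-branch vessel tube. The per-tissue intensities must respect every
#' threshold ordering of the configuration the phantom will be classified
#' against; this is validated at construction and violations are reported
#' by name.
#'
#' @param dim Grid shape (default 96^3 voxels).
#' @param spacing Voxel spacing in mm (default 2 mm isotropic).
#' @param intensities Tissue x modality intensity matrix; see
#'   [canonical_intensities()].
#' @param noise_sigma Gaussian noise sigma per modality: a single number
#'   applied to all five, or a named vector over
#'   `c("t1w","t1wce","t2w","flair","adc")`. ADC noise is applied in the
#'   ADC domain and propagated into the synthesized DWI signals.
#' @param lesion_scale Multiplier on all lesion radii (varies tumor
#'   burden across phantoms).
#' @param with_lesion Set `FALSE` for a lesion-free brain (GM/WM/Fluid
#'   only).
#' @param raw_affine Optional named list of `c(gain, offset)` per
#'   structural modality, applied to the emitted raw intensities to
#'   emulate arbitrary scanner units (`gain > 0`).
#' @param config The [threshold_config()] the intensities are validated
#'   against.
#' @param seed Seed making the phantom fully deterministic.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(96, 96, 96), spacing = c(2, 2, 2),
                         intensities = canonical_intensities(),
                         noise_sigma = 0, lesion_scale = 1,
                         with_lesion = TRUE, raw_affine = NULL,
                         config = threshold_config(), seed = 1L) {
  dim <- as.integer(dim); stopifnot(length(dim) == 3L, all(dim >= 16L))
  spacing <- as.numeric(spacing); stopifnot(all(spacing > 0))
  mods <- c("t1w", "t1wce", "t2w", "flair", "adc")
  if (length(noise_sigma) == 1L && is.null(names(noise_sigma)))
    noise_sigma <- stats::setNames(rep(noise_sigma, 5L), mods)
  if (!all(mods %in% names(noise_sigma)))
    stop("noise_sigma must cover modalities: ", paste(mods, collapse = ", "))
  if (any(noise_sigma < 0)) stop("noise_sigma must be >= 0")
  if (!is.null(raw_affine)) {
    for (nm in names(raw_affine)) {
      if (!nm %in% c("t1w", "t1wce", "t2w", "flair"))
        stop("raw_affine applies to structural modalities only, not ", nm)
      if (raw_affine[[nm]][1] <= 0) stop("raw_affine gain must be > 0")
    }
  }
  validate_phantom_intensities(intensities, config)
  structure(
    list(dim = dim, spacing = spacing, intensities = intensities,
         noise_sigma = noise_sigma[mods], lesion_scale = lesion_scale,
         with_lesion = isTRUE(with_lesion), raw_affine = raw_affine,
         config = config, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Check every intensity ordering the decision tree relies on; stop with the
# name of the violated ordering.
validate_phantom_intensities <- function(m, cfg) {
  req <- function(ok, what) if (!ok) stop("phantom intensities violate ordering: ", what)
  d <- m[, "t1wce"] - m[, "t1w"]
  enh <- c("CE", "BV"); non <- setdiff(rownames(m), enh)
  req(min(d[enh]) > max(d[non]) && min(d[enh]) > 0,
      "enhancement gap (T1wCE - T1w larger for CE/BV than all other tissues)")
  req(m["CE", "flair"] >= cfg$flair_bv_cut, "CE calibrated FLAIR >= flair_bv_cut")
  req(m["BV", "flair"] < cfg$flair_bv_cut, "BV calibrated FLAIR < flair_bv_cut")
  req(all(m[c("GM", "WM"), "t2w"] < cfg$t2w_hyper_cut),
      "GM/WM calibrated T2w < t2w_hyper_cut")
  req(all(m[c("Fluid", "Edema1", "Edema2", "Hemorrhage"), "t2w"] >= cfg$t2w_hyper_cut),
      "Fluid/Edema/Hemorrhage calibrated T2w >= t2w_hyper_cut")
  req(m["WM", "flair"] < cfg$flair_gmwm_cut && m["WM", "t1w"] > cfg$t1w_gmwm_cut,
      "WM FLAIR < flair_gmwm_cut and T1w > t1w_gmwm_cut")
  req(m["GM", "flair"] >= cfg$flair_gmwm_cut || m["GM", "t1w"] <= cfg$t1w_gmwm_cut,
      "GM fails the WM rule (FLAIR >= flair_gmwm_cut or T1w <= t1w_gmwm_cut)")
  req(all(m[c("GM", "WM"), "adc"] > cfg$adc_hemorrhage_max),
      "GM/WM ADC > adc_hemorrhage_max")
  req(m["Fluid", "flair"] < cfg$flair_fluid_cut,
      "Fluid calibrated FLAIR < flair_fluid_cut")
  req(m["Fluid", "adc"] >= cfg$adc_fluid_min, "Fluid ADC >= adc_fluid_min")
  req(m["Hemorrhage", "flair"] >= cfg$flair_fluid_cut,
      "Hemorrhage calibrated FLAIR >= flair_fluid_cut")
  req(m["Hemorrhage", "adc"] < cfg$adc_fluid_min,
      "Hemorrhage ADC < adc_fluid_min")
  req(m["Hemorrhage", "adc"] <= cfg$adc_hemorrhage_max,
      "Hemorrhage ADC <= adc_hemorrhage_max")
  req(m["Hemorrhage", "t1w"] > cfg$t1w_hemorrhage_cut,
      "Hemorrhage calibrated T1w > t1w_hemorrhage_cut")
  for (e in c("Edema1", "Edema2")) {
    req(m[e, "flair"] >= cfg$flair_fluid_cut && m[e, "adc"] < cfg$adc_fluid_min,
        paste(e, "not captured by the fluid rule"))
    req(m[e, "adc"] > cfg$adc_hemorrhage_max && m[e, "t1w"] <= cfg$t1w_hemorrhage_cut,
        paste(e, "not captured by the hemorrhage rule"))
  }
  req(m["Edema1", "t1w"] <= cfg$t1w_edema_cut,
      "Edema1 calibrated T1w <= t1w_edema_cut")
  req(m["Edema2", "t1w"] > cfg$t1w_edema_cut,
      "Edema2 calibrated T1w > t1w_edema_cut")
  invisible(TRUE)
}

ellipsoid_mask <- function(coords, center, radii) {
  t1 <- ((coords$x - center[1]) / radii[1])^2
  t2 <- ((coords$y - center[2]) / radii[2])^2
  t3 <- ((coords$z - center[3]) / radii[3])^2
  outer(outer(t1, t2, "+"), t3, "+") <= 1
}

cylinder_z_mask <- function(coords, cx, cy, r, zmin, zmax) {
  xy <- outer((coords$x - cx)^2, (coords$y - cy)^2, "+") <= r^2
  zin <- coords$z >= zmin & coords$z <= zmax
  outer(xy, zin, "&")
}

#' Generate a digital brain phantom
#'
#' Builds the ground-truth tissuetype map, the raw (uncalibrated)
#' structural volumes, DWI b = 0 / b = 1000 signals synthesized from the
#' true ADC field by the monoexponential forward model, reference-tissue
#' calibration masks (normal WM and ventricular CSF), a loose manual
#' tumor VOI, and reference ET/ED/NCR masks derived from ground truth
#' (ET = enhancing rim, ED = edema shell, NCR = fluid core) for
#' validation-mode tests. Deterministic for a fixed spec seed.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `brain_phantom`: list with `raw` (named list
#'   of raw `mri_volume`s), `dwi` ([dwi_pair()]), `adc_true`, `truth`
#'   ([tissue_labels()]), `brain_mask`, `refs` (per-modality
#'   [reference_pair()]s), `manual_voi`, `reference_masks`
#'   (`et`, `ed`, `ncr`), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  d <- spec$dim; sp <- spec$spacing
  extent <- d * sp
  f <- min(extent)
  c0 <- extent / 2
  coords <- list(x = (seq_len(d[1]) - 0.5) * sp[1],
                 y = (seq_len(d[2]) - 0.5) * sp[2],
                 z = (seq_len(d[3]) - 0.5) * sp[3])

  brain_r <- 0.45 * extent
  # normalized ellipsoid radius, for the GM shell / WM interior split
  t1 <- ((coords$x - c0[1]) / brain_r[1])^2
  t2 <- ((coords$y - c0[2]) / brain_r[2])^2
  t3 <- ((coords$z - c0[3]) / brain_r[3])^2
  rn2 <- outer(outer(t1, t2, "+"), t3, "+")
  brain <- rn2 <= 1

  code <- TISSUE_CODES
  lab <- array(code[["Background"]], dim = d)
  lab[brain] <- code[["GM"]]
  lab[rn2 <= 0.82^2] <- code[["WM"]]

  vent_c <- list(c0 + c(-0.073, 0, 0) * f, c0 + c(0.073, 0, 0) * f)
  vent_r <- c(0.052, 0.135, 0.052) * f
  vent <- ellipsoid_mask(coords, vent_c[[1]], vent_r) |
    ellipsoid_mask(coords, vent_c[[2]], vent_r)
  vent <- vent & brain
  lab[vent] <- code[["Fluid"]]

  wm_region <- rn2 <= 0.82^2
  if (spec$with_lesion) {
    # periventricular leukoaraiosis-like patches
    halo_r <- c(0.083, 0.177, 0.083) * f
    halo <- (ellipsoid_mask(coords, vent_c[[1]], halo_r) |
               ellipsoid_mask(coords, vent_c[[2]], halo_r)) & !vent & wm_region
    lab[halo] <- code[["Edema2"]]

    s <- spec$lesion_scale
    les_c <- c0 + c(0.167, 0.0625, 0) * f
    hem <- ellipsoid_mask(coords, les_c + c(0.12 * f * s, 0, 0),
                          rep(0.031 * f * s, 3)) & brain
    core <- ellipsoid_mask(coords, les_c, rep(0.052 * f * s, 3)) & !hem
    rim <- ellipsoid_mask(coords, les_c, rep(0.0885 * f * s, 3)) &
      !core & !hem
    shell <- ellipsoid_mask(coords, les_c, rep(0.156 * f * s, 3)) &
      !core & !rim & !hem
    shell <- shell & brain; rim <- rim & brain; core <- core & brain
    lab[shell] <- code[["Edema1"]]
    lab[rim] <- code[["CE"]]
    lab[core] <- code[["Fluid"]]
    lab[hem] <- code[["Hemorrhage"]]
  } else {
    core <- rim <- shell <- hem <- array(FALSE, dim = d)
    les_c <- c0
    s <- spec$lesion_scale
  }

  # vessel tree: two trunks and a branch skirting the lesion (together with
  # the enhancing rim a few percent of brain volume, as for real
  # vasculature); vessels overwrite normal brain and edema but not tumor
  # core/rim or hemorrhage
  trunk <- cylinder_z_mask(coords, c0[1] - 0.135 * f, c0[2], 0.03 * f,
                           c0[3] - 0.25 * f, c0[3] + 0.25 * f) |
    cylinder_z_mask(coords, c0[1] + 0.05 * f, c0[2] - 0.17 * f, 0.03 * f,
                    c0[3] - 0.25 * f, c0[3] + 0.25 * f)
  branch <- cylinder_z_mask(coords, les_c[1], les_c[2] - 0.104 * f,
                            0.016 * f, c0[3] - 0.156 * f, c0[3] + 0.156 * f)
  vessel <- (trunk | branch) & brain &
    array(lab %in% code[c("GM", "WM", "Edema1", "Edema2")], dim = d)
  lab[vessel] <- code[["BV"]]

  storage.mode(lab) <- "integer"
  truth <- tissue_labels(lab, spacing = sp, mode = "full",
                         provenance = list(source = "phantom ground truth",
                                           seed = spec$seed))

  # reference-tissue masks from ground truth: a normal-WM ball and
  # ventricular CSF
  wm_ball <- ellipsoid_mask(coords, c0 + c(-0.1875, -0.1875, 0) * f,
                            rep(0.0365 * f, 3))
  ref_wm <- wm_ball & (lab == code[["WM"]])
  ref_csf <- vent & (lab == code[["Fluid"]])
  stopifnot(any(ref_wm), any(ref_csf))

  # emit intensities: canonical mean + Gaussian noise, then optional
  # scanner-unit affine distortion per structural modality
  m <- spec$intensities
  ns <- spec$noise_sigma
  n_vox <- prod(d)
  make_field <- function(modality) {
    vals <- array(0, dim = d)
    for (t in rownames(m)) {
      idx <- lab == code[[t]]
      vals[idx] <- m[t, modality]
    }
    if (ns[[modality]] > 0)
      vals[brain] <- vals[brain] + stats::rnorm(sum(brain), 0, ns[[modality]])
    vals
  }
  raw <- list()
  for (mod in c("t1w", "t1wce", "t2w", "flair")) {
    vals <- make_field(mod)
    ab <- spec$raw_affine[[mod]] %||% c(1, 0)
    vals <- ab[1] * vals + ab[2]
    tag <- c(t1w = "T1w", t1wce = "T1wCE", t2w = "T2w", flair = "FLAIR")[[mod]]
    raw[[mod]] <- mri_volume(vals, spacing = sp, modality = tag)
  }

  adc_field <- make_field("adc")
  adc_field[brain] <- pmax(adc_field[brain], 1)  # physical ADC is positive
  adc_true <- mri_volume(adc_field, spacing = sp, modality = "ADC",
                         calibration = "physical-units")
  # DWI forward model: S(b) = S0 exp(-b * ADC), ADC in mm^2/s
  s0 <- array(0, dim = d); s0[brain] <- 1200
  sb <- s0 * exp(-1000 * adc_field * 1e-6)
  dwi <- dwi_pair(mri_volume(s0, sp, "DWI_b0"),
                  mri_volume(sb, sp, "DWI_b1000"), b1 = 1000)

  # per-modality calibration references: CSF and WM, targets = canonical
  refs <- list()
  for (mod in c("t1w", "t1wce", "t2w", "flair")) {
    csf_t <- m["Fluid", mod]; wm_t <- m["WM", mod]
    if (csf_t < wm_t) {
      refs[[mod]] <- reference_pair(ref_csf, ref_wm, csf_t, wm_t,
                                    "ventricular CSF", "normal WM")
    } else {
      refs[[mod]] <- reference_pair(ref_wm, ref_csf, wm_t, csf_t,
                                    "normal WM", "ventricular CSF")
    }
  }

  manual_voi <- ellipsoid_mask(coords, les_c, rep(0.198 * f * s, 3)) & brain
  if (!spec$with_lesion) manual_voi <- array(FALSE, dim = d)

  structure(
    list(raw = raw, dwi = dwi, adc_true = adc_true,
         brain_mask = brain, truth = truth, refs = refs,
         manual_voi = manual_voi,
         reference_masks = list(et = rim, ed = shell, ncr = core),
         spec = spec),
    class = "brain_phantom"
  )
}

#' Calibrate a phantom and assemble its multiparametric stack
#'
#' Runs two-point calibration of the four structural volumes against the
#' phantom's reference masks, optionally fits the ADC map from the
#' synthesized DWI pair, and assembles the stack.
#'
#' @param phantom A [generate_phantom()] result.
#' @param with_adc Include the ADC map (fitted from DWI)? Set `FALSE` to
#'   produce a stack for no-ADC mode.
#' @return An `mpmri_stack`.
#' @export
phantom_stack <- function(phantom, with_adc = TRUE) {
  stopifnot(inherits(phantom, "brain_phantom"))
  vols <- list(
    t1w = calibrate(phantom$raw$t1w, phantom$refs$t1w),
    t1wce = calibrate(phantom$raw$t1wce, phantom$refs$t1wce),
    t2w = calibrate(phantom$raw$t2w, phantom$refs$t2w),
    flair = calibrate(phantom$raw$flair, phantom$refs$flair)
  )
  if (with_adc) vols$adc <- fit_adc(phantom$dwi)
  assemble_stack(vols, brain_mask = phantom$brain_mask)
}

#' Write a phantom to disk as NIfTI volumes and masks
#'
#' Emits raw structural volumes, the DWI pair, brain and reference masks,
#' the manual VOI, ground-truth labels (with legend sidecar) and the
#' reference ET/ED/NCR masks, plus a `calibration.yaml` with the
#' per-modality reference targets.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "brain_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  for (mod in names(phantom$raw))
    save_volume(phantom$raw[[mod]], p(paste0(mod, ".nii.gz")))
  save_volume(phantom$dwi$s0, p("dwi_b0.nii.gz"))
  save_volume(phantom$dwi$sb, p("dwi_b1000.nii.gz"))
  sp <- phantom$spec$spacing
  save_volume(phantom$brain_mask, p("brain_mask.nii.gz"), spacing = sp)
  save_volume(phantom$manual_voi, p("manual_voi.nii.gz"), spacing = sp)
  for (nm in names(phantom$reference_masks))
    save_volume(phantom$reference_masks[[nm]],
                p(paste0("reference_", nm, ".nii.gz")), spacing = sp)
  save_labels(phantom$truth, p("truth_labels.nii.gz"))
  # calibration reference masks + targets
  first <- phantom$refs$t1w
  low_is_csf <- identical(first$name_low, "ventricular CSF")
  save_volume(if (low_is_csf) first$mask_low else first$mask_high,
              p("ref_csf_mask.nii.gz"), spacing = sp)
  save_volume(if (low_is_csf) first$mask_high else first$mask_low,
              p("ref_wm_mask.nii.gz"), spacing = sp)
  cal <- lapply(phantom$refs, function(r)
    list(ref_low = r$name_low, ref_high = r$name_high,
         target_low = r$target_low, target_high = r$target_high,
         statistic = r$statistic))
  yaml::write_yaml(cal, p("calibration.yaml"))
  invisible(dir)
}

#' Generate a synthetic longitudinal cohort of scan records
#'
#' Emulates a serial-imaging treatment study: each patient is scanned on a
#' monotone grid of on-treatment days (roughly every 4-6 weeks) with
#' smoothly varying abVOI tissue volumes (baseline + linear trend + a slow
#' sinusoidal component), and the observed TTP at each timepoint is the
#' truth model's prediction plus Gaussian noise. Post-progression
#' timepoints may carry negative TTP, as in real trial data.
#'
#' @param truth_model A [ttp_model()] generating the TTP (default: the
#'   bundled reference coefficients, see [reference_ttp_model()]).
#' @param n_patients,scans_per_patient Cohort shape.
#' @param noise_sigma_days Gaussian sigma of the TTP noise in days.
#' @param seed Seed; the cohort is fully deterministic given it.
#' @return A [scan_records()] tibble with `ttp_days` present on every row.
#' @export
generate_cohort <- function(truth_model = reference_ttp_model(),
                            n_patients = 20, scans_per_patient = 10,
                            noise_sigma_days = 10, seed = 1L) {
  stopifnot(inherits(truth_model, "ttp_model"), n_patients >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  traj <- function(n, t, base_rng, slope_rng, amp_rng) {
    base <- stats::runif(1, base_rng[1], base_rng[2])
    slope <- stats::runif(1, slope_rng[1], slope_rng[2])
    amp <- stats::runif(1, amp_rng[1], amp_rng[2])
    phase <- stats::runif(1, 0, 2 * pi)
    pmax(base + slope * t + amp * sin(2 * pi * t / 300 + phase), 0)
  }
  rows <- lapply(seq_len(n_patients), function(i) {
    t <- cumsum(stats::runif(scans_per_patient, 28, 42))
    tibble::tibble(
      patient_id = sprintf("P%02d", i),
      scan_date = as.Date("2016-01-01") + round(t),
      t_C1D1 = t,
      ce_cm3 = traj(scans_per_patient, t, c(2, 30), c(-0.04, 0.08), c(0, 3)),
      fluid_cm3 = traj(scans_per_patient, t, c(1, 15), c(-0.02, 0.04), c(0, 2)),
      edema1_cm3 = traj(scans_per_patient, t, c(5, 40), c(-0.05, 0.05), c(0, 4)),
      edema2_cm3 = traj(scans_per_patient, t, c(2, 20), c(-0.02, 0.02), c(0, 2))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$high_flair_cm3 <- out$edema1_cm3 + out$edema2_cm3
  mu <- predict_ttp(truth_model, out)
  out$ttp_days <- mu + stats::rnorm(nrow(out), 0, noise_sigma_days)
  scan_records(out)
}

#' Reference TTP model coefficients
#'
#' The multivariable linear model relating TTP (days) to time on
#' treatment and abVOI volumes:
#' `TTP = 205.6 - 0.6 * t_C1D1 - 2.5 * CE + 4.8 * Fluid`,
#' with CE and Fluid in cm^3. Used as the default generating truth of
#' [generate_cohort()] and available for direct prediction.
#'
#' @return A [ttp_model()].
#' @export
reference_ttp_model <- function() {
  ttp_model(intercept = 205.6,
            coefficients = c(t_C1D1 = -0.6, ce_cm3 = -2.5, fluid_cm3 = 4.8))
}
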