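tissue_name_of <- function(code) names(TISSUE_CODES)[match(code, TISSUE_CODES)]

# Build a stack straight from calibrated-scale arrays (fake calibration
# records), for voxel-level rule checks.
probe_stack <- function(t1w, t2w, flair, adc = NULL, t1wce = NULL) {
  d <- dim(t1w)
  fake_cal <- list(ref_low = "csf", ref_high = "wm", gain = 1, offset = 0)
  mk <- function(a, mod) {
    v <- mri_volume(a, c(2, 2, 2), mod)
    v$calibration <- if (mod == "ADC") "physical-units" else fake_cal
    v
  }
  if (is.null(t1wce)) t1wce <- t1w
  vols <- list(t1w = mk(t1w, "T1w"), t1wce = mk(t1wce, "T1wCE"),
               t2w = mk(t2w, "T2w"), flair = mk(flair, "FLAIR"))
  if (!is.null(adc)) vols$adc <- mk(adc, "ADC")
  assemble_stack(vols, brain_mask = array(TRUE, dim = d))
}

# WM-filled probe arrays with an enhancing corner so the Otsu split is
# well-posed; probe voxel at [1,1,1]
probe_arrays <- function() {
  d <- c(6, 6, 6)
  m <- canonical_intensities()
  t1w <- array(m["WM", "t1w"], d); t2w <- array(m["WM", "t2w"], d)
  flair <- array(m["WM", "flair"], d); adc <- array(m["WM", "adc"], d)
  flair[, , 6] <- m["CE", "flair"]  # slab becomes enhancing in probe_label
  list(t1w = t1w, t2w = t2w, flair = flair, adc = adc)
}

probe_label <- function(a, adc = TRUE) {
  t1wce <- a$t1w
  t1wce[, , 6] <- a$t1w[, , 6] + 350  # enhancing slab, zero diff elsewhere
  st <- probe_stack(a$t1w, a$t2w, a$flair,
                    adc = if (adc) a$adc else NULL, t1wce = t1wce)
  lab <- if (adc) classify(st) else classify_no_adc(st)
  names(TISSUE_CODES)[match(lab$labels[1, 1, 1], TISSUE_CODES)]
}

test_that("ADC rules in the fluid/pathologic branch follow the cutoffs", {
  a <- probe_arrays()
  # hyperintense on T2w puts the probe in VOI3; FLAIR above the fluid cut
  a$t2w[1, 1, 1] <- 400; a$flair[1, 1, 1] <- 600; a$t1w[1, 1, 1] <- 290
  a$adc[1, 1, 1] <- 2200
  expect_identical(probe_label(a), "Fluid")       # high ADC -> fluid
  a$adc[1, 1, 1] <- 2130
  expect_identical(probe_label(a), "Fluid")       # inclusive cutoff
  a$adc[1, 1, 1] <- 500
  expect_identical(probe_label(a), "Hemorrhage")  # very low ADC
  a$adc[1, 1, 1] <- 550
  expect_identical(probe_label(a), "Hemorrhage")  # inclusive cutoff
  a$adc[1, 1, 1] <- 1300
  expect_identical(probe_label(a), "Edema1")      # mid ADC -> edematous
  a$t1w[1, 1, 1] <- 400
  expect_identical(probe_label(a), "Edema2")      # T1w-brighter edema
  a$t1w[1, 1, 1] <- 700
  expect_identical(probe_label(a), "Hemorrhage")  # T1w-hyperintense
})

test_that("fluid test precedes hemorrhage test in VOI3", {
  a <- probe_arrays()
  # FLAIR-dark and T1w-bright: fluid rule fires first
  a$t2w[1, 1, 1] <- 800; a$flair[1, 1, 1] <- 50; a$t1w[1, 1, 1] <- 700
  a$adc[1, 1, 1] <- 3000
  expect_identical(probe_label(a), "Fluid")
})

test_that("no-ADC mode drops exactly the ADC predicates", {
  a <- probe_arrays()
  a$t2w[1, 1, 1] <- 400; a$flair[1, 1, 1] <- 600; a$t1w[1, 1, 1] <- 290
  a$adc[1, 1, 1] <- 2200
  expect_identical(probe_label(a, adc = FALSE), "Edema1")  # no high-ADC fluid rule
  # FLAIR-dark cavity stays fluid without ADC
  a$flair[1, 1, 1] <- 50
  expect_identical(probe_label(a, adc = FALSE), "Fluid")
  # T1w-hyperintensity rule still catches hemorrhage without ADC
  a$flair[1, 1, 1] <- 600; a$t1w[1, 1, 1] <- 700
  expect_identical(probe_label(a, adc = FALSE), "Hemorrhage")
})

test_that("classify_no_adc refuses a stack that carries ADC", {
  a <- probe_arrays()
  t1wce <- a$t1w; t1wce[, , 6] <- a$t1w[, , 6] + 350
  st <- probe_stack(a$t1w, a$t2w, a$flair, adc = a$adc, t1wce = t1wce)
  expect_error(classify_no_adc(st), "drop it explicitly")
})

test_that("classification requires calibration records", {
  ph <- tiny_phantom()
  vols <- list(t1w = ph$raw$t1w,  # raw, uncalibrated
               t1wce = calibrate(ph$raw$t1wce, ph$refs$t1wce),
               t2w = calibrate(ph$raw$t2w, ph$refs$t2w),
               flair = calibrate(ph$raw$flair, ph$refs$flair))
  st <- assemble_stack(vols, brain_mask = ph$brain_mask)
  expect_error(classify(st), "calibration record on t1w")
})

test_that("zero-noise phantom is reproduced exactly, and labels partition the brain", {
  ph <- tiny_phantom()
  lab <- tiny_labels()
  expect_identical(lab$labels, ph$truth$labels)
  expect_true(all(dice_per_class(lab$labels, ph$truth$labels) == 1))
  # partition: every brain voxel labeled, every outside voxel background
  expect_true(all(lab$labels[ph$brain_mask] != TISSUE_CODES[["Background"]]))
  expect_true(all(lab$labels[!ph$brain_mask] == TISSUE_CODES[["Background"]]))
  expect_identical(lab$mode, "full")
  # provenance carries thresholds and the Otsu cut actually used
  expect_equal(lab$provenance$config$adc_fluid_min, 2130)
  expect_true(is.numeric(lab$provenance$otsu_threshold))
})

test_that("no-ADC phantom labels differ from full mode only on ADC-dependent voxels", {
  ph <- tiny_phantom()
  full <- tiny_labels()
  no_adc <- classify_no_adc(phantom_stack(ph, with_adc = FALSE))
  expect_identical(no_adc$mode, "no_adc")
  diff_vox <- which(full$labels != no_adc$labels)
  # the phantom's hemorrhage focus is T1w-bright, its fluid FLAIR-dark:
  # every label is decidable without ADC, so modes agree everywhere
  expect_length(diff_vox, 0)
  # in no-ADC mode hemorrhage can only come from the T1w rule
  m <- canonical_intensities()
  st <- phantom_stack(ph, with_adc = FALSE)
  hem <- no_adc$labels == TISSUE_CODES[["Hemorrhage"]]
  expect_true(all(st$t1w$data[hem] >
                    no_adc$provenance$config$t1w_hemorrhage_cut))
})

test_that("split_enhancement is invariant to a common additive offset", {
  st <- tiny_stack()
  e1 <- split_enhancement(st)
  st2 <- st
  st2$t1w$data <- st$t1w$data + 123
  st2$t1wce$data <- st$t1wce$data + 123
  e2 <- split_enhancement(st2)
  expect_identical(e1$voi8, e2$voi8)
  expect_equal(e1$otsu_threshold, e2$otsu_threshold)
  # partition of the brain mask
  expect_identical(e1$voi8 | e1$voi1, st$brain_mask)
  expect_false(any(e1$voi8 & e1$voi1))
  # no contrast -> error
  st3 <- st; st3$t1wce <- st3$t1w
  expect_error(split_enhancement(st3), "no contrast")
})

test_that("enhancing set matches the phantom's rim and vessels at zero noise", {
  ph <- tiny_phantom()
  e <- split_enhancement(tiny_stack())
  truth_enh <- array(ph$truth$labels %in% TISSUE_CODES[c("CE", "BV")],
                     dim = dim(ph$truth$labels))
  expect_identical(e$voi8, truth_enh)
})

test_that("raising the fluid cut or lowering the hemorrhage cut is monotone", {
  st <- tiny_stack()
  base <- classify(st)
  n_fluid <- function(l) sum(l$labels == TISSUE_CODES[["Fluid"]])
  n_hem <- function(l) sum(l$labels == TISSUE_CODES[["Hemorrhage"]])
  for (delta in c(200, 900)) {
    up <- classify(st, threshold_config(adc_fluid_min = 2130 + delta))
    expect_lte(n_fluid(up), n_fluid(base))
    down <- classify(st, threshold_config(adc_hemorrhage_max = 550 - delta / 2))
    expect_lte(n_hem(down), n_hem(base))
  }
})

test_that("classification is deterministic", {
  st <- tiny_stack()
  expect_identical(classify(st)$labels, classify(st)$labels)
})

test_that("voxels with unavailable ADC fall through to intensity rules", {
  a <- probe_arrays()
  a$t2w[1, 1, 1] <- 400; a$flair[1, 1, 1] <- 600; a$t1w[1, 1, 1] <- 290
  a$adc[1, 1, 1] <- 0  # would be hemorrhage if ADC were trusted
  t1wce <- a$t1w; t1wce[, , 6] <- a$t1w[, , 6] + 350
  st <- probe_stack(a$t1w, a$t2w, a$flair, adc = a$adc, t1wce = t1wce)
  flag <- array(FALSE, dim = dim(a$adc)); flag[1, 1, 1] <- TRUE
  attr(st$adc, "adc_unavailable") <- flag
  lab <- classify(st)
  expect_identical(tissue_name_of(lab$labels[1, 1, 1]), "Edema1")
})

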