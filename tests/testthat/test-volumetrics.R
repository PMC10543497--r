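test_that("volumes convert voxel counts to cm^3 and derive High FLAIR", {
  lab <- array(0L, dim = c(20, 20, 20))
  lab[1:10, 1:10, 1:10] <- TISSUE_CODES[["CE"]]       # 1000 voxels
  lab[11:20, 1:5, 1] <- TISSUE_CODES[["Edema1"]]      # 50
  lab[11:20, 6:11, 1] <- TISSUE_CODES[["Edema2"]]     # 60
  tl <- tissue_labels(lab, spacing = c(1, 1, 1))
  v <- compute_volumes(tl)
  expect_equal(v$volume_cm3[v$tissue == "CE"], 1.0)
  expect_equal(v$volume_cm3[v$tissue == "HighFLAIR"],
               v$volume_cm3[v$tissue == "Edema1"] +
                 v$volume_cm3[v$tissue == "Edema2"])
  expect_equal(v$voxels[v$tissue == "HighFLAIR"], 110)
  # empty labels -> all zeros
  v0 <- compute_volumes(tissue_labels(array(0L, c(4, 4, 4)), c(1, 1, 1)))
  expect_true(all(v0$volume_cm3 == 0))
})

test_that("phantom volumes match ground-truth tallies; scoped <= whole-brain", {
  ph <- tiny_phantom()
  v <- compute_volumes(ph$truth)
  vv <- prod(ph$spec$spacing) / 1000
  for (t in setdiff(names(TISSUE_CODES), "Background")) {
    expect_equal(v$volume_cm3[v$tissue == t],
                 sum(ph$truth$labels == TISSUE_CODES[[t]]) * vv)
  }
  vs <- compute_volumes(ph$truth, ph$manual_voi)
  expect_true(all(vs$volume_cm3 <= v$volume_cm3))
  expect_true(all(v$volume_cm3 >= 0))
})

test_that("abVOI reclassifies BV to CE inside, conserving total labeled volume", {
  ph <- tiny_phantom()
  lab <- tiny_labels()
  ab <- build_abvoi(lab, ph$manual_voi)
  # abVOI restricted to abnormal tissuetypes inside the manual contour
  expect_true(all(ab$abvoi <= ph$manual_voi))
  before <- lab$labels[ab$abvoi]
  expect_true(all(before %in% TISSUE_CODES[c("BV", "CE", "Edema1",
                                             "Edema2", "Fluid")]))
  # no BV left inside, CE grows by exactly the reclassified count
  after <- ab$reclassified$labels
  expect_false(any(after[ab$abvoi] == TISSUE_CODES[["BV"]]))
  n_bv <- sum(before == TISSUE_CODES[["BV"]])
  expect_gt(n_bv, 0)  # the phantom routes a vessel branch through the VOI
  expect_equal(ab$n_reclassified, n_bv)
  expect_equal(sum(after == TISSUE_CODES[["CE"]]),
               sum(lab$labels == TISSUE_CODES[["CE"]]) + n_bv)
  # labels outside the abVOI untouched
  expect_identical(after[!ab$abvoi], lab$labels[!ab$abvoi])
  # conservation: total labeled voxel count unchanged
  expect_equal(sum(after != 0L), sum(lab$labels != 0L))
  v1 <- compute_volumes(lab); v2 <- compute_volumes(ab$reclassified)
  expect_equal(sum(v1$volume_cm3[v1$tissue != "HighFLAIR"]),
               sum(v2$volume_cm3[v2$tissue != "HighFLAIR"]))
})

test_that("manual VOI over normal brain yields an empty abVOI with a warning", {
  lab <- array(TISSUE_CODES[["WM"]], dim = c(8, 8, 8))
  tl <- tissue_labels(lab, spacing = c(1, 1, 1))
  voi <- array(TRUE, dim = c(8, 8, 8))
  expect_warning(ab <- build_abvoi(tl, voi), "empty abVOI")
  expect_equal(sum(ab$abvoi), 0)
})

test_that("whole-brain manual VOI selects all abnormal+vascular+fluid voxels", {
  ph <- tiny_phantom()
  lab <- tiny_labels()
  ab <- build_abvoi(lab, array(TRUE, dim = dim(lab$labels)))
  expected <- array(lab$labels %in% TISSUE_CODES[c("BV", "CE", "Edema1",
                                                   "Edema2", "Fluid")],
                    dim = dim(lab$labels))
  expect_identical(ab$abvoi, expected)
})

test_that("reference-union abVOI honors emptiness and reports overlap", {
  ph <- tiny_phantom()
  rm <- ph$reference_masks
  u <- build_abvoi_from_reference(rm$et, rm$ncr, rm$ed)
  expect_identical(unclass(u) & TRUE, rm$et | rm$ncr | rm$ed)
  expect_equal(attr(u, "overlap_voxels"), 0)
  # empty ED -> union of the other two
  u2 <- build_abvoi_from_reference(rm$et, rm$ncr, NULL)
  expect_identical(u2 & TRUE, rm$et | rm$ncr)
  # overlapping labels are tolerated and counted
  expect_message(u3 <- build_abvoi_from_reference(rm$et, rm$et, NULL),
                 "overlapping")
  expect_equal(attr(u3, "overlap_voxels"), sum(rm$et))
})

test_that("composition percentages are exact and sum to 100", {
  lab <- array(TISSUE_CODES[["Fluid"]], dim = c(10, 10, 10))
  lab[1:5, , ] <- TISSUE_CODES[["CE"]]
  tl <- tissue_labels(lab, spacing = c(1, 1, 1))
  ref <- array(TRUE, dim = dim(lab))
  cc <- composition(tl, ref)
  expect_equal(cc$percent[cc$tissue == "CE"], 50)
  expect_equal(cc$percent[cc$tissue == "Fluid"], 50)
  expect_equal(sum(cc$percent), 100, tolerance = 1e-9)
  # reference exactly covering CE -> 100%
  cc2 <- composition(tl, lab == TISSUE_CODES[["CE"]])
  expect_equal(cc2$percent[cc2$tissue == "CE"], 100)
  expect_error(composition(tl, array(FALSE, dim = dim(lab))), "empty")
  # phantom ET-like mask matches ground-truth tally
  ph <- tiny_phantom()
  cc3 <- composition(ph$truth, ph$reference_masks$et)
  expect_equal(cc3$percent[cc3$tissue == "CE"], 100)
  expect_equal(sum(cc3$percent), 100, tolerance = 1e-9)
})
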