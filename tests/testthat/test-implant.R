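test_that("MA implantation removes the ACL and keeps the other 7 bundles", {
  m <- default_patient_model()
  ma <- default_ma_model()
  expect_equal(ma$state, "implanted")
  expect_setequal(ma$ligaments$name,
                  c("PCL", "dMCL", "sMCL", "LCL", "ALL", "OPL", "PC"))
  kept <- m$ligaments[m$ligaments$name != "ACL", ]
  rownames(kept) <- rownames(ma$ligaments) <- NULL
  expect_identical(ma$ligaments, kept)
  expect_error(ma_baseline(m, insert_thickness = 0), "thickness")
  expect_error(ma_baseline(ma), "pre-diseased")
})

test_that("the MA knee deviates from the pre-diseased knee", {
  rep <- build_report(default_pre_trace(), default_ma_trace())
  expect_gt(min(rep$kinematic), 0)
  expect_gt(min(rep$strain_pct), 0)
  # strain deviations of single-percent order
  expect_gt(max(rep$strain_pct), 0.5)
  expect_lt(max(rep$strain_pct), 10)
})

test_that("the zero placement is the identity on an implanted knee", {
  ma <- default_ma_model()
  m0 <- apply_placement(ma, rep(0, 9))
  expect_identical(m0$contact, ma$contact)
  expect_identical(m0$ligaments, ma$ligaments)
})

test_that("pure translations invert under the negated placement", {
  ma <- default_ma_model()
  x <- implant_placement(fem_ap = 2.5, fem_lm = -1.5, fem_pd = 3)
  m2 <- apply_placement(apply_placement(ma, x), -unclass(x))
  expect_equal(m2$contact$sphere_center, ma$contact$sphere_center,
               tolerance = 1e-9)
  expect_equal(m2$contact$surface, ma$contact$surface, tolerance = 1e-9)
})

test_that("single-axis rotations invert under the negated placement", {
  ma <- default_ma_model()
  for (par in c("fem_fe", "fem_ei", "fem_vv", "tib_fe", "tib_ei", "tib_vv")) {
    x <- stats::setNames(rep(0, 9), tkaplan:::PLACEMENT_NAMES)
    x[par] <- 2.5
    m2 <- apply_placement(apply_placement(ma, x), -x)
    expect_equal(m2$contact$sphere_center, ma$contact$sphere_center,
                 tolerance = 1e-9)
    expect_equal(m2$contact$tib_rot, ma$contact$tib_rot, tolerance = 1e-9)
  }
})

test_that("placements move the components in the stated directions", {
  ma <- default_ma_model()
  # posterior (positive ap) moves sphere centres toward -x
  mp <- apply_placement(ma, implant_placement(fem_ap = 3))
  expect_equal(mp$contact$sphere_center[, 1],
               ma$contact$sphere_center[, 1] - 3)
  # proximal moves +y, medial moves -z
  mq <- apply_placement(ma, implant_placement(fem_pd = 2, fem_lm = 1))
  expect_equal(mq$contact$sphere_center[, 2],
               ma$contact$sphere_center[, 2] + 2)
  expect_equal(mq$contact$sphere_center[, 3],
               ma$contact$sphere_center[, 3] - 1)
  # tibial FE (slope) tilts the insert frame about z
  mt <- apply_placement(ma, implant_placement(tib_fe = 5))
  expect_equal(mt$contact$tib_rot,
               tkaplan:::component_rotation(5, 0, 0), tolerance = 1e-12)
})

reported_placements <- list(
  ST1 = c(-2.8, -0.2, 3.9, -1.4, -0.2, -1.2, 5.2, 2.8, 2.2),
  ST2 = c(-1.7, -1.8, 3.6, -1.5, -1.6, -1.5, 0.9, 2.8, -1.9),
  ST3 = c(-1.1, 0.1, 2.3, 0.9, -1.8, -0.4, -1.8, -1.5, 3.2),
  ST4 = c(-2.4, -0.8, 3.6, -0.6, -0.3, 1.6, -2.8, -0.2, 2.6),
  ST5 = c(-2.3, -1.5, 3.7, -1.9, -0.5, -1.4, 3.6, 2.3, -1.1))

test_that("all reported optimal placements lie within the search bounds", {
  b <- placement_bounds()
  for (nm in names(reported_placements)) {
    x <- as.numeric(reported_placements[[nm]])
    expect_silent(check_bounds(tkaplan:::as_placement(x), b))
    m <- apply_placement(default_ma_model(), x)
    expect_s3_class(m, "knee_model")
  }
})

test_that("each bound violated by epsilon is rejected, naming the parameter", {
  b <- placement_bounds()
  for (j in 1:9) {
    hi <- rep(0, 9); hi[j] <- b$upper[j] + 1e-6
    lo <- rep(0, 9); lo[j] <- b$lower[j] - 1e-6
    expect_error(check_bounds(tkaplan:::as_placement(hi), b),
                 tkaplan:::PLACEMENT_NAMES[j], fixed = TRUE)
    expect_error(check_bounds(tkaplan:::as_placement(lo), b),
                 tkaplan:::PLACEMENT_NAMES[j], fixed = TRUE)
  }
  expect_error(apply_placement(default_ma_model(),
                               implant_placement(fem_ap = 7)), "fem_ap")
})

test_that("placement tables follow the reporting column order", {
  x <- tkaplan:::as_placement(reported_placements$ST5)
  tab <- placement_table(x, target = "ST5")
  expect_equal(tab$component, c("femoral", "tibial"))
  expect_equal(tab$ap_mm, c(-2.3, NA))
  expect_equal(tab$fe_deg, c(-1.9, 3.6))
  expect_equal(tab$vv_deg, c(-1.4, -1.1))
})
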