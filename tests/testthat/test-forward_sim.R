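test_that("a symmetric knee in pure flexion stays in the sagittal plane", {
  m <- symmetric_knee()
  for (fe in c(0, 20, 45, 60)) {
    s <- solve_quasi_static(m, fe)
    expect_true(s$converged)
    expect_equal(s$pose[["lm"]], 0, tolerance = 1e-6)
    expect_equal(s$pose[["vv"]], 0, tolerance = 1e-6)
    expect_equal(s$pose[["ei"]], 0, tolerance = 1e-6)
  }
})

test_that("with no ligaments and no gravity the solver finds the minimum
           penetration-energy configuration", {
  m <- default_patient_model()
  m$ligaments$k[] <- 0
  m$mass <- 1e-12          # effectively gravity-free
  s <- solve_quasi_static(m, 30, guess = c(0, 0, tkaplan:::resting_pd(m$contact), 0, 0))
  expect_true(s$converged)
  ev <- tkaplan:::cpp_eval(tkaplan:::model_to_cpp(m), 30,
                           as.numeric(s$pose[c("ap", "lm", "pd", "ei", "vv")]))
  # contact energy at the solution is (numerically) unbeatable nearby
  set.seed(1)
  for (i in 1:20) {
    dq <- stats::rnorm(5, 0, 0.05)
    ev2 <- tkaplan:::cpp_eval(tkaplan:::model_to_cpp(m), 30,
                              as.numeric(s$pose[c("ap", "lm", "pd", "ei", "vv")]) + dq)
    expect_gte(ev2$energy, ev$energy - 1e-9)
  }
})

test_that("every converged sample satisfies the 5 N residual contract", {
  tr <- default_pre_trace()
  expect_true(all(tr$converged))
  expect_true(all(tr$residual[tr$converged] < 5))
})

test_that("the extension trace samples 60 points from 60 to 0 degrees", {
  tr <- default_pre_trace()
  expect_equal(tr$t, 60L)
  expect_equal(nrow(tr$pose), 60L)
  expect_equal(tr$pose$fe[1], 60)
  expect_equal(tr$pose$fe[60], 0)
  expect_equal(tr$pose$fe, seq(60, 0, length.out = 60))
  expect_true(all(diff(tr$pose$fe) < 0))
})

test_that("simulation is deterministic: identical call, identical trace", {
  m <- default_patient_model()
  t1 <- simulate_extension(m, t = 20)
  t2 <- simulate_extension(m, t = 20)
  expect_identical(t1$pose, t2$pose)
  expect_identical(t1$strain, t2$strain)
  expect_identical(t1$residual, t2$residual)
})

test_that("warm-started and cold-started traces agree (path independence)", {
  m <- default_patient_model()
  warm <- simulate_extension(m, t = 20)
  cold <- simulate_extension(m, t = 20, warm = FALSE)
  expect_true(all(warm$converged) && all(cold$converged))
  expect_equal(as.matrix(warm$pose), as.matrix(cold$pose), tolerance = 1e-6)
})

test_that("halving the flexion step leaves shared samples unchanged", {
  m <- default_patient_model()
  coarse <- simulate_extension(m, t = 60)
  fine <- simulate_extension(m, t = 119)   # nested grid: every 2nd sample shared
  shared <- seq(1, 119, by = 2)
  expect_equal(fine$pose$fe[shared], coarse$pose$fe, tolerance = 1e-12)
  expect_equal(unname(as.matrix(fine$pose[shared, ])),
               unname(as.matrix(coarse$pose)), tolerance = 1e-5)
})

test_that("strain curves are continuous along the arc", {
  tr <- default_pre_trace()
  jumps <- abs(diff(tr$strain))
  expect_lt(max(jumps), 0.01)
})

test_that("default pre-diseased strains stay inside the plausibility envelope", {
  tr <- default_pre_trace()
  expect_true(all(tr$strain > -0.05 & tr$strain < 0.12))
})

test_that("trace CSV export writes kinematics and percent strains", {
  tr <- default_pre_trace()
  kin <- withr::local_tempfile(fileext = ".csv")
  st <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, kin, st)
  s <- utils::read.csv(st)
  expect_equal(names(s), c("flexion_deg", "ACL", "PCL", "dMCL", "sMCL",
                           "LCL", "ALL", "OPL", "PC"))
  expect_equal(s$LCL, 100 * unname(tr$strain[, "LCL"]), tolerance = 1e-10)
})
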