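test_that("ligament length reduces to plain distances at the identity pose", {
  b <- ligament_bundle("ACL", c(0, 0, 0), c(0, -100, 0), k = 5000, L0 = 95)
  expect_equal(ligament_length(b, pose6()), 100)
  b2 <- ligament_bundle("ACL", c(3, -4, 0), c(3, -4, 0), k = 5000, L0 = 10)
  expect_equal(ligament_length(b2, pose6()), 0)
})

test_that("ligament length matches an explicit 4x4 transform oracle", {
  b <- ligament_bundle("LCL", c(0, 4, 42), c(-10, -42, 38), k = 2000, L0 = 60)
  for (p in random_poses(50, seed = 5)) {
    T <- compose_jcs(p)      # exercised independently in test-kinematics
    i_f <- (T %*% c(-10, -42, 38, 1))[1:3]
    expect_equal(ligament_length(b, p),
                 sqrt(sum((i_f - c(0, 4, 42))^2)), tolerance = 1e-10)
  }
})

test_that("strain is (L - L0)/L0 and rejects non-positive slack lengths", {
  expect_equal(ligament_strain(110, 100), 0.10)
  expect_equal(ligament_strain(100, 100), 0)
  expect_equal(ligament_strain(95, 100), -0.05)
  expect_error(ligament_strain(100, 0), "L0")
  expect_error(ligament_strain(100, -1), "L0")
})

test_that("force law: slack gives zero, branches meet C0/C1 at 2*epsl", {
  b <- ligament_bundle("sMCL", c(0, 0, 0), c(0, -60, 0), k = 2750, L0 = 60,
                       epsl = 0.03)
  expect_equal(ligament_force(b, 0), 0)
  expect_equal(ligament_force(b, -0.04), 0)
  # both branch formulas evaluated at the junction strain
  eps_j <- 2 * 0.03
  quad <- 2750 * eps_j^2 / (4 * 0.03)
  lin <- 2750 * (eps_j - 0.03)
  expect_equal(quad, lin, tolerance = 1e-12)
  expect_equal(ligament_force(b, eps_j), quad, tolerance = 1e-12)
  # C1: one-sided difference quotients agree at the junction
  h <- 1e-8
  d_lo <- (ligament_force(b, eps_j) - ligament_force(b, eps_j - h)) / h
  d_hi <- (ligament_force(b, eps_j + h) - ligament_force(b, eps_j)) / h
  expect_equal(d_lo, d_hi, tolerance = 1e-4)
})

test_that("force is non-decreasing in strain on a dense grid", {
  b <- ligament_bundle("PCL", c(0, 0, 0), c(0, -40, 0), k = 9000, L0 = 40)
  f <- ligament_force(b, seq(-0.05, 0.20, by = 1e-4))
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0))
})

flat_pair <- function(kc = 300, p = 2) {
  # plane at height 0, spheres of radius 21 centred 22 mm apart in z
  ctr <- rbind(c(0, 1, 22), c(0, 1, -22))
  surf <- rbind(c(0, 0, 0, 0, 0,  22, 40, 20),
                c(0, 0, 0, 0, 0, -22, 40, 20))
  contact_pair(ctr, c(21, 21), surf, kc, p)
}

test_that("separated surfaces transmit zero contact force", {
  cf <- contact_force(flat_pair(), pose6(pd = -25))
  expect_equal(cf$penetration, c(0, 0))
  expect_equal(cf$force, matrix(0, 3, 2))
})

test_that("sphere-on-plane penetration follows the closed-form contact law", {
  kc <- 300; p <- 2
  for (d in c(0.1, 0.25, 0.5)) {
    # sphere centres sit at tibial height 1 - pd; penetration = 20 + pd
    cf <- contact_force(flat_pair(kc, p), pose6(pd = -20 + d))
    expect_equal(cf$penetration, c(d, d), tolerance = 1e-10)
    expect_equal(cf$force[2, ], rep(kc * d^p, 2), tolerance = 1e-10)
    expect_equal(cf$force[c(1, 3), ], matrix(0, 2, 2), tolerance = 1e-12)
  }
})

test_that("symmetric penetration gives mediolaterally mirrored forces", {
  pair <- flat_pair()
  cf <- contact_force(pair, pose6(pd = -19.5, vv = 0.5))
  expect_gt(sum(cf$penetration), 0)
  # mirrored pose: varus <-> valgus swaps compartments
  cf_m <- contact_force(pair, pose6(pd = -19.5, vv = -0.5))
  expect_equal(cf$penetration, rev(cf_m$penetration), tolerance = 1e-10)
  expect_equal(cf$force[2, ], rev(cf_m$force[2, ]), tolerance = 1e-10)
})

test_that("contact force is continuous across first touch", {
  pair <- flat_pair()
  eps <- 1e-7
  just_off <- contact_force(pair, pose6(pd = -20 - eps))
  just_on <- contact_force(pair, pose6(pd = -20 + eps))
  expect_lt(max(abs(just_on$force - just_off$force)), 1e-6)
})

test_that("poses outside the contact working range are rejected", {
  expect_error(contact_force(flat_pair(), pose6(ap = 60, pd = -19)), "range")
})

test_that("knee model validation enforces the ligament set and mass", {
  m <- default_patient_model()
  expect_silent(tkaplan:::validate_knee_model(m))
  m_dup <- m
  m_dup$ligaments$name[1] <- "PCL"
  expect_error(tkaplan:::validate_knee_model(m_dup), "exactly once")
  m_bad <- m
  m_bad$ligaments$L0[3] <- -1
  expect_error(tkaplan:::validate_knee_model(m_bad), "positive")
  expect_error(knee_model(m$femur_frame, m$tibia_frame, m$ligaments,
                          m$contact, mass = 0, com = m$com), "mass")
})

test_that("knee model serialization round-trips bit-exactly", {
  m <- default_patient_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_knee_model(m, path)
  m2 <- read_knee_model(path)
  expect_identical(m2$ligaments$name, m$ligaments$name)
  expect_identical(m2$ligaments$L0, m$ligaments$L0)
  expect_identical(m2$contact$sphere_center, m$contact$sphere_center)
  expect_identical(m2$contact$surface, m$contact$surface)
  expect_identical(m2$mass, m$mass)
  expect_identical(m2$com, m$com)
  # and the round-tripped model simulates identically
  t1 <- simulate_extension(m, t = 10)
  t2 <- simulate_extension(m2, t = 10)
  expect_identical(t1$pose, t2$pose)
  expect_identical(t1$strain, t2$strain)
})
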