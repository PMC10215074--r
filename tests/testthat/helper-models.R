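# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_patient_model <- function() {
  fixture("model", function() generate_knee(patient_spec()))
}

default_pre_trace <- function() {
  fixture("pre_trace", function() simulate_extension(default_patient_model()))
}

default_ma_model <- function() {
  fixture("ma_model", function() ma_baseline(default_patient_model()))
}

default_ma_trace <- function() {
  fixture("ma_trace", function() simulate_extension(default_ma_model()))
}

# independent rotation oracle: Rodrigues axis-angle formula
rodrigues <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

random_poses <- function(n, seed, vv_max = 60) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    pose6(fe = stats::runif(1, -90, 90), ap = stats::runif(1, -20, 20),
          lm = stats::runif(1, -20, 20), pd = stats::runif(1, -40, 10),
          ei = stats::runif(1, -45, 45), vv = stats::runif(1, -vv_max, vv_max)))
}

random_frame <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- rodrigues(q[1:3] / sqrt(sum(q[1:3]^2)), 2 * acos(min(1, abs(q[4]))))
  anatomical_frame(origin = stats::rnorm(3, 0, 50), axes = R)
}

# mirror-symmetric knee: midline bundles on the sagittal plane, lateral /
# medial bundles as exact mirror pairs with equal mechanics
symmetric_knee <- function(mass = 4.5) {
  defs <- list(
    list("ACL", c(-5, 0, 0), c(8, -4, 0), 5000),
    list("PCL", c(-4, -2, 0), c(-28, -8, 0), 9000),
    list("sMCL", c(2, 4, -42), c(5, -65, -20), 2400),
    list("LCL",  c(2, 4, 42),  c(5, -65, 20), 2400),
    list("dMCL", c(1, 2, -40), c(0, -18, -28), 1500),
    list("ALL",  c(1, 2, 40),  c(0, -18, 28), 1500),
    list("OPL", c(-8, 2, 0), c(-24, -30, 0), 1250),
    list("PC", c(-6, 1, 0), c(-20, -42, 0), 1500))
  ctr <- rbind(c(-4, 1, 22), c(-4, 1, -22))
  # congruent enough (sagittal + frontal dish) that the sagittal-plane
  # equilibrium is a stable minimum, not a saddle
  surf <- rbind(c(0, tan(5 * pi / 180), 0.004, 0.008, -4,  22, 30, 15),
                c(0, tan(5 * pi / 180), 0.004, 0.008, -4, -22, 30, 15))
  contact <- contact_pair(ctr, c(21, 21), surf, 300)
  pd_ref <- tkaplan:::resting_pd(contact)
  Tr <- compose_jcs(pose6(fe = 0, pd = pd_ref))
  lig <- do.call(rbind, lapply(defs, function(d) {
    i_f <- c(Tr %*% c(d[[3]], 1))[1:3]
    L <- sqrt(sum((i_f - d[[2]])^2))
    ligament_bundle(d[[1]], d[[2]], d[[3]], d[[4]], L0 = L / 1.02)
  }))
  knee_model(anatomical_frame(), anatomical_frame(), lig, contact,
             mass = mass, com = c(0, -250, 0), gravity_dir = c(-1, 0, 0),
             state = "pre_diseased")
}

# hand-built minimal trace for objective arithmetic tests
toy_trace <- function(t = 5, kin = 0, strain = 0, residual = 0,
                      converged = TRUE,
                      ligaments = c("PCL", "dMCL", "sMCL", "LCL", "ALL",
                                    "OPL", "PC")) {
  fe <- seq(60, 0, length.out = t)
  pose <- data.frame(fe = fe, ap = rep_len(kin, t), lm = rep_len(kin, t),
                     pd = rep_len(kin, t), ei = rep_len(kin, t),
                     vv = rep_len(kin, t))
  st <- matrix(strain, t, length(ligaments))
  colnames(st) <- ligaments
  structure(list(pose = pose, strain = st,
                 residual = rep_len(residual, t),
                 converged = rep_len(converged, t),
                 ligaments = ligaments, t = t),
            class = "simulation_trace")
}
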