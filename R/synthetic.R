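#' Default ligament mechanical parameters
#'
#' Linear-region stiffnesses (N per unit strain) and full-extension reference
#' strains (unitless) for the eight bundles, typical of the nonlinear
#' spring-ligament literature; frozen package defaults.
#'
#' @return Data frame with `name`, `k`, `ref_strain`.
#' @export
default_ligament_params <- function() {
  data.frame(
    name = LIGAMENT_NAMES,
    k = c(5000, 9000, 2000, 2750, 2000, 1000, 1250, 1500),
    ref_strain = c(0.030, 0.005, 0.015, 0.025, 0.020, 0.015, 0.015, 0.012),
    stringsAsFactors = FALSE)
}

#' Synthetic patient specification
#'
#' Parameters of the synthetic pre-diseased knee generator: an overall
#' anthropometric scale, the per-bundle reference strains used to calibrate
#' slack lengths at full extension, the attachment-jitter magnitude, the
#' native posterior tibial slope, and contact-law constants. Deterministic
#' given `seed`.
#'
#' @param seed Integer RNG seed.
#' @param scale Anthropometric scale factor (1 = reference size).
#' @param ref_strains Named vector of 8 full-extension reference strains,
#'   each in (-0.05, 0.10).
#' @param jitter Attachment jitter standard deviation, mm (default 0.8).
#' @param slope Native posterior tibial slope, degrees (default 5).
#' @param contact_k Contact stiffness, N/mm^2 (default 300).
#' @param mass Shank + foot mass, kg (default 4.5).
#' @return List of class `patient_spec`.
#' @export
patient_spec <- function(seed = 1, scale = 1,
                         ref_strains = NULL, jitter = 0.8, slope = 5,
                         contact_k = 300, mass = 4.5) {
  if (is.null(ref_strains)) {
    p <- default_ligament_params()
    ref_strains <- stats::setNames(p$ref_strain, p$name)
  }
  ref_strains <- ref_strains[LIGAMENT_NAMES]
  if (anyNA(ref_strains) || any(ref_strains <= -0.05 | ref_strains >= 0.10))
    stop("reference strains must be named for all 8 bundles and lie in (-0.05, 0.10)")
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  if (jitter < 0) stop("jitter must be >= 0")
  structure(list(seed = as.integer(seed), scale = scale,
                 ref_strains = ref_strains, jitter = jitter, slope = slope,
                 contact_k = contact_k, mass = mass),
            class = "patient_spec")
}

# nominal attachment sites (right knee, mm): femoral frame origin at the
# mid-epicondylar knee centre, tibial frame origin at the plateau centre
nominal_attachments <- function() {
  list(
    origin = rbind(ACL = c(-5, 0, 6), PCL = c(-4, -2, -6),
                   dMCL = c(1, 2, -40), sMCL = c(2, 4, -42),
                   LCL = c(0, 4, 42), ALL = c(-2, 2, 40),
                   OPL = c(-8, 2, 14), PC = c(-6, 1, 0)),
    insertion = rbind(ACL = c(8, -4, 0), PCL = c(-28, -8, -2),
                      dMCL = c(0, -18, -28), sMCL = c(5, -65, -20),
                      LCL = c(-10, -42, 38), ALL = c(18, -22, 32),
                      OPL = c(-24, -30, -18), PC = c(-20, -42, 0)))
}

#' Generate a synthetic pre-diseased knee
#'
#' Builds a [knee_model()] with the structure the analysis assumes: eight
#' ligament bundles at anatomically plausible, seed-jittered attachment
#' sites; per-condyle femoral spheres on a near-planar tibial profile with
#' the specified posterior slope; slack lengths calibrated so each bundle
#' carries its reference strain at the geometric full-extension resting
#' pose. Deterministic given the spec's seed.
#'
#' @param spec A [patient_spec()].
#' @return A pre-diseased [knee_model()].
#' @export
generate_knee <- function(spec) {
  if (!inherits(spec, "patient_spec")) stop("spec must be a patient_spec")
  set.seed(spec$seed)
  att <- nominal_attachments()
  s <- spec$scale
  jo <- matrix(stats::rnorm(24, 0, spec$jitter), 8, 3)
  ji <- matrix(stats::rnorm(24, 0, spec$jitter), 8, 3)
  origin <- att$origin * s + jo
  insertion <- att$insertion * s + ji

  R_nat <- 21 * s
  ctr <- rbind(c(-4, 1, 22), c(-4, 1, -22)) * s
  # native plateau: lateral compartment is flatter and more posteriorly
  # sloped than the medial, as in the native knee
  cx_lat <- tan((spec$slope + 3) * pi / 180)
  cx_med <- tan((spec$slope - 3) * pi / 180)
  surf <- rbind(
    c(0, cx_lat, 0.0015 / s, 0.002 / s, -4 * s,  22 * s, 30 * s, 15 * s),
    c(0, cx_med, 0.0015 / s, 0.005 / s, -4 * s, -22 * s, 30 * s, 15 * s))
  contact <- contact_pair(ctr, rep(R_nat, 2), surf, spec$contact_k)

  # slack lengths from reference strains at the geometric resting pose
  pd_ref <- resting_pd(contact)
  Tr <- compose_jcs(pose6(fe = 0, pd = pd_ref))
  p <- default_ligament_params()
  lig <- do.call(rbind, lapply(seq_len(8), function(i) {
    i_f <- c(Tr %*% c(insertion[i, ], 1))[1:3]
    L_ref <- sqrt(sum((i_f - origin[i, ])^2))
    ligament_bundle(LIGAMENT_NAMES[i], origin[i, ], insertion[i, ],
                    k = p$k[i] * s,
                    L0 = L_ref / (1 + spec$ref_strains[[LIGAMENT_NAMES[i]]]))
  }))

  knee_model(anatomical_frame(), anatomical_frame(), lig, contact,
             mass = spec$mass * s^3, com = c(0, -250 * s, 0),
             gravity_dir = c(-1, 0, 0), state = "pre_diseased")
}

#' Hidden-truth optimization scenario
#'
#' Implants the generated knee at a known placement `x_star` and takes the
#' simulated trace of that implanted model as the reference curves, so that
#' by construction the global objective minimum is zero (up to numerical
#' noise) at `x = x_star`. This is the perfect-model benchmark for the
#' optimizer; the realistic mode (reference = native pre-diseased trace,
#' where zero objective is unattainable) is obtained by passing the
#' pre-diseased trace to [make_target()] instead.
#'
#' @param spec A [patient_spec()].
#' @param x_star An [implant_placement()] strictly inside `bounds`.
#' @param t Flexion samples (default 60).
#' @param bounds A [placement_bounds()].
#' @return List of class `hidden_truth`: `model` (pre-diseased), `ma_model`,
#'   `reference` (trace at `x_star`), `ma_trace`, `x_star`.
#' @export
make_hidden_truth <- function(spec, x_star, t = 60,
                              bounds = placement_bounds()) {
  x_star <- as_placement(x_star)
  on_edge <- abs(x_star - bounds$lower) < 1e-9 | abs(x_star - bounds$upper) < 1e-9
  if (any(x_star < bounds$lower | x_star > bounds$upper) || any(on_edge))
    stop("x_star must lie strictly inside the placement bounds")
  model <- generate_knee(spec)
  ma <- ma_baseline(model)
  reference <- simulate_extension(apply_placement(ma, x_star, bounds), t = t)
  ma_trace <- simulate_extension(ma, t = t)
  structure(list(model = model, ma_model = ma, reference = reference,
                 ma_trace = ma_trace, x_star = x_star, t = t),
            class = "hidden_truth")
}

#' Generate a cohort of patient specifications
#'
#' Reproducibly jitters the base specification: each patient receives its
#' own generator seed plus small perturbations of scale (about 3 percent)
#' and native slope (about 1 degree).
#'
#' @param n Number of patients (>= 1).
#' @param base_spec A [patient_spec()] template.
#' @param seed Cohort-level seed.
#' @return List of `n` [patient_spec()]s.
#' @export
generate_cohort <- function(n, base_spec = patient_spec(), seed = 1) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, n)
  scales <- base_spec$scale * exp(stats::rnorm(n, 0, 0.03))
  slopes <- base_spec$slope + stats::rnorm(n, 0, 1)
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$seed <- seeds[i]; sp$scale <- scales[i]; sp$slope <- slopes[i]
    sp
  })
}
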