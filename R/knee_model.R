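LIGAMENT_NAMES <- c("ACL", "PCL", "dMCL", "sMCL", "LCL", "ALL", "OPL", "PC")

#' Ligament bundle
#'
#' One straight-line ligament bundle with a Blankevoort-style piecewise
#' quadratic/linear force law in strain. `k` is the linear-region stiffness
#' (N per unit strain), `L0` the slack length (mm) and `epsl` the toe-region
#' limit strain (the law is quadratic up to `2*epsl` and linear beyond).
#'
#' @param name One of ACL, PCL, dMCL, sMCL, LCL, ALL, OPL, PC.
#' @param origin Femoral-frame attachment, mm (3-vector).
#' @param insertion Tibial-frame attachment, mm (3-vector).
#' @param k Stiffness, N (per unit strain). Must be >= 0.
#' @param L0 Slack length, mm. Must be > 0.
#' @param epsl Toe limit strain (default 0.03). Must be > 0.
#' @return One-row data frame of class `ligament_bundle`.
#' @export
ligament_bundle <- function(name, origin, insertion, k, L0, epsl = 0.03) {
  name <- match.arg(name, LIGAMENT_NAMES)
  origin <- as.numeric(origin); insertion <- as.numeric(insertion)
  stopifnot(length(origin) == 3L, length(insertion) == 3L)
  if (!is.finite(L0) || L0 <= 0) stop("slack length L0 must be > 0")
  if (!is.finite(k) || k < 0) stop("stiffness k must be >= 0")
  if (!is.finite(epsl) || epsl <= 0) stop("toe limit epsl must be > 0")
  structure(
    data.frame(name = name, ox = origin[1], oy = origin[2], oz = origin[3],
               ix = insertion[1], iy = insertion[2], iz = insertion[3],
               k = k, L0 = L0, epsl = epsl, stringsAsFactors = FALSE),
    class = c("ligament_bundle", "data.frame"))
}

#' Articular / implant contact surface pair
#'
#' Per-condyle femoral spheres articulating on per-compartment tibial height
#' profiles `s(x, z) = y0 + cx*x + ax*(x-xc)^2 + az*(z-zc)^2` evaluated in the
#' tibial (insert) component frame, with an elastic contact law
#' `force = contact_k * penetration^contact_exp`.
#'
#' @param sphere_center 2x3 matrix, femoral-frame sphere centres
#'   (row 1 lateral, row 2 medial), mm.
#' @param sphere_radius Length-2 vector, mm.
#' @param surface 2x8 matrix with columns
#'   `y0, cx, ax, az, xc, zc, xrange, zrange` (lateral, medial rows).
#' @param contact_k Contact stiffness, N/mm^`contact_exp`.
#' @param contact_exp Contact exponent (default 2).
#' @param pen_max Working-range penetration limit, mm.
#' @param tib_rot 3x3 rotation of the tibial component (insert) frame within
#'   the tibial bone frame; identity for a native knee.
#' @return List of class `contact_pair`.
#' @export
contact_pair <- function(sphere_center, sphere_radius, surface,
                         contact_k, contact_exp = 2, pen_max = 5,
                         tib_rot = diag(3)) {
  sphere_center <- unname(as.matrix(sphere_center))
  surface <- unname(as.matrix(surface))
  tib_rot <- unname(as.matrix(tib_rot))
  storage.mode(sphere_center) <- "double"
  storage.mode(surface) <- "double"
  storage.mode(tib_rot) <- "double"
  stopifnot(all(dim(sphere_center) == c(2L, 3L)),
            length(sphere_radius) == 2L,
            all(dim(surface) == c(2L, 8L)),
            contact_k > 0, contact_exp > 0, pen_max > 0)
  structure(list(sphere_center = sphere_center,
                 sphere_radius = as.numeric(sphere_radius),
                 surface = surface,
                 contact_k = as.numeric(contact_k),
                 contact_exp = as.numeric(contact_exp),
                 pen_max = as.numeric(pen_max), tib_rot = tib_rot),
            class = "contact_pair")
}

#' Knee model
#'
#' A rigid femur-tibia pair: anatomical frames, ligament bundles, a contact
#' surface pair, shank mass properties and the gravity direction. A
#' pre-diseased model carries all 8 named bundles; an implanted
#' (cruciate-retaining) model carries 7, the ACL having been resected.
#'
#' @param femur_frame,tibia_frame [anatomical_frame()]s.
#' @param ligaments Data frame of stacked [ligament_bundle()] rows.
#' @param contact A [contact_pair()].
#' @param mass Shank + foot mass, kg.
#' @param com Centre of mass in the tibial frame, mm.
#' @param gravity_dir Unit 3-vector along gravity in the femoral frame.
#' @param state `"pre_diseased"` or `"implanted"`.
#' @param meta Optional list of extra fields (e.g. implant baseline geometry).
#' @return List of class `knee_model`.
#' @export
knee_model <- function(femur_frame, tibia_frame, ligaments, contact,
                       mass, com, gravity_dir = c(-1, 0, 0),
                       state = c("pre_diseased", "implanted"), meta = list()) {
  state <- match.arg(state)
  ligaments <- as.data.frame(ligaments)
  for (cl in setdiff(names(ligaments), "name"))
    ligaments[[cl]] <- as.numeric(ligaments[[cl]])
  m <- structure(list(femur_frame = femur_frame, tibia_frame = tibia_frame,
                      ligaments = ligaments, contact = contact,
                      mass = as.numeric(mass), com = as.numeric(com),
                      gravity_dir = as.numeric(gravity_dir) /
                        sqrt(sum(gravity_dir^2)),
                      state = state, meta = meta),
                 class = "knee_model")
  validate_knee_model(m)
  m
}

#' @export
print.knee_model <- function(x, ...) {
  cat(sprintf("<knee_model: %s, %d ligaments, mass %.2f kg>\n",
              x$state, nrow(x$ligaments), x$mass))
  invisible(x)
}

validate_knee_model <- function(m) {
  if (!inherits(m, "knee_model")) stop("not a knee_model")
  validate_frame(m$femur_frame); validate_frame(m$tibia_frame)
  lg <- m$ligaments
  expected <- if (m$state == "pre_diseased") LIGAMENT_NAMES else
    setdiff(LIGAMENT_NAMES, "ACL")
  if (!setequal(lg$name, expected) || anyDuplicated(lg$name))
    stop(sprintf("a %s model must contain each of {%s} exactly once",
                 m$state, paste(expected, collapse = ", ")))
  if (any(lg$L0 <= 0)) stop("slack lengths must be positive")
  if (any(lg$k < 0)) stop("stiffnesses must be non-negative")
  if (!is.finite(m$mass) || m$mass <= 0) stop("mass must be positive")
  if (!inherits(m$contact, "contact_pair")) stop("contact must be a contact_pair")
  invisible(m)
}

# Flatten a knee_model for the compiled core (frame-local coordinates)
model_to_cpp <- function(m) {
  lg <- m$ligaments
  list(lig_origin = as.matrix(lg[, c("ox", "oy", "oz")]),
       lig_insertion = as.matrix(lg[, c("ix", "iy", "iz")]),
       lig_k = lg$k, lig_L0 = lg$L0, lig_epsl = lg$epsl,
       sphere_center = m$contact$sphere_center,
       sphere_radius = m$contact$sphere_radius,
       surface = m$contact$surface,
       contact_k = m$contact$contact_k,
       contact_exp = m$contact$contact_exp,
       pen_max = m$contact$pen_max,
       tib_rot = m$contact$tib_rot,
       mass = m$mass, gravity = 9.81,
       com = m$com, gravity_dir = m$gravity_dir)
}

#' Ligament length at a pose
#'
#' Straight-line distance (mm) between the femoral origin and the tibial
#' insertion mapped through the Grood-Suntay transform of `pose`
#' (frame-local coordinates).
#'
#' @param bundle A [ligament_bundle()].
#' @param pose A [pose6()].
#' @return Length in mm.
#' @export
ligament_length <- function(bundle, pose) {
  pose <- as_pose6(pose)
  T <- compose_jcs(pose)
  i_f <- c(T %*% c(bundle$ix, bundle$iy, bundle$iz, 1))[1:3]
  sqrt(sum((i_f - c(bundle$ox, bundle$oy, bundle$oz))^2))
}

#' Ligament strain
#'
#' `(length - L0) / L0`; negative values indicate a slack bundle.
#'
#' @param length Current length, mm.
#' @param L0 Slack length, mm (> 0).
#' @return Unitless strain.
#' @export
ligament_strain <- function(length, L0) {
  if (any(!is.finite(L0)) || any(L0 <= 0)) stop("L0 must be > 0")
  (length - L0) / L0
}

#' Ligament tension
#'
#' Piecewise force law: zero when slack, quadratic toe region for
#' `0 < strain <= 2*epsl`, linear `k * (strain - epsl)` beyond; continuous
#' and C1 at the transition. Never negative.
#'
#' @param bundle A [ligament_bundle()] (uses `k` and `epsl`).
#' @param strain Unitless strain (vectorised).
#' @return Tension in N (>= 0).
#' @export
ligament_force <- function(bundle, strain) {
  k <- bundle$k; epsl <- bundle$epsl
  ifelse(strain <= 0, 0,
         ifelse(strain <= 2 * epsl, k * strain^2 / (4 * epsl),
                k * (strain - epsl)))
}

#' Tibiofemoral contact force at a pose
#'
#' Evaluates the per-compartment elastic contact law: zero when the surfaces
#' are separated, otherwise `contact_k * penetration^contact_exp` directed
#' along the energy-consistent surface normal, independently for the medial
#' and lateral compartments.
#'
#' @param pair A [contact_pair()].
#' @param pose A [pose6()].
#' @return List with `force` (3x2 matrix, femoral frame, N; columns lateral,
#'   medial), `point` (3x2, application points, femoral frame, mm) and
#'   `penetration` (length-2, mm).
#' @export
contact_force <- function(pair, pose) {
  pose <- as_pose6(pose)
  dummy <- minimal_model_for_contact(pair)
  ev <- cpp_eval(dummy, pose[["fe"]],
                 as.numeric(pose[c("ap", "lm", "pd", "ei", "vv")]))
  if (!ev$range_ok)
    stop("pose outside the contact working range")
  list(force = ev$contact_force, point = ev$contact_point,
       penetration = as.numeric(ev$penetration))
}

# ligament-free, gravity-free shell so cpp_eval sees only the contact pair
minimal_model_for_contact <- function(pair) {
  list(lig_origin = matrix(0, 1, 3), lig_insertion = matrix(c(0, -1, 0), 1, 3),
       lig_k = 0, lig_L0 = 1, lig_epsl = 0.03,
       sphere_center = pair$sphere_center, sphere_radius = pair$sphere_radius,
       surface = pair$surface, contact_k = pair$contact_k,
       contact_exp = pair$contact_exp, pen_max = pair$pen_max,
       tib_rot = pair$tib_rot,
       mass = 1, gravity = 0, com = c(0, 0, 0), gravity_dir = c(-1, 0, 0))
}

#' Serialize / deserialize a knee model
#'
#' Writes the model as structured JSON with full numeric precision; the
#' write-read round trip restores every field bit-exactly.
#'
#' @param model A [knee_model()].
#' @param path File path (`.json`).
#' @export
write_knee_model <- function(model, path) {
  validate_knee_model(model)
  obj <- list(
    state = model$state,
    femur_frame = list(origin = model$femur_frame$origin,
                       axes = model$femur_frame$axes),
    tibia_frame = list(origin = model$tibia_frame$origin,
                       axes = model$tibia_frame$axes),
    ligaments = model$ligaments,
    contact = list(sphere_center = model$contact$sphere_center,
                   sphere_radius = model$contact$sphere_radius,
                   surface = model$contact$surface,
                   contact_k = model$contact$contact_k,
                   contact_exp = model$contact$contact_exp,
                   pen_max = model$contact$pen_max,
                   tib_rot = model$contact$tib_rot),
    mass = model$mass, com = model$com, gravity_dir = model$gravity_dir,
    meta = model$meta)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_knee_model
#' @export
read_knee_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  knee_model(
    femur_frame = anatomical_frame(o$femur_frame$origin, o$femur_frame$axes),
    tibia_frame = anatomical_frame(o$tibia_frame$origin, o$tibia_frame$axes),
    ligaments = o$ligaments,
    contact = contact_pair(o$contact$sphere_center, o$contact$sphere_radius,
                           o$contact$surface, o$contact$contact_k,
                           o$contact$contact_exp, o$contact$pen_max,
                           o$contact$tib_rot),
    mass = o$mass, com = o$com, gravity_dir = o$gravity_dir,
    state = o$state,
    meta = if (length(o$meta)) o$meta else list())
}
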