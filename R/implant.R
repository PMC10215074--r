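PLACEMENT_NAMES <- c("fem_ap", "fem_lm", "fem_pd", "fem_fe", "fem_ei",
                     "fem_vv", "tib_fe", "tib_ei", "tib_vv")

#' Implant placement vector
#'
#' The nine positional parameters of the femoral and tibial components
#' relative to the mechanical-alignment (MA) baseline: femoral translations
#' AP/LM/PD (mm) and rotations FE/EI/VV (degrees), plus tibial rotations
#' FE/EI/VV (degrees). Tibial translations are structurally absent. Component
#' sign convention: positive values denote posterior, medial and proximal
#' translations, and flexion, internal and varus rotations of the components
#' (opposite to the kinematic reporting convention, which is anterior /
#' lateral / external positive).
#'
#' @param fem_ap,fem_lm,fem_pd Femoral component translations, mm.
#' @param fem_fe,fem_ei,fem_vv Femoral component rotations, degrees.
#' @param tib_fe,tib_ei,tib_vv Tibial component rotations, degrees
#'   (tibial FE is a posterior-slope change).
#' @return Named numeric vector of class `implant_placement` (length 9, in
#'   reporting column order: femoral AP, LM, PD, FE, EI, VV; tibial FE, EI, VV).
#' @export
implant_placement <- function(fem_ap = 0, fem_lm = 0, fem_pd = 0,
                              fem_fe = 0, fem_ei = 0, fem_vv = 0,
                              tib_fe = 0, tib_ei = 0, tib_vv = 0) {
  x <- c(fem_ap = fem_ap, fem_lm = fem_lm, fem_pd = fem_pd,
         fem_fe = fem_fe, fem_ei = fem_ei, fem_vv = fem_vv,
         tib_fe = tib_fe, tib_ei = tib_ei, tib_vv = tib_vv)
  if (any(!is.finite(x))) stop("placement parameters must be finite")
  structure(x, class = "implant_placement")
}

as_placement <- function(x) {
  if (inherits(x, "implant_placement")) return(x)
  x <- as.numeric(x)
  stopifnot(length(x) == 9L)
  do.call(implant_placement, as.list(stats::setNames(x, PLACEMENT_NAMES)))
}

#' Placement bounds
#'
#' Box bounds on the nine placement parameters, relative to MA. Defaults:
#' femoral translations +/-6 mm; femoral FE +/-3 deg (narrowed to avoid
#' anterior notching of the femoral cortex); femoral EI/VV and all tibial
#' rotations +/-6 deg.
#'
#' @param lower,upper Named length-9 numeric vectors (names as in
#'   [implant_placement()]).
#' @return List of class `placement_bounds` with `lower` and `upper`.
#' @export
placement_bounds <- function(
    lower = c(fem_ap = -6, fem_lm = -6, fem_pd = -6, fem_fe = -3,
              fem_ei = -6, fem_vv = -6, tib_fe = -6, tib_ei = -6, tib_vv = -6),
    upper = -lower) {
  lower <- lower[PLACEMENT_NAMES]; upper <- upper[PLACEMENT_NAMES]
  stopifnot(!anyNA(lower), !anyNA(upper), all(lower < upper))
  structure(list(lower = lower, upper = upper), class = "placement_bounds")
}

#' Check a placement against bounds
#'
#' Errors (naming every violating parameter) if any coordinate of `x` lies
#' outside `bounds`; invisibly returns `x` otherwise.
#'
#' @param x An [implant_placement()].
#' @param bounds A [placement_bounds()].
#' @export
check_bounds <- function(x, bounds = placement_bounds()) {
  x <- as_placement(x)
  bad <- which(x < bounds$lower | x > bounds$upper)
  if (length(bad))
    stop("placement out of bounds: ",
         paste(sprintf("%s = %.3g (bounds [%g, %g])", PLACEMENT_NAMES[bad],
                       x[bad], bounds$lower[bad], bounds$upper[bad]),
               collapse = "; "))
  invisible(x)
}

#' Implant surrogate geometry
#'
#' Parameters of the single-radius cruciate-retaining component surrogate:
#' femoral condylar spheres and a dished polyethylene insert profile.
#' Defaults are fixed (one component size).
#'
#' @param fem_radius Femoral component sagittal/condylar sphere radius, mm.
#' @param fem_center_x,fem_center_y Sphere-centre offset from the femoral
#'   component origin (posterior offset gives femoral flexion leverage), mm.
#' @param cond_half_sep Half mediolateral separation of the condylar
#'   spheres, mm.
#' @param insert_ax,insert_az Insert dish curvatures (1/mm) in the sagittal
#'   and frontal directions.
#' @param insert_xrange,insert_zrange Insert working half-extents, mm.
#' @return List of class `implant_geometry`.
#' @export
implant_geometry <- function(fem_radius = 22, fem_center_x = 0,
                             fem_center_y = 2, cond_half_sep = 20,
                             insert_ax = 0.006, insert_az = 0.008,
                             insert_xrange = 30, insert_zrange = 14) {
  structure(list(fem_radius = fem_radius, fem_center_x = fem_center_x,
                 fem_center_y = fem_center_y, cond_half_sep = cond_half_sep,
                 insert_ax = insert_ax, insert_az = insert_az,
                 insert_xrange = insert_xrange, insert_zrange = insert_zrange),
            class = "implant_geometry")
}

#' Mechanically aligned implantation (the x = 0 baseline)
#'
#' Replaces the native articular surfaces with the implant surrogate placed
#' per mechanical-alignment principles: component axes aligned with the
#' mechanical axes (neutral varus-valgus and rotation, zero tibial slope),
#' joint line restored by matching the composite resection/implant thickness
#' at the default 9 mm insert, and the ACL removed from the ligament set
#' (cruciate-retaining design; the ACL is resected at surgery). The
#' remaining 7 bundles are unchanged.
#'
#' @param model A pre-diseased [knee_model()].
#' @param insert_thickness Tibial polyethylene insert thickness, mm
#'   (default 9; deviations from 9 shift the joint line by the difference).
#' @param implant An [implant_geometry()].
#' @return An implanted [knee_model()] at placement `x = 0`, carrying its MA
#'   component geometry in `meta` so [apply_placement()] can reposition it.
#' @export
ma_baseline <- function(model, insert_thickness = 9,
                        implant = implant_geometry()) {
  validate_knee_model(model)
  if (model$state != "pre_diseased")
    stop("ma_baseline expects a pre-diseased model")
  if (!is.finite(insert_thickness) || insert_thickness <= 0)
    stop("insert thickness must be > 0")
  nat <- model$contact
  ctr <- rbind(c(implant$fem_center_x, implant$fem_center_y,  implant$cond_half_sep),
               c(implant$fem_center_x, implant$fem_center_y, -implant$cond_half_sep))
  # insert top follows the change in the femoral distal tangent so the joint
  # line is restored at the 9 mm reference insert
  d_bottom <- (implant$fem_center_y - implant$fem_radius) -
    mean(nat$sphere_center[, 2] - nat$sphere_radius)
  y0 <- mean(nat$surface[, 1]) + d_bottom + (insert_thickness - 9)
  surf <- rbind(
    c(y0, 0, implant$insert_ax, implant$insert_az, implant$fem_center_x,
      implant$cond_half_sep, implant$insert_xrange, implant$insert_zrange),
    c(y0, 0, implant$insert_ax, implant$insert_az, implant$fem_center_x,
      -implant$cond_half_sep, implant$insert_xrange, implant$insert_zrange))
  contact <- contact_pair(ctr, rep(implant$fem_radius, 2), surf,
                          nat$contact_k, nat$contact_exp, nat$pen_max)
  knee_model(model$femur_frame, model$tibia_frame,
             model$ligaments[model$ligaments$name != "ACL", ],
             contact, model$mass, model$com, model$gravity_dir,
             state = "implanted",
             meta = list(ma_sphere_center = ctr,
                         ma_surface = surf,
                         insert_thickness = insert_thickness,
                         placement = rep(0, 9)))
}

# component rotation: intrinsic FE -> EI -> VV about the component's own
# axes, in the component sign convention (flexion/internal/varus positive)
component_rotation <- function(fe, ei, vv) {
  d <- pi / 180
  rot_z(-fe * d) %*% rot_y(ei * d) %*% rot_x(vv * d)
}

#' Apply a placement vector to an implanted knee
#'
#' Rigidly transforms the femoral component surfaces by the six femoral
#' parameters about the femoral component frame, and rotates the tibial
#' component (insert) surfaces by the three tibial parameters about the
#' tibial component frame (intrinsic order FE, then EI, then VV).
#' Bone-attached ligament points are unchanged. The transformation acts on
#' the model's current component surfaces, so applying `x` to the MA
#' baseline gives "MA displaced by x", pure translations invert under `-x`,
#' and single-axis rotations invert under their negation.
#'
#' @param implanted An implanted [knee_model()] from [ma_baseline()].
#' @param x An [implant_placement()]; must lie within `bounds`.
#' @param bounds A [placement_bounds()] (violations error and identify the
#'   offending parameter).
#' @return The repositioned implanted [knee_model()].
#' @export
apply_placement <- function(implanted, x, bounds = placement_bounds()) {
  validate_knee_model(implanted)
  if (implanted$state != "implanted")
    stop("apply_placement expects an implanted model from ma_baseline()")
  x <- check_bounds(as_placement(x), bounds)
  # femoral: component convention -> frame axes (posterior = -x, medial = -z,
  # proximal = +y); rotation about the femoral component frame origin
  tr <- c(-x[["fem_ap"]], x[["fem_pd"]], -x[["fem_lm"]])
  Rf <- component_rotation(x[["fem_fe"]], x[["fem_ei"]], x[["fem_vv"]])
  ct <- implanted$contact
  ctr <- t(Rf %*% t(ct$sphere_center)) + matrix(tr, 2, 3, byrow = TRUE)
  # tibial: intrinsic rotation about the insert's own (current) axes
  Rt <- ct$tib_rot %*% component_rotation(x[["tib_fe"]], x[["tib_ei"]],
                                          x[["tib_vv"]])
  contact <- contact_pair(ctr, ct$sphere_radius, ct$surface,
                          ct$contact_k, ct$contact_exp, ct$pen_max,
                          tib_rot = Rt)
  out <- implanted
  out$contact <- contact
  out$meta$placement <- implanted$meta$placement + as.numeric(x)
  out
}

#' Placement as a planning-table CSV row
#'
#' One row per component with the placement in the reporting column order
#' (translations AP, LM, PD in mm; rotations FE, EI, VV in degrees); tibial
#' translations are reported as NA since they are structurally fixed.
#'
#' @param x An [implant_placement()].
#' @param target Optional label (e.g. `"ST5"`).
#' @return Data frame with columns `target, component, ap_mm, lm_mm, pd_mm,
#'   fe_deg, ei_deg, vv_deg`.
#' @export
placement_table <- function(x, target = NA_character_) {
  x <- as_placement(x)
  data.frame(target = target, component = c("femoral", "tibial"),
             ap_mm = c(x[["fem_ap"]], NA), lm_mm = c(x[["fem_lm"]], NA),
             pd_mm = c(x[["fem_pd"]], NA),
             fe_deg = c(x[["fem_fe"]], x[["tib_fe"]]),
             ei_deg = c(x[["fem_ei"]], x[["tib_ei"]]),
             vv_deg = c(x[["fem_vv"]], x[["tib_vv"]]),
             stringsAsFactors = FALSE)
}
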