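#' Quasi-static equilibrium at a prescribed flexion angle
#'
#' Holds flexion fixed and equilibrates the five free tibiofemoral
#' coordinates (ap, lm, pd, ei, vv) under gravity, ligament and contact
#' forces by damped Newton iteration on the potential-energy gradient.
#' The residual is the Euclidean norm of the five generalized forces, with
#' the two moment components converted to force units by a 40 mm lever arm.
#'
#' @param model A [knee_model()].
#' @param flexion Prescribed flexion, degrees.
#' @param guess Starting pose: a [pose6()] or the 5 free coordinates
#'   `(ap, lm, pd, ei, vv)`. Defaults to a geometry-derived resting guess.
#' @param tol Residual tolerance, N (the solver converges far below the 5 N
#   simulation contract; default 1e-5).
#' @param maxit Maximum Newton iterations (default 200).
#' @return List with `pose` ([pose6()]), `residual` (N), `converged`,
#'   `iterations`.
#' @export
solve_quasi_static <- function(model, flexion, guess = NULL,
                               tol = 1e-5, maxit = 200) {
  validate_knee_model(model)
  q <- free_coords(model, guess)
  sol <- cpp_solve(model_to_cpp(model), flexion, q, tol, maxit)
  list(pose = pose6(fe = flexion, ap = sol$q[1], lm = sol$q[2],
                    pd = sol$q[3], ei = sol$q[4], vv = sol$q[5]),
       residual = sol$residual, converged = sol$converged,
       iterations = sol$iterations)
}

free_coords <- function(model, guess) {
  if (is.null(guess)) return(default_guess(model))
  if (inherits(guess, "pose6"))
    return(as.numeric(guess[c("ap", "lm", "pd", "ei", "vv")]))
  guess <- as.numeric(guess)
  stopifnot(length(guess) == 5L)
  guess
}

# surface height directly under each sphere centre (neutral rotations)
surface_under_spheres <- function(contact) {
  vapply(1:2, function(c) {
    s <- contact$surface[c, ]
    x <- contact$sphere_center[c, 1]; z <- contact$sphere_center[c, 3]
    s[1] + s[2] * x + s[3] * (x - s[5])^2 + s[4] * (z - s[6])^2
  }, numeric(1))
}

# resting pd: sphere centres resting on the tibial surface with a nominal
# 0.2 mm penetration
resting_pd <- function(contact) {
  mean(contact$sphere_center[, 2] - contact$sphere_radius -
         surface_under_spheres(contact)) + 0.2
}

default_guess <- function(model) {
  c(0, 0, resting_pd(model$contact), 0, 0)
}

#' Simulate an unloaded knee-extension trial
#'
#' Prescribes flexion on a uniform grid from `fe_start` (default 60 deg) to
#' `fe_end` (default 0 deg), inclusive of both endpoints, and solves the
#' quasi-static equilibrium at each sample, warm-starting each step from the
#' previous solution. Per-step convergence failures are flagged in the trace
#' and never abort the run.
#'
#' @param model A [knee_model()].
#' @param t Number of flexion samples (default 60).
#' @param fe_start,fe_end Flexion arc endpoints, degrees.
#' @param guess Starting free coordinates for the first step (see
#'   [solve_quasi_static()]).
#' @param warm Warm-start each step from the previous solution (default TRUE);
#'   FALSE re-starts every step from `guess`.
#' @param tol,maxit Solver controls, as in [solve_quasi_static()].
#' @return A `simulation_trace`: list with `pose` (t x 6 data frame:
#'   `fe, ap, lm, pd, ei, vv`), `strain` (t x n_ligaments matrix, unitless),
#'   `residual` (N), `converged` (logical), `ligaments` (names), `t`.
#' @export
simulate_extension <- function(model, t = 60, fe_start = 60, fe_end = 0,
                               guess = NULL, warm = TRUE,
                               tol = 1e-5, maxit = 200) {
  validate_knee_model(model)
  stopifnot(t >= 2, fe_start > fe_end)
  q0 <- free_coords(model, guess)
  raw <- cpp_trace(model_to_cpp(model), as.integer(t), fe_start, fe_end,
                   q0, tol, maxit, warm)
  pose <- as.data.frame(raw$pose)
  names(pose) <- c("fe", "ap", "lm", "pd", "ei", "vv")
  strain <- raw$strain
  colnames(strain) <- model$ligaments$name
  structure(list(pose = pose, strain = strain,
                 residual = as.numeric(raw$residual),
                 converged = as.logical(raw$converged),
                 ligaments = model$ligaments$name, t = as.integer(t)),
            class = "simulation_trace")
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf(
    "<simulation_trace: %d samples, %.0f->%.0f deg, %d/%d converged, max residual %.2g N>\n",
    x$t, x$pose$fe[1], x$pose$fe[x$t], sum(x$converged), x$t, max(x$residual)))
  invisible(x)
}

#' @export
as.data.frame.simulation_trace <- function(x, ...) {
  cbind(x$pose, as.data.frame(x$strain), residual = x$residual,
        converged = x$converged)
}

#' Export a trace to kinematics and strain CSV files
#'
#' Kinematics columns follow the pose-curve convention
#' (`flexion_deg, ap_mm, lm_mm, pd_mm, ei_deg, vv_deg`); the strain file has
#' `flexion_deg` followed by one column per ligament, in percent.
#'
#' @param trace A `simulation_trace`.
#' @param kinematics_path,strains_path Output CSV paths.
#' @export
write_trace_csv <- function(trace, kinematics_path, strains_path) {
  write_pose_curve(trace$pose, kinematics_path)
  st <- as.data.frame(100 * trace$strain)
  utils::write.csv(cbind(flexion_deg = trace$pose$fe, st), strains_path,
                   row.names = FALSE)
  invisible(c(kinematics_path, strains_path))
}
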