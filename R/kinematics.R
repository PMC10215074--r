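#' Anatomical frame
#'
#' A bone-fixed coordinate frame: origin (mm) and three orthonormal axes
#' with x pointing anterior, y proximal and z lateral (right-knee convention;
#' left knees are mirrored at input).
#'
#' @param origin Numeric 3-vector, mm.
#' @param axes 3x3 matrix whose columns are the x (anterior), y (proximal)
#'   and z (lateral) unit axes.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  origin <- as.numeric(origin)
  axes <- unname(as.matrix(axes))
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  f <- structure(list(origin = origin, axes = axes), class = "anatomical_frame")
  validate_frame(f)
  f
}

validate_frame <- function(f, tol = 1e-9) {
  if (!inherits(f, "anatomical_frame")) stop("not an anatomical_frame")
  A <- f$axes
  if (any(!is.finite(A)) || any(!is.finite(f$origin))) stop("frame is not finite")
  if (max(abs(crossprod(A) - diag(3))) > tol)
    stop("frame axes must be orthonormal (tolerance 1e-9)")
  if (det(A) < 0) stop("frame must be right-handed")
  invisible(f)
}

#' Tibiofemoral pose in the Grood-Suntay joint coordinate system
#'
#' Six coordinates of the tibia relative to the femur: flexion `fe` (deg,
#' flexion positive), anterior-posterior `ap` (mm, anterior positive),
#' lateral-medial `lm` (mm, lateral positive), proximal-distal `pd` (mm,
#' proximal positive), external-internal `ei` (deg, tibial external positive)
#' and varus-valgus `vv` (deg, varus positive).
#'
#' @param fe,ap,lm,pd,ei,vv Pose coordinates (degrees / mm).
#' @return Named numeric vector of class `pose6`, in the order
#'   `fe, ap, lm, pd, ei, vv`.
#' @export
pose6 <- function(fe = 0, ap = 0, lm = 0, pd = 0, ei = 0, vv = 0) {
  p <- c(fe = fe, ap = ap, lm = lm, pd = pd, ei = ei, vv = vv)
  if (any(!is.finite(p))) stop("pose coordinates must be finite")
  ang <- p[c("fe", "ei", "vv")]
  if (any(ang <= -180 | ang > 180)) stop("angles must lie in (-180, 180]")
  structure(p, class = "pose6")
}

as_pose6 <- function(x) {
  if (inherits(x, "pose6")) return(x)
  x <- as.numeric(x)
  stopifnot(length(x) == 6L)
  pose6(x[1], x[2], x[3], x[4], x[5], x[6])
}

rot_z <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}
rot_x <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

# JCS rotation (tibia relative to femur, frame-local coords) as the mobile
# Euler sequence z-x-y: flexion about femoral z, varus about the floating
# axis, external about tibial y. Angles in degrees.
jcs_rotation <- function(fe, ei, vv) {
  d <- pi / 180
  rot_z(-fe * d) %*% rot_x(vv * d) %*% rot_y(-ei * d)
}

# JCS axis triad and local translation vector
jcs_translation <- function(R, ap, lm, pd) {
  e1 <- c(0, 0, 1)
  e3 <- R %*% c(0, 1, 0)
  u <- c(e3[2], -e3[1], 0)          # e3 x e1
  e2 <- u / sqrt(sum(u^2))
  lm * e1 + ap * e2 + pd * c(e3)
}

frame_embedding <- function(f) {
  T <- diag(4)
  T[1:3, 1:3] <- f$axes
  T[1:3, 4] <- f$origin
  T
}

#' Compose a rigid transform from a Grood-Suntay pose
#'
#' Builds the 4x4 rigid transform mapping tibial bone coordinates to femoral
#' bone coordinates that realises `pose`: flexion about the femoral z
#' (mediolateral) axis, external-internal rotation about the tibial y axis,
#' varus-valgus about the floating axis, and translations along the classic
#' non-orthogonal Grood-Suntay axis triad.
#'
#' @param pose A [pose6()].
#' @param femur_frame,tibia_frame [anatomical_frame()] objects giving each
#'   frame's embedding in its bone's coordinates.
#' @return 4x4 rigid transform (tibia bone coords -> femur bone coords).
#' @export
compose_jcs <- function(pose, femur_frame = anatomical_frame(),
                        tibia_frame = anatomical_frame()) {
  pose <- as_pose6(pose)
  validate_frame(femur_frame); validate_frame(tibia_frame)
  if (abs(abs(pose[["vv"]]) - 90) < 1e-6)
    stop("gimbal configuration: varus-valgus of +/-90 degrees is not representable")
  R <- jcs_rotation(pose[["fe"]], pose[["ei"]], pose[["vv"]])
  d <- jcs_translation(R, pose[["ap"]], pose[["lm"]], pose[["pd"]])
  Tl <- diag(4)
  Tl[1:3, 1:3] <- R
  Tl[1:3, 4] <- d
  Ef <- frame_embedding(femur_frame)
  Et <- frame_embedding(tibia_frame)
  Ef %*% Tl %*% solve(Et)
}

#' Decompose a rigid transform into a Grood-Suntay pose
#'
#' Inverse of [compose_jcs()] on its range. The input must be a rigid
#' transform (orthonormal rotation block with determinant +1).
#'
#' @param transform 4x4 rigid transform (tibia bone coords -> femur bone coords).
#' @param femur_frame,tibia_frame Frame embeddings as in [compose_jcs()].
#' @param tol Rigidity tolerance.
#' @return A [pose6()].
#' @export
decompose_jcs <- function(transform, femur_frame = anatomical_frame(),
                          tibia_frame = anatomical_frame(), tol = 1e-8) {
  stopifnot(is.matrix(transform), all(dim(transform) == c(4L, 4L)))
  validate_frame(femur_frame); validate_frame(tibia_frame)
  Ef <- frame_embedding(femur_frame)
  Et <- frame_embedding(tibia_frame)
  Tl <- solve(Ef) %*% transform %*% Et
  R <- Tl[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("transform is not rigid (rotation block not orthonormal with det +1)")
  # R = Rz(a) Rx(b) Ry(c); row 3 = (-cb*sc, sb, cb*cc); a from column 2
  sb <- R[3, 2]
  if (abs(sb) > 1 - 1e-8)
    stop("near-gimbal configuration: varus-valgus approaches +/-90 degrees")
  b <- asin(sb)
  c <- atan2(-R[3, 1], R[3, 3])
  a <- atan2(-R[1, 2], R[2, 2])
  d <- 180 / pi
  fe <- -a * d; vv <- b * d; ei <- -c * d
  # translations along the (non-orthogonal) JCS triad: solve [e2 e1 e3] q = d
  e1 <- c(0, 0, 1)
  e3 <- c(R %*% c(0, 1, 0))
  u <- c(e3[2], -e3[1], 0)
  e2 <- u / sqrt(sum(u^2))
  q <- unname(solve(cbind(e2, e1, e3), Tl[1:3, 4]))
  pose6(fe = fe, ap = q[1], lm = q[2], pd = q[3], ei = ei, vv = vv)
}

#' Write / read a pose curve as CSV
#'
#' Columns: `flexion_deg, ap_mm, lm_mm, pd_mm, ei_deg, vv_deg`.
#'
#' @param poses Data frame or matrix with columns fe, ap, lm, pd, ei, vv.
#' @param path File path.
#' @export
write_pose_curve <- function(poses, path) {
  m <- as.data.frame(poses)
  stopifnot(ncol(m) >= 6L)
  out <- data.frame(flexion_deg = m[[1]], ap_mm = m[[2]], lm_mm = m[[3]],
                    pd_mm = m[[4]], ei_deg = m[[5]], vv_deg = m[[6]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_curve
#' @export
read_pose_curve <- function(path) {
  utils::read.csv(path)
}
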