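#' Rotation matrix about an axis
#'
#' Right-handed rotation by `angle` radians about `axis` (Rodrigues formula).
#'
#' @param axis Non-zero length-3 vector.
#' @param angle Rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("zero rotation axis")
  u <- axis / n
  K <- matrix(c(0, -u[3L], u[2L],
                u[3L], 0, -u[1L],
                -u[2L], u[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

.unit <- function(v) v / sqrt(sum(v^2))

.angle_between <- function(u, v) {
  c2 <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, c2)))
}

# Deterministic unit vector perpendicular to v: reject the first standard
# basis vector that is not nearly parallel to v.
.any_perpendicular <- function(v) {
  u <- .unit(v)
  for (e in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    w <- e - sum(e * u) * u
    if (sum(w^2) > 1e-6) return(.unit(w))
  }
  stop("unreachable")
}

#' Orientation solution container
#'
#' @param U 3 x 3 rotation (crystal setting in the lab frame).
#' @param B Busing-Levy matrix of the prior cell.
#' @param source Provenance (e.g. contributing vector ids or network id).
#' @param stats Acceptance statistics, if computed.
#' @return Object of class `"orientation_solution"` with `U` and `R = U B`.
#' @export
orientation_solution <- function(U, B, source = NULL, stats = NULL) {
  structure(list(U = U, R = U %*% B, source = source, stats = stats),
            class = "orientation_solution")
}

#' Orientation matrix from two matched inter-spot vectors
#'
#' Given two observed inter-spot vectors and the theoretical lattice vectors
#' they were matched to, constructs the rotation aligning observed onto
#' theoretical space. Q_a rotates i_obs onto the direction of i_thr about
#' the axis C = i_obs x i_thr by the angle between them; Q_b then rotates
#' about i_thr by the angle beta that best aligns Q_a j_obs with j_thr
#' (closed form: signed angle between their projections onto the plane
#' perpendicular to i_thr). With Q_c = Q_b Q_a, the crystal setting is
#' U = Q_c^T and the full orientation matrix is R = U B, mapping integer
#' (h, k, l) to observed reciprocal coordinates.
#'
#' The two vectors may share one spot (three-spot case); they only need to
#' be linearly independent. When i_obs and i_thr are antiparallel the
#' rotation axis is taken as a deterministic perpendicular of i_obs.
#'
#' @param i_obs,j_obs Observed vectors (inverse Angstrom, lab frame).
#' @param i_thr,j_thr Matched theoretical vectors (inverse Angstrom,
#'   crystal frame).
#' @param B Busing-Levy matrix.
#' @param source Optional provenance tag.
#' @return An [orientation_solution()].
#' @export
matrix_from_vector_pair <- function(i_obs, j_obs, i_thr, j_thr, B,
                                    source = NULL) {
  min_ang <- 1e-3  # radians; below this the pair is unusable
  if (.angle_between(i_obs, j_obs) < min_ang ||
      pi - .angle_between(i_obs, j_obs) < min_ang)
    stop("degenerate pair: observed vectors are (anti)parallel")
  if (.angle_between(i_thr, j_thr) < min_ang ||
      pi - .angle_between(i_thr, j_thr) < min_ang)
    stop("degenerate pair: theoretical vectors are (anti)parallel")

  alpha <- .angle_between(i_obs, i_thr)
  C <- c(i_obs[2L] * i_thr[3L] - i_obs[3L] * i_thr[2L],
         i_obs[3L] * i_thr[1L] - i_obs[1L] * i_thr[3L],
         i_obs[1L] * i_thr[2L] - i_obs[2L] * i_thr[1L])
  Qa <- if (alpha < 1e-12) {
    diag(3)
  } else if (sum(C^2) < 1e-24) {          # antiparallel: any perpendicular axis
    rotation_about_axis(.any_perpendicular(i_obs), alpha)
  } else {
    rotation_about_axis(C, alpha)
  }

  ih <- .unit(i_thr)
  jp <- as.numeric(Qa %*% j_obs)
  jp <- jp - sum(jp * ih) * ih
  jt <- j_thr - sum(j_thr * ih) * ih
  beta <- atan2(sum(ih * c(jp[2L] * jt[3L] - jp[3L] * jt[2L],
                           jp[3L] * jt[1L] - jp[1L] * jt[3L],
                           jp[1L] * jt[2L] - jp[2L] * jt[1L])),
                sum(jp * jt))
  Qc <- rotation_about_axis(i_thr, beta) %*% Qa
  orientation_solution(t(Qc), B, source = source)
}

.as_rotation <- function(x) {
  if (inherits(x, "orientation_solution")) x$U else x
}

#' Symmetry-aware rotation-matrix similarity metric
#'
#' For rotations P and Q and point-group rotation operators O_s, the metric
#' is the minimum over s of the Frobenius norm ||P - Q O_s||. It is zero
#' exactly when P and Q are symmetry-equivalent crystal settings, and for a
#' pure relative rotation by angle theta equals 2 sqrt(2) sin(theta/2), so a
#' value of 0.25 corresponds to a relative rotation of 10 degrees or less.
#'
#' @param P,Q Rotations (3 x 3 matrices or [orientation_solution()]s).
#' @param ops List of Cartesian symmetry rotations
#'   (see [rotational_symmetry_ops()]); defaults to identity only.
#' @return Non-negative scalar in (0, 2 sqrt(2)).
#' @export
similarity_metric <- function(P, Q, ops = list(diag(3))) {
  P <- .as_rotation(P); Q <- .as_rotation(Q)
  best <- Inf
  for (O in ops) {
    d <- sum((P - Q %*% O)^2)
    if (d < best) best <- d
  }
  sqrt(best)
}

# Batch form: metric from one rotation U to each of n rotations stored as
# rows of a n x 9 matrix (row-major flattening), under symmetry ops.
.metric_to_many <- function(U, flat, ops) {
  u <- as.numeric(t(U))
  best <- rep(Inf, nrow(flat))
  for (O in ops) {
    # rows are V_i; compare U with V_i O: flatten(V O) = flat %*% kron(I,O)?
    # cheaper: ||U - V O||^2 = 6 - 2 tr(O^T V^T U) = 6 - 2 <V, U O^T>
    target <- as.numeric(t(U %*% t(O)))
    d2 <- 6 - 2 * as.numeric(flat %*% target)
    best <- pmin(best, d2)
  }
  sqrt(pmax(best, 0))
}

#' Convert an angular radius to the similarity-metric scale
#'
#' Metric value of a pure rotation by the given angle:
#' 2 sqrt(2) sin(angle / 2). Monotone on 0..180 degrees, so angular
#' thresholds (e.g. the 8-degree neighbourhood radius or the 10-degree
#' duplicate criterion) translate consistently to metric units.
#'
#' @param angle_deg Angle in degrees, 0..180.
#' @return Metric value.
#' @export
angle_threshold_to_metric <- function(angle_deg) {
  stopifnot(all(angle_deg >= 0), all(angle_deg <= 180))
  2 * sqrt(2) * sin(angle_deg * pi / 360)
}

#' Polar projection of an orientation
#'
#' Rotates a reference unit vector by the orientation and returns its
#' spherical angles, giving the 2-D map on which clusters of similar
#' orientations (and their symmetry images) are visualized.
#'
#' @param R A rotation matrix or [orientation_solution()] (its U is used).
#' @param reference_axis Unit vector to rotate; default (1, 0, 0).
#' @return Named numeric vector `c(theta, phi)` in degrees: `theta` is the
#'   polar angle from +z, `phi` the azimuth in the xy plane.
#' @export
polar_projection <- function(R, reference_axis = c(1, 0, 0)) {
  U <- .as_rotation(R)
  v <- as.numeric(U %*% .unit(reference_axis))
  c(theta = acos(max(-1, min(1, v[3L]))) * 180 / pi,
    phi = atan2(v[2L], v[1L]) * 180 / pi)
}
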