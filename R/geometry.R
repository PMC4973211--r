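#' Detector geometry
#'
#' Describes a single flat detector panel mounted orthogonal to the beam.
#' Pixel coordinates are 0-based with pixel centres at integer coordinates;
#' `beam_centre` is the (fast, slow) pixel hit by the direct beam.
#'
#' @param distance_mm Crystal-to-detector distance along the beam, in mm.
#' @param beam_centre_px Numeric length-2, (fast, slow) beam centre in pixels.
#' @param pixel_size_mm Pixel edge length in mm (square pixels).
#' @param n_fast,n_slow Panel size in pixels along the fast and slow axes.
#' @return An object of class `"detector_geometry"`.
#' @examples
#' detector_geometry(101.2, c(512, 512), 0.11, 1024, 1024)
#' @export
detector_geometry <- function(distance_mm, beam_centre_px, pixel_size_mm,
                              n_fast, n_slow) {
  stopifnot(is.numeric(distance_mm), length(distance_mm) == 1L,
            is.finite(distance_mm), distance_mm > 0,
            is.numeric(beam_centre_px), length(beam_centre_px) == 2L,
            all(is.finite(beam_centre_px)),
            is.numeric(pixel_size_mm), length(pixel_size_mm) == 1L,
            is.finite(pixel_size_mm), pixel_size_mm > 0,
            n_fast >= 1, n_slow >= 1)
  structure(list(distance_mm = as.numeric(distance_mm),
                 beam_centre_px = as.numeric(beam_centre_px),
                 pixel_size_mm = as.numeric(pixel_size_mm),
                 n_fast = as.integer(n_fast),
                 n_slow = as.integer(n_slow)),
            class = "detector_geometry")
}

#' X-ray beam model
#'
#' @param wavelength_A Nominal wavelength in Angstrom.
#' @param bandwidth Fractional full-width spectral bandwidth (d-lambda/lambda);
#'   an XFEL SASE spike train is typically a few 1e-3.
#' @return An object of class `"beam"`.
#' @export
beam <- function(wavelength_A, bandwidth = 0) {
  stopifnot(is.numeric(wavelength_A), length(wavelength_A) == 1L,
            is.finite(wavelength_A), wavelength_A > 0,
            is.numeric(bandwidth), length(bandwidth) == 1L, bandwidth >= 0)
  structure(list(wavelength_A = as.numeric(wavelength_A),
                 bandwidth = as.numeric(bandwidth)),
            class = "beam")
}

.as_pixel_matrix <- function(pixel) {
  if (is.matrix(pixel)) {
    stopifnot(ncol(pixel) == 2L)
    pixel
  } else {
    stopifnot(is.numeric(pixel), length(pixel) == 2L)
    matrix(pixel, ncol = 2L)
  }
}

#' Convert pixel coordinates to mm relative to the beam centre
#'
#' @param pixel Length-2 (fast, slow) vector or an n x 2 matrix of pixels.
#' @param geometry A [detector_geometry()].
#' @return n x 2 matrix of (x, y) positions in mm in the detector plane.
#' @export
mm_from_pixels <- function(pixel, geometry) {
  px <- .as_pixel_matrix(pixel)
  cbind(x = (px[, 1L] - geometry$beam_centre_px[1L]) * geometry$pixel_size_mm,
        y = (px[, 2L] - geometry$beam_centre_px[2L]) * geometry$pixel_size_mm)
}

#' Back-project detector pixels onto the Ewald sphere
#'
#' The lab frame has the beam along +z with incident wavevector
#' s0 = (0, 0, 1/lambda); the detector plane sits at z = distance. Each spot's
#' scattered unit direction u is proportional to (x_mm, y_mm, distance) and its
#' reciprocal coordinate is rlp = u/lambda - s0, which lies exactly on the
#' nominal Ewald sphere (|rlp + s0| = |s0|) with |rlp| = 2 sin(theta)/lambda.
#' Recordable rlps have a non-positive z component.
#'
#' @inheritParams mm_from_pixels
#' @param beam A [beam()].
#' @return n x 3 matrix of reciprocal coordinates in inverse Angstrom.
#' @export
back_project <- function(pixel, geometry, beam) {
  mm <- mm_from_pixels(pixel, geometry)
  lambda <- beam$wavelength_A
  nrm <- sqrt(mm[, 1L]^2 + mm[, 2L]^2 + geometry$distance_mm^2)
  cbind(mm[, 1L] / (nrm * lambda),
        mm[, 2L] / (nrm * lambda),
        (geometry$distance_mm / nrm - 1) / lambda)
}

.as_rlp_matrix <- function(rlp) {
  if (is.matrix(rlp)) {
    stopifnot(ncol(rlp) == 3L)
    rlp
  } else {
    stopifnot(is.numeric(rlp), length(rlp) == 3L)
    matrix(rlp, ncol = 3L)
  }
}

#' Project reciprocal coordinates onto the detector
#'
#' Inverse of [back_project()]. The diffracted ray runs along s = rlp + s0;
#' coordinates with s_z <= 0 cannot reach the detector ("not recordable").
#' rlps slightly off the nominal sphere are projected along the same ray, so
#' predictions from finite-bandwidth models land where their spots would.
#'
#' @param rlp Length-3 vector or n x 3 matrix of reciprocal coordinates.
#' @inheritParams back_project
#' @return Data frame with columns `fast`, `slow` (pixels; NA when not
#'   recordable), `recordable`, and `on_panel`.
#' @export
project_to_detector <- function(rlp, geometry, beam) {
  q <- .as_rlp_matrix(rlp)
  s <- cbind(q[, 1L], q[, 2L], q[, 3L] + 1 / beam$wavelength_A)
  recordable <- s[, 3L] > 0
  fast <- slow <- rep(NA_real_, nrow(q))
  if (any(recordable)) {
    scale <- geometry$distance_mm / s[recordable, 3L]
    xmm <- s[recordable, 1L] * scale
    ymm <- s[recordable, 2L] * scale
    fast[recordable] <- xmm / geometry$pixel_size_mm + geometry$beam_centre_px[1L]
    slow[recordable] <- ymm / geometry$pixel_size_mm + geometry$beam_centre_px[2L]
  }
  on_panel <- recordable &
    fast >= 0 & fast < geometry$n_fast &
    slow >= 0 & slow < geometry$n_slow
  on_panel[is.na(on_panel)] <- FALSE
  data.frame(fast = fast, slow = slow,
             recordable = recordable, on_panel = on_panel)
}

#' Ewald-sphere wavelength of a reciprocal coordinate
#'
#' Returns the wavelength lambda_i whose Ewald sphere (centre (0, 0, -1/lambda_i),
#' passing through the origin) contains the given point:
#' lambda_i = -2 q_z / |q|^2. Used as the per-reflection acceptance statistic:
#' spots of a correctly oriented lattice all back-compute to wavelengths near
#' the beam wavelength.
#'
#' @param rlp Length-3 vector or n x 3 matrix; each row must have a negative z
#'   component and non-zero length, otherwise no Ewald sphere through the
#'   origin contains it and an error is signalled.
#' @return Numeric vector of wavelengths in Angstrom.
#' @export
ewald_wavelength <- function(rlp) {
  q <- .as_rlp_matrix(rlp)
  q2 <- rowSums(q^2)
  if (any(q2 == 0) || any(q[, 3L] >= 0))
    stop("no Ewald sphere through the origin contains this point ",
         "(need |rlp| > 0 and rlp_z < 0)")
  -2 * q[, 3L] / q2
}

#' Detector-plane span of a reciprocal-space distance
#'
#' The distance in mm that a reciprocal-space vector of the given length spans
#' across the detector when located near the beam centre:
#' span = D tan(2 asin(q lambda / 2)). Useful for judging whether the shortest
#' allowed inter-spot vector is resolvable at a given geometry.
#'
#' @param length_inv_A Reciprocal length in inverse Angstrom.
#' @param beam A [beam()].
#' @param distance_mm Detector distance in mm.
#' @return Span in mm.
#' @export
vector_span_mm <- function(length_inv_A, beam, distance_mm) {
  stopifnot(length_inv_A >= 0, distance_mm > 0)
  distance_mm * tan(2 * asin(length_inv_A * beam$wavelength_A / 2))
}
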