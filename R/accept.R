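#' Ewald-wavelength statistics of an orientation solution
#'
#' For each observed spot, finds the nearest centring-allowed integer Miller
#' index under the solution's R matrix (searching the 3x3x3 integer
#' neighbourhood of round(R^-1 rlp)) and back-computes the Ewald-sphere
#' wavelength of the modelled reciprocal coordinate R hkl. For a correct
#' orientation these wavelengths concentrate tightly around the beam
#' wavelength; for a wrong one they scatter. The spread (standard deviation)
#' and the height of the histogram peak are the acceptance statistics.
#'
#' @param sol An [orientation_solution()].
#' @param image An [image_model()].
#' @param priors A [crystal_priors()] (for the centring rule).
#' @param d_max Only spots with |rlp| <= d_max are assigned (default: all).
#' @param d_min Spots below this resolution are excluded: the Ewald-sphere
#'   radius of a reciprocal point is poorly conditioned at low scattering
#'   angle (a fixed positional offset perturbs the inferred radius as
#'   1/sin^2(theta)), so low-resolution spots dilute the discrimination
#'   between correct and incorrect orientations.
#' @param assign_tol Maximum model-to-observation distance (inverse
#'   Angstrom) for a spot to count as assigned. On multi-lattice images the
#'   spots of other lattices are far from any reciprocal point of the
#'   candidate orientation; excluding them keeps the statistic about the
#'   lattice under test.
#' @return Object of class `"acceptance_stats"`: `wavelengths`, `stdev`,
#'   `peak_height`, `n_assigned`, `hkl` (assigned indices), `model_rlp`.
#' @export
solution_wavelengths <- function(sol, image, priors, d_max = Inf, d_min = 0,
                                 assign_tol = Inf) {
  rlp <- image$rlp
  if (is.finite(d_max) || d_min > 0) {
    nrm <- sqrt(rowSums(rlp^2))
    rlp <- rlp[nrm <= d_max & nrm >= d_min, , drop = FALSE]
  }
  n <- nrow(rlp)
  empty <- structure(list(wavelengths = numeric(0), stdev = NA_real_,
                          peak_height = 0L, n_assigned = 0L,
                          hkl = matrix(0L, 0, 3), model_rlp = matrix(0, 0, 3)),
                     class = "acceptance_stats")
  if (n == 0) return(empty)
  R <- sol$R
  hkl0 <- round(rlp %*% t(solve(R)))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  # n*27 candidate indices
  cand <- hkl0[rep(seq_len(n), each = 27L), ] + off[rep(1:27, n), ]
  ok <- centring_allowed(cand, priors$sg$centring) &
    !(cand[, 1L] == 0 & cand[, 2L] == 0 & cand[, 3L] == 0)
  model <- cand %*% t(R)
  d2 <- rowSums((model - rlp[rep(seq_len(n), each = 27L), ])^2)
  d2[!ok] <- Inf
  pick <- max.col(-matrix(d2, nrow = n, byrow = TRUE), ties.method = "first")
  sel <- (seq_len(n) - 1L) * 27L + pick
  hkl <- cand[sel, , drop = FALSE]
  model <- model[sel, , drop = FALSE]
  usable <- is.finite(d2[sel]) & model[, 3L] < 0 & rowSums(model^2) > 0 &
    sqrt(d2[sel]) <= assign_tol
  if (!any(usable)) return(empty)
  wl <- ewald_wavelength(model[usable, , drop = FALSE])
  lambda <- image$beam$wavelength_A
  bw <- if (image$beam$bandwidth > 0) image$beam$bandwidth else 1e-3
  binw <- lambda * bw / 4
  peaks <- table(floor((wl - lambda) / binw))
  structure(list(wavelengths = wl,
                 stdev = if (length(wl) > 1) stats::sd(wl) else 0,
                 peak_height = as.integer(max(peaks)),
                 n_assigned = sum(usable),
                 hkl = hkl[usable, , drop = FALSE],
                 model_rlp = model[usable, , drop = FALSE]),
            class = "acceptance_stats")
}

#' Accept or reject an indexing solution
#'
#' A solution is accepted when the standard deviation of the per-spot Ewald
#' wavelengths is at or below `sigma_t`, or when the wavelength histogram has
#' a sufficiently high peak. Both thresholds are exposed because suitable
#' values depend on the crystal form and geometry.
#'
#' @param stats A [solution_wavelengths()] result.
#' @param sigma_t Wavelength-spread threshold in Angstrom (inclusive).
#' @param min_peak Minimum histogram peak height (inclusive).
#' @return Logical.
#' @export
accept_solution <- function(stats, sigma_t, min_peak = Inf) {
  if (is.na(stats$stdev) || stats$n_assigned == 0L) return(FALSE)
  stats$stdev <= sigma_t || stats$peak_height >= min_peak
}

# Shared forward model: which reflections of orientation R diffract, and
# where. Selection: centring-allowed hkl with |R hkl| <= res_max whose
# reciprocal coordinate lies within rlp_radius + (bandwidth/2)/lambda of the
# nominal Ewald sphere surface (euclidean distance to the sphere through the
# origin with centre (0,0,-1/lambda)); the bandwidth term approximates the
# radial extent of the nest of spheres. This exact rule is also the
# simulator's reflection-selection rule, so prediction round-trips the
# simulation.
.predict_reflections <- function(R, geometry, beam, priors, rlp_radius,
                                 res_max = NULL) {
  if (is.null(res_max)) res_max <- .corner_resolution(geometry, beam)
  ball <- .hkl_ball_cached(priors, res_max)
  q <- ball$dhkl %*% t(R)
  lambda <- beam$wavelength_A
  r0 <- 1 / lambda
  d_sphere <- abs(sqrt(q[, 1L]^2 + q[, 2L]^2 + (q[, 3L] + r0)^2) - r0)
  tol <- rlp_radius + (beam$bandwidth / 2) / lambda
  sel <- which(d_sphere <= tol)
  list(hkl = ball$dhkl[sel, , drop = FALSE],
       q = q[sel, , drop = FALSE])
}

#' Predict spot positions for an orientation solution
#'
#' Enumerates every centring-allowed reflection the solution places close
#' enough to the nest of Ewald spheres (euclidean distance to the nominal
#' sphere within the rlp radius plus the half-bandwidth radial spread) and
#' projects it to detector pixels, keeping on-panel predictions.
#'
#' @param sol An [orientation_solution()].
#' @param geometry A [detector_geometry()].
#' @param beam A [beam()].
#' @param priors A [crystal_priors()].
#' @param rlp_radius Effective rlp radius, inverse Angstrom.
#' @param res_max Resolution limit, inverse Angstrom (default: detector
#'   corner).
#' @return Data frame with columns `h`, `k`, `l`, `fast`, `slow`.
#' @export
predict_spots <- function(sol, geometry, beam, priors, rlp_radius = 1e-4,
                          res_max = NULL) {
  ref <- .predict_reflections(sol$R, geometry, beam, priors, rlp_radius,
                              res_max)
  if (nrow(ref$hkl) == 0)
    return(data.frame(h = integer(0), k = integer(0), l = integer(0),
                      fast = numeric(0), slow = numeric(0)))
  proj <- project_to_detector(ref$q, geometry, beam)
  keep <- proj$on_panel
  data.frame(h = ref$hkl[keep, 1L], k = ref$hkl[keep, 2L],
             l = ref$hkl[keep, 3L],
             fast = proj$fast[keep], slow = proj$slow[keep])
}

#' Remove spots explained by an existing solution
#'
#' Drops every observed spot lying within `radius_px` of any predicted spot,
#' so that indexing can resume on the remainder and find further lattices.
#'
#' @param image An [image_model()].
#' @param predictions A [predict_spots()] result.
#' @param radius_px Removal radius in pixels.
#' @return A new [image_model()] with the surviving spots.
#' @export
remove_predicted <- function(image, predictions, radius_px = 2) {
  stopifnot(radius_px > 0)
  if (nrow(predictions) == 0 || nrow(image$spots) == 0) return(image)
  dx <- outer(image$spots$fast, predictions$fast, "-")
  dy <- outer(image$spots$slow, predictions$slow, "-")
  near <- rowSums(dx^2 + dy^2 <= radius_px^2) > 0
  image_model(image$id, image$geometry, image$beam,
              image$spots[!near, , drop = FALSE])
}
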