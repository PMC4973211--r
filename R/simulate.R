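#' Specification of a synthetic still-image experiment
#'
#' Defines the forward model used to fabricate still diffraction images with
#' known ground truth. Reflections are selected by proximity to the nest of
#' Ewald spheres (finite rlp size plus bandwidth, the exact rule of
#' [predict_spots()]), projected to the detector, and jittered in pixel
#' position; uniform noise spots emulate spot-finder false positives, and
#' several lattices may be superimposed.
#'
#' The defaults emulate a cubic I23 crystal with a 106.1 Angstrom cell at a
#' 1.46 Angstrom XFEL beam and 101.2 mm detector distance on a 0.11 mm-pixel
#' panel, yielding on the order of a hundred reflections per image.
#'
#' @param cell A [unit_cell()].
#' @param spacegroup Space-group symbol or [space_group_info()].
#' @param geometry A [detector_geometry()].
#' @param beam A [beam()]; default 1.46 Angstrom with 6e-4 bandwidth.
#' @param rlp_radius Effective rlp radius, inverse Angstrom.
#' @param jitter_px Gaussian sigma of the centroid positional error, pixels.
#' @param n_noise_spots Number of uniform false-positive spots per image.
#' @param n_lattices Number of superimposed lattices.
#' @param res_max Resolution limit of simulated reflections, inverse
#'   Angstrom (default: the detector-corner limit).
#' @param seed Master seed; each image's stream is derived from
#'   (seed, image index) so images are independently reproducible.
#' @return Object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(cell = unit_cell(106.1),
                            spacegroup = "I23",
                            geometry = detector_geometry(101.2, c(512, 512),
                                                         0.11, 1024, 1024),
                            beam = NULL,
                            rlp_radius = 1e-4,
                            jitter_px = 0.3,
                            n_noise_spots = 16,
                            n_lattices = 1,
                            res_max = NULL,
                            seed = 1) {
  if (is.character(spacegroup)) spacegroup <- space_group_info(spacegroup)
  if (is.null(beam)) beam <- beam(1.46, bandwidth = 6e-4)
  stopifnot(inherits(beam, "beam"), n_lattices >= 1, jitter_px >= 0,
            n_noise_spots >= 0)
  structure(list(cell = cell, spacegroup = spacegroup, geometry = geometry,
                 beam = beam, rlp_radius = rlp_radius, jitter_px = jitter_px,
                 n_noise_spots = n_noise_spots, n_lattices = n_lattices,
                 res_max = res_max, seed = seed),
            class = "simulation_spec")
}

.image_seed <- function(master, index) {
  as.integer((as.double(master) * 1000003 + as.double(index)) %% 2147483647)
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Random orientation, uniform over rotations
#'
#' Draws a unit quaternion from four standard normals (uniform on SO(3)) and
#' converts it to a rotation matrix. Uses the current RNG stream.
#'
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
random_orientation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Simulate one still image with ground truth
#'
#' For each lattice a uniformly random orientation is drawn and its
#' reflections are selected and projected with exactly the forward model of
#' [predict_spots()]; centroids are jittered by N(0, jitter_px^2) per axis,
#' uniform noise spots are appended, and the spot list is shuffled. The
#' returned image back-projects the (jittered) pixel centroids at the
#' nominal wavelength, exactly as real spot lists are treated.
#'
#' @param spec A [simulation_spec()].
#' @param index Image index (with the master seed, fixes this image's RNG
#'   stream).
#' @param priors Optional [crystal_priors()] for the same cell/space group
#'   (shares the reflection-enumeration cache); built on the fly if NULL.
#' @return List with `image` (an [image_model()]) and `truth` (class
#'   `"ground_truth"`: `U` list of per-lattice rotations, `label` integer
#'   per spot with 0 = noise, `hkl` integer matrix per spot, NA for noise).
#' @export
simulate_image <- function(spec, index = 1, priors = NULL) {
  if (is.null(priors))
    priors <- crystal_priors(spec$cell, spec$spacegroup, d_max = 0.05)
  B <- priors$B
  geom <- spec$geometry
  .with_seed(.image_seed(spec$seed, index), {
    fast <- numeric(0); slow <- numeric(0)
    label <- integer(0)
    hkl <- matrix(NA_integer_, 0, 3)
    Us <- vector("list", spec$n_lattices)
    for (lat in seq_len(spec$n_lattices)) {
      U <- random_orientation()
      Us[[lat]] <- U
      ref <- .predict_reflections(U %*% B, geom, spec$beam, priors,
                                  spec$rlp_radius, spec$res_max)
      if (nrow(ref$hkl) == 0) next
      proj <- project_to_detector(ref$q, geom, spec$beam)
      keep <- proj$on_panel
      nf <- proj$fast[keep] + stats::rnorm(sum(keep), 0, spec$jitter_px)
      ns <- proj$slow[keep] + stats::rnorm(sum(keep), 0, spec$jitter_px)
      on <- nf >= 0 & nf < geom$n_fast & ns >= 0 & ns < geom$n_slow
      fast <- c(fast, nf[on]); slow <- c(slow, ns[on])
      label <- c(label, rep(lat, sum(on)))
      hkl <- rbind(hkl, ref$hkl[keep, , drop = FALSE][on, , drop = FALSE])
    }
    if (spec$n_noise_spots > 0) {
      fast <- c(fast, stats::runif(spec$n_noise_spots, 0, geom$n_fast))
      slow <- c(slow, stats::runif(spec$n_noise_spots, 0, geom$n_slow))
      label <- c(label, rep(0L, spec$n_noise_spots))
      hkl <- rbind(hkl, matrix(NA_integer_, spec$n_noise_spots, 3))
    }
    n <- length(fast)
    if (sum(label > 0) == 0)
      warning("image ", index, ": no predicted reflections on the panel")
    ord <- if (n > 0) sample.int(n) else integer(0)
    image <- image_model(sprintf("sim-%d-%d", spec$seed, index),
                         geom, spec$beam,
                         data.frame(id = seq_len(n), fast = fast[ord],
                                    slow = slow[ord]))
    truth <- structure(list(U = Us, label = label[ord],
                            hkl = hkl[ord, , drop = FALSE]),
                       class = "ground_truth")
    list(image = image, truth = truth)
  })
}

#' Simulate a series of still images
#'
#' @param spec A [simulation_spec()].
#' @param n_images Number of images.
#' @param priors Optional shared [crystal_priors()].
#' @return List of [simulate_image()] results.
#' @export
simulate_images <- function(spec, n_images, priors = NULL) {
  if (is.null(priors))
    priors <- crystal_priors(spec$cell, spec$spacegroup, d_max = 0.05)
  lapply(seq_len(n_images), function(ii) simulate_image(spec, ii, priors))
}

#' Compare found orientations against ground truth
#'
#' Greedy one-to-one matching of found solutions to true lattice
#' orientations by minimum symmetry-aware metric; a pair matches when its
#' metric does not exceed `metric_threshold` (0.25, i.e. about 10 degrees).
#'
#' @param truth A `ground_truth` (from [simulate_image()]).
#' @param found List of [orientation_solution()]s.
#' @param ops Cartesian symmetry operators ([rotational_symmetry_ops()]).
#' @param metric_threshold Match criterion in metric units.
#' @return List with `n_true`, `n_found`, `matched` (data frame: found,
#'   truth, metric), `n_matched`, `n_missed`, `n_spurious`.
#' @export
evaluate_solutions <- function(truth, found, ops, metric_threshold = 0.25) {
  n_t <- length(truth$U); n_f <- length(found)
  matched <- data.frame(found = integer(0), truth = integer(0),
                        metric = numeric(0))
  if (n_t > 0 && n_f > 0) {
    d <- matrix(Inf, n_f, n_t)
    for (a in seq_len(n_f))
      for (b in seq_len(n_t))
        d[a, b] <- similarity_metric(found[[a]], truth$U[[b]], ops)
    while (TRUE) {
      k <- which.min(d)
      if (!length(k) || !is.finite(d[k]) || d[k] > metric_threshold) break
      a <- (k - 1) %% n_f + 1; b <- (k - 1) %/% n_f + 1
      matched <- rbind(matched,
                       data.frame(found = a, truth = b, metric = d[k]))
      d[a, ] <- Inf; d[, b] <- Inf
    }
  }
  list(n_true = n_t, n_found = n_f, matched = matched,
       n_matched = nrow(matched), n_missed = n_t - nrow(matched),
       n_spurious = n_f - nrow(matched))
}
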