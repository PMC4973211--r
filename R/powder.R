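#' One-dimensional pseudo-powder pattern
#'
#' Histogram of all inter-spot vector lengths pooled over a set of images.
#' Unlike a conventional powder pattern (which superimposes images and needs
#' many of them), a pseudo-powder pattern is usable from a handful of stills,
#' and also shows off-axis distances that axial systematic absences remove
#' from conventional patterns. Peak positions depend on the unit cell and on
#' the experiment geometry, so comparing against the theoretical stick
#' pattern diagnoses detector-distance and wavelength errors.
#'
#' @param images List of [image_model()]s.
#' @param d_max Longest vector length histogrammed, inverse Angstrom.
#' @param bin_width Histogram bin width, inverse Angstrom.
#' @param filter_lattices If > 1, apply [filter_by_neighbours()] per image
#'   with this expected-lattice count before pooling.
#' @param tm,beam Tolerance model and beam for the optional filtering.
#' @return Object of class `"powder_pattern"`: `bin_edges`, `counts`,
#'   `n_images`, `n_vectors`.
#' @export
pseudo_powder <- function(images, d_max = 0.1, bin_width = 2e-4,
                          filter_lattices = 1, tm = tolerance_model(),
                          beam = NULL) {
  stopifnot(length(images) >= 1)
  lens <- unlist(lapply(images, function(im) {
    if (nrow(im$rlp) < 2) return(numeric(0))
    sv <- build_spot_vectors(im, d_max = d_max)
    if (filter_lattices > 1)
      sv <- filter_by_neighbours(sv, filter_lattices, tm,
                                 if (is.null(beam)) im$beam else beam)
    sv$length
  }))
  edges <- seq(0, d_max + bin_width, by = bin_width)
  counts <- if (length(lens) > 0)
    as.integer(table(cut(lens, breaks = edges, right = FALSE)))
  else integer(length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts,
                 n_images = length(images), n_vectors = length(lens)),
            class = "powder_pattern")
}

#' @export
print.powder_pattern <- function(x, ...) {
  cat(sprintf("<powder_pattern: %d vectors from %d image(s), %d bins>\n",
              x$n_vectors, x$n_images, length(x$counts)))
  invisible(x)
}

#' Agreement score between a pseudo-powder pattern and theoretical lengths
#'
#' Fraction of observed vectors (histogram mass) whose bin centre lies within
#' `tol` of some theoretical length. The score is 1 when every observed
#' length sits on a predicted ring, and for uniformly random lengths it
#' approaches the fraction of the axis covered by tolerance windows, so it is
#' a monotone, parameter-light criterion for geometry refinement.
#'
#' @param obs A [pseudo_powder()] result.
#' @param theory_lengths Numeric vector of theoretical lengths (e.g. the
#'   `length` column of [theoretical_pattern()]).
#' @param tol Matching tolerance, inverse Angstrom.
#' @return Scalar in 0..1 (0 for an empty pattern).
#' @export
powder_fit_score <- function(obs, theory_lengths, tol = 5e-4) {
  stopifnot(inherits(obs, "powder_pattern"))
  total <- sum(obs$counts)
  if (total == 0) return(0)
  centres <- obs$bin_edges[-length(obs$bin_edges)] + diff(obs$bin_edges) / 2
  tl <- sort(theory_lengths)
  pos <- findInterval(centres, tl)
  d_lo <- ifelse(pos >= 1, centres - tl[pmax(pos, 1L)], Inf)
  d_hi <- ifelse(pos < length(tl), tl[pmin(pos + 1L, length(tl))] - centres, Inf)
  near <- pmin(d_lo, d_hi) <= tol
  sum(obs$counts[near]) / total
}

#' Grid scan of one geometry parameter against the pseudo-powder pattern
#'
#' Re-back-projects every image's spot centroids under trial values of a
#' geometry or beam parameter, rebuilds the pseudo-powder pattern, and scores
#' it against the theoretical lengths; returns the trial grid with scores and
#' the argmax (ties resolved to the smallest trial value). This automates
#' the manual refinement of the detector distance or wavelength against the
#' sharpness/position of pseudo-powder rings.
#'
#' @param images List of [image_model()]s.
#' @param grid Numeric vector of trial parameter values.
#' @param parameter One of "distance_mm", "wavelength_A", "beam_centre_fast".
#' @param theory_lengths Theoretical lengths to score against.
#' @param d_max,bin_width Passed to [pseudo_powder()].
#' @param tol Passed to [powder_fit_score()].
#' @return List with `parameter`, `grid`, `scores`, `best` (argmax value).
#' @export
scan_geometry <- function(images, grid,
                          parameter = c("distance_mm", "wavelength_A",
                                        "beam_centre_fast"),
                          theory_lengths, d_max = 0.1, bin_width = 2e-4,
                          tol = 5e-4) {
  parameter <- match.arg(parameter)
  stopifnot(length(grid) >= 1)
  scores <- vapply(grid, function(val) {
    trial <- lapply(images, function(im) {
      g <- im$geometry; b <- im$beam
      if (parameter == "distance_mm") g$distance_mm <- val
      if (parameter == "wavelength_A") b$wavelength_A <- val
      if (parameter == "beam_centre_fast") g$beam_centre_px[1L] <- val
      image_model(im$id, g, b, im$spots)
    })
    pp <- pseudo_powder(trial, d_max = d_max, bin_width = bin_width)
    if (pp$n_vectors == 0) NA_real_
    else powder_fit_score(pp, theory_lengths, tol = tol)
  }, numeric(1))
  if (all(is.na(scores))) stop("no vectors at any grid point")
  best <- grid[which(scores == max(scores, na.rm = TRUE))]
  list(parameter = parameter, grid = grid, scores = scores,
       best = min(best))
}

#' Scan the detector distance against the pseudo-powder pattern
#'
#' Convenience wrapper around [scan_geometry()] for the most commonly
#' mis-measured parameter.
#'
#' @inheritParams scan_geometry
#' @return Best-fitting distance in mm (see [scan_geometry()] for details).
#' @export
scan_detector_distance <- function(images, grid, theory_lengths,
                                   d_max = 0.1, bin_width = 2e-4, tol = 5e-4) {
  scan_geometry(images, grid, "distance_mm", theory_lengths,
                d_max = d_max, bin_width = bin_width, tol = tol)$best
}
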