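#' Crystal priors for indexing
#'
#' Bundles everything indexing needs to know about the crystal: the unit
#' cell, space-group information, the Busing-Levy B matrix, the Cartesian
#' point-group rotations, and the table of theoretically allowed inter-spot
#' difference vectors up to `d_max`.
#'
#' @param cell A [unit_cell()].
#' @param sg A [space_group_info()] or a space-group symbol string.
#' @param d_max Longest inter-spot vector considered, inverse Angstrom.
#' @return Object of class `"crystal_priors"`.
#' @export
crystal_priors <- function(cell, sg, d_max = 0.1) {
  if (is.character(sg)) sg <- space_group_info(sg)
  theory <- enumerate_theoretical_vectors(cell, sg, d_max)
  structure(list(cell = cell, sg = sg,
                 B = busing_levy_matrix(cell),
                 ops = rotational_symmetry_ops(sg, cell),
                 lattice_ops = rotational_symmetry_ops(sg, cell,
                                                       lattice = TRUE),
                 theory = theory, d_max = d_max,
                 cache = new.env(parent = emptyenv())),
            class = "crystal_priors")
}

#' @export
print.crystal_priors <- function(x, ...) {
  cat(sprintf(paste0("<crystal_priors: %s, a=%.4g b=%.4g c=%.4g A, ",
                     "%d symmetry ops, %d theoretical vectors <= %.3g 1/A>\n"),
              x$sg$symbol, x$cell$a, x$cell$b, x$cell$c,
              length(x$ops), length(x$theory$length), x$d_max))
  invisible(x)
}

# Cached centring-allowed hkl ball up to a resolution limit (used by spot
# prediction and the simulator; one enumeration per priors object & limit).
.hkl_ball_cached <- function(priors, res_max) {
  key <- sprintf("ball_%.6g", res_max)
  if (is.null(priors$cache[[key]]))
    priors$cache[[key]] <- .allowed_hkl_ball(priors$cell, priors$sg$centring,
                                             res_max, cap = 8e6)
  priors$cache[[key]]
}

# Resolution limit of the detector corner (where prediction stops mattering).
.corner_resolution <- function(geometry, beam) {
  cx <- max(geometry$beam_centre_px[1L],
            geometry$n_fast - geometry$beam_centre_px[1L])
  cy <- max(geometry$beam_centre_px[2L],
            geometry$n_slow - geometry$beam_centre_px[2L])
  r <- sqrt(cx^2 + cy^2) * geometry$pixel_size_mm
  2 * sin(atan2(r, geometry$distance_mm) / 2) / beam$wavelength_A
}
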