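#' Unit cell
#'
#' @param a,b,c Cell edge lengths in Angstrom. `b` and `c` default to `a`
#'   (convenient for cubic cells).
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return An object of class `"unit_cell"`.
#' @examples
#' unit_cell(106.1)                      # cubic
#' unit_cell(92.9, 92.9, 130.4, gamma = 120)  # hexagonal
#' @export
unit_cell <- function(a, b = a, c = a, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180,
            gamma > 0, gamma < 180)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  vol_fac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vol_fac <= 1e-12) stop("degenerate unit cell (volume ~ 0)")
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 volume = a * b * c * sqrt(vol_fac)),
            class = "unit_cell")
}

#' Busing-Levy B matrix
#'
#' Upper-triangular matrix mapping integer Miller indices (h, k, l) to
#' Cartesian reciprocal coordinates in inverse Angstrom, in the standard
#' Busing & Levy convention (a* along x, b* in the xy plane). For a cubic
#' cell B = (1/a) I.
#'
#' @param cell A [unit_cell()].
#' @return 3 x 3 numeric matrix.
#' @export
busing_levy_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  deg <- pi / 180
  a <- cell$a; b <- cell$b; c <- cell$c
  sa <- sin(cell$alpha * deg); ca <- cos(cell$alpha * deg)
  sb <- sin(cell$beta * deg);  cb <- cos(cell$beta * deg)
  sg <- sin(cell$gamma * deg); cg <- cos(cell$gamma * deg)
  V <- cell$volume
  as_ <- b * c * sa / V
  bs_ <- a * c * sb / V
  cs_ <- a * b * sg / V
  cas <- (cb * cg - ca) / (sb * sg)
  cbs <- (ca * cg - cb) / (sa * sg)
  cgs <- (ca * cb - cg) / (sa * sb)
  sgs <- sqrt(max(0, 1 - cgs^2))
  sbs <- sqrt(max(0, 1 - cbs^2))
  matrix(c(as_, bs_ * cgs,       cs_ * cbs,
           0,   bs_ * sgs,      -cs_ * sbs * ca,
           0,   0,               1 / c),
         nrow = 3L, byrow = TRUE)
}

#' Lattice-centring reflection condition
#'
#' Tests whether integer index triples are allowed by a lattice centring
#' type. Centring absences forbid not only reflections but also the
#' corresponding inter-reflection difference vectors, which is why they
#' shape the table of allowed inter-spot distances (axial screw-axis
#' absences do not, and are deliberately not applied here).
#'
#' @param hkl Integer length-3 vector or n x 3 matrix.
#' @param centring One of "P", "I", "F", "A", "B", "C", "R".
#' @return Logical vector.
#' @export
centring_allowed <- function(hkl, centring) {
  m <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3L)
  h <- m[, 1L]; k <- m[, 2L]; l <- m[, 3L]
  switch(centring,
         P = rep(TRUE, length(h)),
         I = (h + k + l) %% 2 == 0,
         F = (h %% 2 == k %% 2) & (k %% 2 == l %% 2),
         A = (k + l) %% 2 == 0,
         B = (h + l) %% 2 == 0,
         C = (h + k) %% 2 == 0,
         R = (-h + k + l) %% 3 == 0,
         stop("unknown centring symbol: ", centring))
}

# Real-space rotation generators of the supported point groups; the full
# group is produced by closure under multiplication.
.pg_generators <- list(
  "1"   = list(diag(3)),
  "222" = list(diag(c(1, -1, -1)), diag(c(-1, 1, -1))),
  "23"  = list(matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE),
               diag(c(-1, -1, 1)), diag(c(1, -1, -1))),
  "622" = list(matrix(c(1, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE),
               matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3, byrow = TRUE)),
  "432" = list(matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE),
               matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE))
)

# pg: point-group rotations of the crystal; lattice_pg: rotation subgroup of
# the lattice holohedry. They differ for the 23 point group, whose cubic
# lattice admits 432: spot positions alone cannot tell the two settings
# apart (the familiar indexing ambiguity, resolvable only with intensities).
.sg_table <- list(
  P1       = list(centring = "P", pg = "1",   lattice_pg = "1"),
  P212121  = list(centring = "P", pg = "222", lattice_pg = "222"),
  I23      = list(centring = "I", pg = "23",  lattice_pg = "432"),
  F23      = list(centring = "F", pg = "23",  lattice_pg = "432"),
  P6122    = list(centring = "P", pg = "622", lattice_pg = "622")
)

.group_closure <- function(gens) {
  ops <- list(diag(3))
  keys <- paste(round(diag(3)), collapse = ",")
  frontier <- gens
  while (length(frontier) > 0) {
    nxt <- list()
    for (g in frontier) {
      for (o in ops) {
        for (prod in list(g %*% o, o %*% g)) {
          key <- paste(round(prod), collapse = ",")
          if (!(key %in% keys)) {
            ops[[length(ops) + 1L]] <- round(prod)
            keys <- c(keys, key)
            nxt[[length(nxt) + 1L]] <- round(prod)
          }
        }
      }
    }
    frontier <- nxt
    if (length(ops) > 192) stop("symmetry generator set does not close")
  }
  ops
}

#' Space-group information
#'
#' Holds the lattice centring type and the rotational parts of the point
#' group, which is all the symmetry knowledge this package needs: centring
#' controls which difference vectors exist, and the point-group rotations
#' define when two orientation matrices are symmetry-equivalent.
#'
#' A small built-in table covers P1, P212121, I23, F23 and P6122; any other
#' group can be supplied generically as a centring symbol plus an explicit
#' list of integer rotation matrices (fractional, real-space basis).
#'
#' @param symbol Space-group symbol, e.g. "I23".
#' @param centring,rotations Generic alternative to `symbol`.
#' @return An object of class `"space_group_info"` with fields `symbol`,
#'   `centring` and `rotations` (list of 3 x 3 integer matrices acting on
#'   real-space fractional coordinates).
#' @export
space_group_info <- function(symbol = NULL, centring = NULL, rotations = NULL) {
  if (!is.null(symbol)) {
    key <- gsub("[ _()]", "", symbol)
    entry <- .sg_table[[key]]
    if (is.null(entry))
      stop("unsupported space group '", symbol,
           "'; supply centring= and rotations= explicitly")
    rot <- .group_closure(.pg_generators[[entry$pg]])
    return(structure(list(symbol = key, centring = entry$centring,
                          rotations = rot,
                          lattice_rotations =
                            .group_closure(.pg_generators[[entry$lattice_pg]])),
                     class = "space_group_info"))
  }
  stopifnot(!is.null(centring))
  if (is.null(rotations)) rotations <- list(diag(3))
  rotations <- lapply(rotations, function(m) {
    m <- matrix(as.numeric(m), 3L, 3L)
    if (abs(det(m) - 1) > 1e-9) stop("rotations must have determinant +1")
    m
  })
  rot <- .group_closure(rotations)
  structure(list(symbol = paste0(centring, "-custom"), centring = centring,
                 rotations = rot, lattice_rotations = rot),
            class = "space_group_info")
}

#' Point-group rotation operators in the Cartesian frame
#'
#' Converts the stored fractional rotation matrices to operators acting on
#' Cartesian reciprocal coordinates: a real-space rotation W acts on Miller
#' indices as (W^-1)^T, and the Cartesian form is B (W^-1)^T B^-1. Each
#' returned matrix is orthogonal with determinant +1 and maps the theoretical
#' vector set onto itself.
#'
#' @param sg A [space_group_info()].
#' @param cell A [unit_cell()] (fixes the Cartesian frame through B).
#' @param lattice Use the rotation subgroup of the lattice holohedry instead
#'   of the crystal point group. The two differ for point group 23 on a
#'   cubic lattice (23 vs 432): spot positions alone determine an
#'   orientation only up to the lattice group, so duplicate detection and
#'   position-based validation should use `lattice = TRUE`.
#' @return List of 3 x 3 orthogonal matrices (identity first).
#' @export
rotational_symmetry_ops <- function(sg, cell, lattice = FALSE) {
  stopifnot(inherits(sg, "space_group_info"))
  B <- busing_levy_matrix(cell)
  Binv <- solve(B)
  src <- if (lattice) sg$lattice_rotations else sg$rotations
  lapply(src, function(W) B %*% t(solve(W)) %*% Binv)
}

# All centring-allowed integer triples with |B hkl| <= d_max, excluding the
# origin. Bound |h| <= a d_max holds exactly because h is the projection of
# the reciprocal vector onto the real-space basis vector a.
.allowed_hkl_ball <- function(cell, centring, d_max, cap = 4e6,
                              include_origin = FALSE) {
  B <- busing_levy_matrix(cell)
  hmax <- ceiling(cell$a * d_max)
  kmax <- ceiling(cell$b * d_max)
  lmax <- ceiling(cell$c * d_max)
  n_grid <- (2 * hmax + 1) * (2 * kmax + 1) * (2 * lmax + 1)
  if (n_grid > cap)
    stop("d_max too large: index grid has ", n_grid, " entries (cap ", cap, ")")
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  keep <- centring_allowed(grid, centring)
  if (!include_origin)
    keep <- keep & (grid[, 1L] != 0 | grid[, 2L] != 0 | grid[, 3L] != 0)
  grid <- grid[keep, , drop = FALSE]
  cart <- grid %*% t(B)
  len <- sqrt(rowSums(cart^2))
  sel <- len <= d_max
  list(dhkl = grid[sel, , drop = FALSE],
       cart = cart[sel, , drop = FALSE],
       length = len[sel])
}

#' Enumerate theoretically allowed inter-reflection difference vectors
#'
#' All integer difference vectors dhkl allowed by the lattice centring with
#' |B dhkl| <= d_max, i.e. the "theoretical space" that observed inter-spot
#' vectors are matched against. Both dhkl and -dhkl are kept as distinct
#' entries. Axial (screw-axis) absences are not applied: general inter-spot
#' difference vectors are unaffected by them.
#'
#' @param cell A [unit_cell()].
#' @param sg A [space_group_info()].
#' @param d_max Longest difference-vector length considered, inverse Angstrom.
#' @param cap Guard on the enumeration grid size.
#' @return Object of class `"theoretical_vectors"`: list with `dhkl`
#'   (n x 3 integer), `cart` (n x 3, inverse Angstrom), `length` (n), sorted
#'   by length, plus the generating `cell`, `sg` and `B` as attributes.
#' @export
enumerate_theoretical_vectors <- function(cell, sg, d_max, cap = 4e6) {
  stopifnot(d_max > 0)
  ball <- .allowed_hkl_ball(cell, sg$centring, d_max, cap = cap)
  ord <- order(ball$length, ball$dhkl[, 1L], ball$dhkl[, 2L], ball$dhkl[, 3L])
  structure(list(dhkl = ball$dhkl[ord, , drop = FALSE],
                 cart = ball$cart[ord, , drop = FALSE],
                 length = ball$length[ord]),
            cell = cell, sg = sg, B = busing_levy_matrix(cell),
            class = "theoretical_vectors")
}

#' Distinct theoretical lengths with multiplicities
#'
#' Collates the enumerated difference vectors into distinct lengths (binned
#' within 1e-6 inverse Angstrom) with the count of index triples sharing each
#' length: the stick pattern overlaid on pseudo-powder histograms.
#'
#' @param theory A [enumerate_theoretical_vectors()] result.
#' @return Data frame with columns `length` and `multiplicity`.
#' @export
theoretical_pattern <- function(theory) {
  len <- theory$length
  if (length(len) == 0)
    return(data.frame(length = numeric(0), multiplicity = integer(0)))
  len <- sort(len)
  grp <- cumsum(c(TRUE, diff(len) > 1e-6))
  data.frame(length = as.numeric(tapply(len, grp, mean)),
             multiplicity = as.integer(tapply(len, grp, length)),
             row.names = NULL)
}
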