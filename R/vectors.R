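#' Tolerance model for inter-spot vector lengths
#'
#' Two observed vectors (or an observed and a theoretical vector) are
#' considered the same length within a tolerance that is either a constant,
#' or computed per length as the maximum separation of two finite-size rlps
#' sitting on opposite extremes of the nest of Ewald spheres spanned by the
#' bandwidth: tol(d) = 2 rlp_radius + d * bandwidth.
#'
#' @param mode "fixed" or "variable".
#' @param fixed_tol Constant tolerance in inverse Angstrom (fixed mode).
#' @param rlp_radius Effective reciprocal-lattice point radius, inverse
#'   Angstrom (variable mode).
#' @param bandwidth Fractional bandwidth; if NULL, taken from the beam at
#'   evaluation time.
#' @return Object of class `"tolerance_model"`.
#' @export
tolerance_model <- function(mode = c("fixed", "variable"), fixed_tol = 5e-4,
                            rlp_radius = 1e-4, bandwidth = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") stopifnot(fixed_tol > 0)
  stopifnot(rlp_radius >= 0)
  structure(list(mode = mode, fixed_tol = fixed_tol,
                 rlp_radius = rlp_radius, bandwidth = bandwidth),
            class = "tolerance_model")
}

#' Length tolerance for a given vector length
#'
#' @param length Vector length(s), inverse Angstrom.
#' @param tm A [tolerance_model()].
#' @param beam A [beam()] (supplies the bandwidth in variable mode when the
#'   model does not carry one).
#' @return Tolerance(s), inverse Angstrom.
#' @export
length_tolerance <- function(length, tm, beam = NULL) {
  stopifnot(all(length >= 0))
  if (tm$mode == "fixed") return(rep(tm$fixed_tol, length(length)))
  bw <- if (!is.null(tm$bandwidth)) tm$bandwidth else beam$bandwidth
  2 * tm$rlp_radius + length * bw
}

#' Build observed inter-spot vectors
#'
#' All unordered spot pairs of an image whose back-projected reciprocal
#' coordinates differ by at most `d_max`. Optionally each spot is also paired
#' with the reciprocal origin (Miller index (0,0,0)), which boosts the number
#' of usable vectors on sparse images.
#'
#' @param image An [image_model()].
#' @param d_max Longest vector retained, inverse Angstrom.
#' @param include_origin Pair every spot with the reciprocal origin too.
#' @return Object of class `"spot_vectors"`: list with integer `i`, `j`
#'   (spot row indices; 0 denotes the origin pseudo-spot), `delta` (n x 3),
#'   `length` (n), and `matches` (populated by [match_to_theory()]).
#' @export
build_spot_vectors <- function(image, d_max = Inf, include_origin = FALSE) {
  rlp <- image$rlp
  n <- nrow(rlp)
  stopifnot(n >= 2 || (include_origin && n >= 1))
  if (n >= 2) {
    pr <- utils::combn(n, 2L)
    i <- pr[1L, ]; j <- pr[2L, ]
    delta <- rlp[j, , drop = FALSE] - rlp[i, , drop = FALSE]
  } else {
    i <- integer(0); j <- integer(0); delta <- matrix(0, 0, 3)
  }
  if (include_origin) {
    i <- c(i, rep(0L, n))
    j <- c(j, seq_len(n))
    delta <- rbind(delta, rlp)
  }
  len <- sqrt(rowSums(delta^2))
  keep <- len <= d_max & len > 0
  structure(list(i = i[keep], j = j[keep],
                 delta = delta[keep, , drop = FALSE],
                 length = len[keep], matches = NULL),
            image_id = image$id, class = "spot_vectors")
}

#' Match observed vectors to theoretical lattice vectors by length
#'
#' An observed vector is kept for indexing if its length lies within the
#' length tolerance of at least one theoretical difference-vector length;
#' its `matches` field then lists the indices of all theoretical vectors in
#' the matching length families. Unmatched vectors are dropped from the
#' indexing pool (they still contribute to pseudo-powder patterns, which are
#' built from unmatched vectors upstream).
#'
#' @param sv A [build_spot_vectors()] result.
#' @param theory A [enumerate_theoretical_vectors()] result.
#' @param tm A [tolerance_model()].
#' @param beam A [beam()].
#' @return `sv` restricted to matched vectors, with `matches` populated
#'   (list of integer index vectors into `theory`).
#' @export
match_to_theory <- function(sv, theory, tm, beam) {
  stopifnot(length(theory$length) > 0)
  tl <- theory$length                      # sorted ascending
  tol <- length_tolerance(sv$length, tm, beam)
  lo <- findInterval(sv$length - tol, tl) + 1L
  hi <- findInterval(sv$length + tol, tl)
  keep <- which(hi >= lo)
  matches <- lapply(keep, function(k) seq.int(lo[k], hi[k]))
  structure(list(i = sv$i[keep], j = sv$j[keep],
                 delta = sv$delta[keep, , drop = FALSE],
                 length = sv$length[keep], matches = matches),
            image_id = attr(sv, "image_id"), class = "spot_vectors")
}

#' Expected number of lattices on an image
#'
#' n = round(s / l) with round-half-up, floored at one: the spot count of the
#' image divided by the typical number of spots one lattice contributes.
#'
#' @param s Number of spots on the image.
#' @param l Expected spots per lattice.
#' @return Integer >= 1.
#' @export
expected_lattices <- function(s, l) {
  stopifnot(s >= 0, l > 0)
  max(1L, as.integer(floor(s / l + 0.5)))
}

#' Filter inter-spot vectors by neighbour score
#'
#' Scores every vector by the number of other vectors equal to it (or its
#' negation) within the length tolerance, sorts by score, and keeps the top
#' fraction p_t = 1/n, where n is the expected number of lattices: with n
#' lattices only about 1/n of vectors connect spots of the same lattice, and
#' those repeat across the image and therefore have many neighbours, so the
#' retained set is enriched in intra-lattice vectors. Ties at the cutoff are
#' all retained, making the result order-independent. With n = 1 the input
#' is returned unchanged.
#'
#' @param sv A [spot_vectors][build_spot_vectors()] object.
#' @param n Expected number of lattices (see [expected_lattices()]).
#' @param tm A [tolerance_model()].
#' @param beam A [beam()].
#' @return Filtered `spot_vectors`, in decreasing neighbour-score order, with
#'   a `neighbour_score` field.
#' @export
filter_by_neighbours <- function(sv, n, tm, beam) {
  stopifnot(n >= 1)
  if (n == 1) return(sv)
  m <- length(sv$length)
  if (m == 0) return(sv)
  tol <- length_tolerance(sv$length, tm, beam)
  D <- sv$delta
  nrm2 <- rowSums(D^2)
  score <- integer(m)
  block <- 512L
  for (start in seq(1L, m, by = block)) {
    idx <- start:min(start + block - 1L, m)
    G <- D[idx, , drop = FALSE] %*% t(D)   # inner products
    # |a-b|^2 = |a|^2+|b|^2-2ab ; |a+b|^2 = |a|^2+|b|^2+2ab
    S <- outer(nrm2[idx], nrm2, "+")
    d2 <- pmin(S - 2 * G, S + 2 * G)
    hit <- d2 <= (tol[idx])^2
    score[idx] <- as.integer(rowSums(hit)) - 1L  # exclude self
  }
  p_t <- 1 / n
  ord <- order(score, decreasing = TRUE)
  cutoff <- score[ord][ceiling(p_t * m)]
  keep <- ord[score[ord] >= cutoff]
  out <- list(i = sv$i[keep], j = sv$j[keep],
              delta = sv$delta[keep, , drop = FALSE],
              length = sv$length[keep],
              matches = if (!is.null(sv$matches)) sv$matches[keep] else NULL,
              neighbour_score = score[keep])
  structure(out, image_id = attr(sv, "image_id"), class = "spot_vectors")
}
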