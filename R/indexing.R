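#' Indexing parameters
#'
#' Collects the tunable parameters of both indexing branches.
#'
#' @param method "network" (grow self-consistent vector networks; the more
#'   generally robust branch) or "cluster" (cluster rotation matrices from
#'   all candidate vector pairs; suited to cubic cells at low resolution).
#' @param d_max Longest inter-spot vector used for indexing, inverse
#'   Angstrom.
#' @param pair_angle_tol Maximum discrepancy (degrees) between the observed
#'   inter-vector angle and the theoretical one for a pair/assignment to be
#'   considered.
#' @param neighbour_radius Angular radius (degrees) within which two
#'   orientation matrices count as neighbours / consistent, applied through
#'   the symmetry-aware similarity metric.
#' @param network_threshold Minimum number of vectors a network must reach to
#'   count as an indexing solution rather than noise.
#' @param require_common_spot Only admit vectors sharing at least one spot
#'   with the existing network (favours single-lattice membership).
#' @param max_lattices Maximum number of lattices sought per image.
#' @param tolerance A [tolerance_model()] for vector-length matching.
#' @param duplicate_metric_threshold Two solutions closer than this (metric
#'   units; 0.25 ~ 10 degrees) are symmetry-duplicates.
#' @param include_origin Pair spots with the reciprocal origin as well.
#' @param min_pair_angle Observed vector pairs closer than this to (anti)
#'   parallel (degrees) are too degenerate to define an orientation.
#' @param sigma_t,min_peak Acceptance thresholds, see [accept_solution()].
#' @param accept_d_min Minimum spot resolution (inverse Angstrom) entering
#'   the acceptance statistic (see [solution_wavelengths()]).
#' @param accept_assign_tol Assignment-distance cut for the acceptance
#'   statistic (see [solution_wavelengths()]).
#' @param rlp_radius Effective rlp radius for spot prediction/removal.
#' @param removal_radius_px Pixel radius for removing predicted spots.
#' @param filter_lattices Expected-lattice count for the optional
#'   neighbour-score pre-filter (1 = off); "auto" estimates it from the spot
#'   count via [expected_lattices()] with `l_per_lattice`.
#' @param l_per_lattice Expected spots contributed by one lattice (used by
#'   the "auto" filter).
#' @param max_vectors Cap on the matched-vector pool per image
#'   (deterministic truncation in seed order).
#' @param max_seeds,max_seed_combos,max_growth_attempts Work caps for the
#'   network branch (seeds tried per lattice, assignment combinations per
#'   seed, and growth attempts per lattice).
#' @param max_cluster_vectors,max_candidates,max_acceptance_tests Work caps
#'   for the cluster branch.
#' @return Object of class `"indexing_params"`.
#' @export
indexing_params <- function(method = c("network", "cluster"),
                            d_max = 0.1,
                            pair_angle_tol = 1,
                            neighbour_radius = 8,
                            network_threshold = 20,
                            require_common_spot = TRUE,
                            max_lattices = 1,
                            tolerance = tolerance_model(),
                            duplicate_metric_threshold = 0.25,
                            include_origin = FALSE,
                            min_pair_angle = 10,
                            sigma_t = 0.08,
                            min_peak = Inf,
                            accept_d_min = 0.1,
                            accept_assign_tol = 1e-3,
                            rlp_radius = 1e-4,
                            removal_radius_px = 2,
                            filter_lattices = 1,
                            l_per_lattice = 100,
                            max_vectors = 400,
                            max_seeds = 40,
                            max_seed_combos = 12,
                            max_growth_attempts = 120,
                            max_cluster_vectors = 60,
                            max_candidates = 1500,
                            max_acceptance_tests = 25) {
  method <- match.arg(method)
  stopifnot(d_max > 0, pair_angle_tol > 0, neighbour_radius > 0,
            network_threshold > 0, max_lattices >= 1,
            duplicate_metric_threshold > 0,
            duplicate_metric_threshold < 2 * sqrt(2),
            min_pair_angle > 0, sigma_t > 0, rlp_radius >= 0,
            removal_radius_px > 0, max_vectors >= 2)
  structure(as.list(environment()), class = "indexing_params")
}

# Seed ordering: most length-specific vectors first (fewest theoretical
# matches), then longest first (longer vectors carry proportionately lower
# angular error).
.seed_order <- function(sv) {
  nm <- vapply(sv$matches, length, integer(1))
  order(nm, -sv$length)
}

.subset_sv <- function(sv, idx) {
  structure(list(i = sv$i[idx], j = sv$j[idx],
                 delta = sv$delta[idx, , drop = FALSE],
                 length = sv$length[idx],
                 matches = if (!is.null(sv$matches)) sv$matches[idx] else NULL),
            image_id = attr(sv, "image_id"), class = "spot_vectors")
}

# Build, match, optionally pre-filter and cap the vector pool of an image.
.indexing_pool <- function(image, params, priors) {
  sv <- build_spot_vectors(image, d_max = min(params$d_max, priors$d_max),
                           include_origin = params$include_origin)
  if (length(sv$length) == 0) return(sv)
  matched <- match_to_theory(sv, priors$theory, params$tolerance, image$beam)
  nf <- params$filter_lattices
  if (identical(nf, "auto"))
    nf <- expected_lattices(nrow(image$spots), params$l_per_lattice)
  if (nf > 1) {
    # keep the most-repeated vectors (filter returns score-descending order)
    # before seed-ordering: repeated vectors are the intra-lattice ones
    matched <- filter_by_neighbours(matched, nf, params$tolerance, image$beam)
    matched <- .subset_sv(matched,
                          seq_len(min(length(matched$length),
                                      params$max_vectors)))
  }
  ord <- .seed_order(matched)
  .subset_sv(matched, ord[seq_len(min(length(ord), params$max_vectors))])
}

#' Candidate vector pairs with theoretical assignments
#'
#' Enumerates every pair of matched observed vectors whose mutual angle is
#' compatible (within `pair_angle_tol` degrees) with the angle between some
#' pair of their matching theoretical vectors. Each compatible assignment is
#' one candidate orientation. Near-(anti)parallel observed pairs are
#' excluded as degenerate.
#'
#' @param matched A [match_to_theory()] result.
#' @param theory The [enumerate_theoretical_vectors()] table used to match.
#' @param pair_angle_tol Angle agreement tolerance, degrees.
#' @param min_pair_angle Degeneracy exclusion angle, degrees.
#' @return Data frame with columns `v1`, `v2` (vector indices), `t1`, `t2`
#'   (theory row indices) and `angle_error_deg`.
#' @export
candidate_pairs <- function(matched, theory, pair_angle_tol = 1,
                            min_pair_angle = 10) {
  m <- length(matched$length)
  out <- list()
  if (m < 2) return(data.frame(v1 = integer(0), v2 = integer(0),
                               t1 = integer(0), t2 = integer(0),
                               angle_error_deg = numeric(0)))
  vhat <- matched$delta / matched$length
  thr_unit <- theory$cart / theory$length
  tol <- pair_angle_tol * pi / 180
  min_a <- min_pair_angle * pi / 180
  for (a in 1:(m - 1)) {
    for (b in (a + 1):m) {
      ca <- sum(vhat[a, ] * vhat[b, ])
      ang_obs <- acos(max(-1, min(1, ca)))
      if (ang_obs < min_a || pi - ang_obs < min_a) next
      ta <- matched$matches[[a]]; tb <- matched$matches[[b]]
      cth <- thr_unit[ta, , drop = FALSE] %*% t(thr_unit[tb, , drop = FALSE])
      err <- abs(acos(pmin(pmax(cth, -1), 1)) - ang_obs)
      hit <- which(err <= tol, arr.ind = TRUE)
      if (nrow(hit) > 0)
        out[[length(out) + 1L]] <-
          data.frame(v1 = a, v2 = b, t1 = ta[hit[, 1L]], t2 = tb[hit[, 2L]],
                     angle_error_deg = err[hit] * 180 / pi)
    }
  }
  if (length(out) == 0)
    return(data.frame(v1 = integer(0), v2 = integer(0),
                      t1 = integer(0), t2 = integer(0),
                      angle_error_deg = numeric(0)))
  do.call(rbind, out)
}

.grow_one <- function(sol0, seed_idx, seed_t, partner_idx, partner_t,
                      pool, priors, params, thr8) {
  n_pool <- length(pool$length)
  vhat <- pool$vhat
  thr_unit <- pool$thr_unit
  member <- logical(n_pool)
  member[c(seed_idx, partner_idx)] <- TRUE
  assignment <- integer(n_pool)
  assignment[seed_idx] <- seed_t
  assignment[partner_idx] <- partner_t
  spot_in <- rep(FALSE, pool$n_spots + 1L)
  spot_in[pool$i[c(seed_idx, partner_idx)] + 1L] <- TRUE
  spot_in[pool$j[c(seed_idx, partner_idx)] + 1L] <- TRUE
  U0 <- sol0$U
  seed_hat <- vhat[seed_idx, ]
  a_hat <- thr_unit[seed_t, ]
  min_a <- params$min_pair_angle * pi / 180
  tol <- params$pair_angle_tol * pi / 180
  screen_cos <- cos(min(pi / 2, 1.5 * params$neighbour_radius * pi / 180 +
                          2 * tol))
  ang_obs_seed <- acos(pmin(1, pmax(-1, as.numeric(vhat %*% seed_hat))))
  pred_dir <- vhat %*% U0          # candidate obs dirs in theory frame
  repeat {
    added <- FALSE
    for (v in seq_len(n_pool)) {
      if (member[v]) next
      if (params$require_common_spot &&
          !spot_in[pool$i[v] + 1L] && !spot_in[pool$j[v] + 1L]) next
      mt <- pool$matches[[v]]
      # (b) angle pre-screen against the seed member's assignment
      ang_thr <- acos(pmin(1, pmax(-1,
        as.numeric(thr_unit[mt, , drop = FALSE] %*% a_hat))))
      ok <- abs(ang_thr - ang_obs_seed[v]) <= tol
      if (!any(ok)) next
      # orientation screen: assignment direction must agree with consensus
      dots_signed <- as.numeric(thr_unit[mt, , drop = FALSE] %*% pred_dir[v, ])
      cand <- mt[ok & dots_signed >= screen_cos]
      if (length(cand) == 0) next
      errs <- abs(ang_thr[match(cand, mt)] - ang_obs_seed[v])
      cand <- cand[order(errs)][seq_len(min(2L, length(cand)))]
      # (c) pairwise matrix against an anchor member, checked on the metric
      anchor <- seed_idx
      av <- acos(max(-1, min(1, sum(vhat[v, ] * vhat[anchor, ]))))
      if (av < min_a || pi - av < min_a) {
        anchor <- partner_idx
        av <- acos(max(-1, min(1, sum(vhat[v, ] * vhat[anchor, ]))))
        if (av < min_a || pi - av < min_a) next
      }
      for (b in cand) {
        M <- try(matrix_from_vector_pair(
          pool$delta[anchor, ], pool$delta[v, ],
          priors$theory$cart[assignment[anchor], ], priors$theory$cart[b, ],
          priors$B), silent = TRUE)
        if (inherits(M, "try-error")) next
        if (similarity_metric(M$U, U0, priors$lattice_ops) <= thr8) {
          member[v] <- TRUE
          assignment[v] <- b
          spot_in[pool$i[v] + 1L] <- TRUE
          spot_in[pool$j[v] + 1L] <- TRUE
          added <- TRUE
          break
        }
      }
    }
    if (!added) break
  }
  list(member = which(member), assignment = assignment, size = sum(member))
}

#' Grow an inter-spot vector network from a seed vector
#'
#' Starting from one matched vector, finds a partner vector (sharing a spot
#' when required) and an assignment pair whose observed and theoretical
#' angles agree, builds the corresponding orientation, and then grows the
#' network: a vector joins if (a) it shares a spot with the network (when
#' required), (b) its angle to the seed member is consistent with its
#' candidate theoretical assignment, and (c) the orientation built from it
#' and an existing member lies within the angular neighbourhood of the
#' network's consensus under the symmetry-aware metric. Growth iterates with
#' an explicit pass loop (equivalent to depth-first recursion) until no
#' vector can be added. The network is a solution only if it reaches
#' `network_threshold` vectors.
#'
#' @param seed Index of the seed vector in `pool`.
#' @param pool A matched [spot_vectors][match_to_theory()] object.
#' @param params An [indexing_params()].
#' @param priors A [crystal_priors()].
#' @param n_spots Number of spots on the image.
#' @return Object of class `"vector_network"` (fields `members`,
#'   `assignments`, `spots`, `consensus`, `size`, `attempts`), or `NULL`
#'   when no network reaches the threshold ("too small").
#' @export
grow_network <- function(seed, pool, params, priors, n_spots) {
  m <- length(pool$length)
  if (m < 2 || length(pool$matches[[seed]]) == 0) return(NULL)
  thr8 <- angle_threshold_to_metric(params$neighbour_radius)
  p <- list(i = pool$i, j = pool$j, delta = pool$delta, length = pool$length,
            matches = pool$matches, vhat = pool$delta / pool$length,
            thr_unit = priors$theory$cart / priors$theory$length,
            n_spots = n_spots)
  tol <- params$pair_angle_tol * pi / 180
  min_a <- params$min_pair_angle * pi / 180
  seed_hat <- p$vhat[seed, ]
  shares <- pool$i == pool$i[seed] | pool$i == pool$j[seed] |
    pool$j == pool$i[seed] | pool$j == pool$j[seed]
  partners <- setdiff(if (params$require_common_spot) which(shares)
                      else seq_len(m), seed)
  combos_tried <- 0L
  for (u in partners) {
    ang_obs <- acos(max(-1, min(1, sum(seed_hat * p$vhat[u, ]))))
    if (ang_obs < min_a || pi - ang_obs < min_a) next
    ta <- pool$matches[[seed]]; tb <- pool$matches[[u]]
    cth <- p$thr_unit[ta, , drop = FALSE] %*% t(p$thr_unit[tb, , drop = FALSE])
    err <- abs(acos(pmin(pmax(cth, -1), 1)) - ang_obs)
    hit <- which(err <= tol, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    hit <- hit[order(err[hit]), , drop = FALSE]
    for (r in seq_len(nrow(hit))) {
      combos_tried <- combos_tried + 1L
      if (combos_tried > params$max_seed_combos) return(NULL)
      a <- ta[hit[r, 1L]]; b <- tb[hit[r, 2L]]
      sol0 <- try(matrix_from_vector_pair(pool$delta[seed, ], pool$delta[u, ],
                                          priors$theory$cart[a, ],
                                          priors$theory$cart[b, ], priors$B,
                                          source = list(seed = seed,
                                                        partner = u)),
                  silent = TRUE)
      if (inherits(sol0, "try-error")) next
      net <- .grow_one(sol0, seed, a, u, b, p, priors, params, thr8)
      if (net$size >= params$network_threshold) {
        spots <- sort(unique(c(pool$i[net$member], pool$j[net$member])))
        return(structure(list(members = net$member,
                              assignments = net$assignment[net$member],
                              spots = spots[spots > 0],
                              consensus = sol0, size = net$size,
                              attempts = combos_tried),
                         class = "vector_network"))
      }
    }
  }
  NULL
}

.is_duplicate <- function(sol, solutions, ops, threshold) {
  for (s in solutions)
    if (similarity_metric(sol$U, s$U, ops) < threshold) return(TRUE)
  FALSE
}

#' Index one image by growing inter-spot vector networks
#'
#' Iterates seed vectors (most specific and longest first) until a network
#' reaches the size threshold and its consensus orientation passes the
#' Ewald-wavelength acceptance test; the accepted solution's predicted spots
#' are then removed and indexing resumes on the remainder, up to
#' `max_lattices` solutions. Networks reproducing an already-determined
#' orientation (or a symmetry-equivalent one) are rejected.
#'
#' @param image An [image_model()].
#' @param params An [indexing_params()].
#' @param priors A [crystal_priors()].
#' @return List of accepted [orientation_solution()]s (possibly empty), each
#'   annotated with `network_size`, `stats` and `accepted`.
#' @export
network_index <- function(image, params, priors) {
  solutions <- list()
  current <- image
  for (lat in seq_len(params$max_lattices)) {
    if (nrow(current$spots) < 3) break
    pool <- .indexing_pool(current, params, priors)
    m <- length(pool$length)
    if (m < params$network_threshold) break
    found <- NULL
    attempts <- 0L
    for (seed in seq_len(min(m, params$max_seeds))) {
      net <- grow_network(seed, pool, params, priors, nrow(current$spots))
      attempts <- attempts + 1L
      if (is.null(net)) {
        if (attempts >= params$max_growth_attempts) break
        next
      }
      sol <- net$consensus
      if (.is_duplicate(sol, solutions, priors$lattice_ops,
                        params$duplicate_metric_threshold)) next
      stats <- solution_wavelengths(sol, current, priors, d_min = params$accept_d_min,
                                    assign_tol = params$accept_assign_tol)
      if (accept_solution(stats, params$sigma_t, params$min_peak)) {
        sol$stats <- stats
        sol$network_size <- net$size
        sol$accepted <- TRUE
        sol$source <- list(method = "network", lattice = lat,
                           n_spots = length(net$spots))
        found <- sol
        break
      }
      if (attempts >= params$max_growth_attempts) break
    }
    if (is.null(found)) break
    solutions[[length(solutions) + 1L]] <- found
    pred <- predict_spots(found, current$geometry, current$beam, priors,
                          rlp_radius = params$rlp_radius)
    current <- remove_predicted(current, pred, params$removal_radius_px)
  }
  solutions
}

#' Index one image by clustering candidate rotation matrices
#'
#' Builds an orientation matrix for every candidate vector-pair assignment,
#' scores each by its number of neighbours within the angular neighbourhood
#' radius under the symmetry-aware metric, and selects maxima greedily,
#' discarding symmetry-duplicates and keeping only solutions that pass the
#' Ewald-wavelength acceptance test.
#'
#' @inheritParams network_index
#' @return List of accepted [orientation_solution()]s ranked by neighbour
#'   count.
#' @export
cluster_index <- function(image, params, priors) {
  pool <- .indexing_pool(image, params, priors)
  m <- length(pool$length)
  if (m < 2) return(list())
  keep <- seq_len(min(m, params$max_cluster_vectors))
  pool <- .subset_sv(pool, keep)
  cand <- candidate_pairs(pool, priors$theory, params$pair_angle_tol,
                          params$min_pair_angle)
  if (nrow(cand) == 0) return(list())
  # deterministic truncation: best angle agreement first
  cand <- cand[order(cand$angle_error_deg, cand$v1, cand$v2,
                     cand$t1, cand$t2), , drop = FALSE]
  cand <- cand[seq_len(min(nrow(cand), params$max_candidates)), , drop = FALSE]
  sols <- vector("list", nrow(cand))
  ok <- logical(nrow(cand))
  flat <- matrix(0, nrow(cand), 9L)
  for (k in seq_len(nrow(cand))) {
    s <- try(matrix_from_vector_pair(
      pool$delta[cand$v1[k], ], pool$delta[cand$v2[k], ],
      priors$theory$cart[cand$t1[k], ], priors$theory$cart[cand$t2[k], ],
      priors$B, source = list(method = "cluster", pair = c(cand$v1[k],
                                                           cand$v2[k]))),
      silent = TRUE)
    if (inherits(s, "try-error")) next
    sols[[k]] <- s
    flat[k, ] <- as.numeric(t(s$U))
    ok[k] <- TRUE
  }
  idx <- which(ok)
  if (length(idx) == 0) return(list())
  flat <- flat[idx, , drop = FALSE]
  sols <- sols[idx]
  thr_n <- angle_threshold_to_metric(params$neighbour_radius)
  # pairwise neighbour counts under the metric
  best_dot <- matrix(-Inf, length(idx), length(idx))
  for (O in priors$lattice_ops) {
    rot <- t(vapply(seq_len(length(idx)), function(k)
      as.numeric(t(matrix(flat[k, ], 3, byrow = TRUE) %*% t(O))),
      numeric(9)))
    best_dot <- pmax(best_dot, flat %*% t(rot))
  }
  d2 <- 6 - 2 * best_dot
  neigh <- as.integer(rowSums(d2 <= thr_n^2)) - 1L
  ord <- order(neigh, decreasing = TRUE)
  solutions <- list()
  tested <- 0L
  for (k in ord) {
    if (length(solutions) >= params$max_lattices) break
    if (tested >= params$max_acceptance_tests) break
    sol <- sols[[k]]
    if (.is_duplicate(sol, solutions, priors$lattice_ops,
                      params$duplicate_metric_threshold)) next
    tested <- tested + 1L
    stats <- solution_wavelengths(sol, image, priors, d_min = params$accept_d_min,
                                    assign_tol = params$accept_assign_tol)
    if (accept_solution(stats, params$sigma_t, params$min_peak)) {
      sol$stats <- stats
      sol$neighbour_count <- neigh[k]
      sol$accepted <- TRUE
      solutions[[length(solutions) + 1L]] <- sol
    }
  }
  solutions
}

#' Index one image with the configured method
#'
#' @inheritParams network_index
#' @return List of accepted [orientation_solution()]s.
#' @export
index_image <- function(image, params, priors) {
  switch(params$method,
         network = network_index(image, params, priors),
         cluster = cluster_index(image, params, priors))
}

#' Multi-cycle indexing with a parameter schedule
#'
#' Runs a list of parameter sets in sequence; each cycle attempts only the
#' images that previous cycles failed to index (the usual schedule tightens
#' the length tolerance while relaxing the network threshold, and may finish
#' with a cluster cycle).
#'
#' @param images List of [image_model()]s.
#' @param schedule List of [indexing_params()].
#' @param priors A [crystal_priors()].
#' @return List with `solutions` (per image), `indexed` (logical per image),
#'   `cycle_fraction` (cumulative indexed fraction after each cycle).
#' @export
multi_cycle <- function(images, schedule, priors) {
  stopifnot(length(schedule) >= 1)
  n <- length(images)
  solutions <- vector("list", n)
  indexed <- logical(n)
  cycle_fraction <- numeric(length(schedule))
  for (cy in seq_along(schedule)) {
    params <- schedule[[cy]]
    for (ii in which(!indexed)) {
      sols <- index_image(images[[ii]], params, priors)
      if (length(sols) > 0) {
        solutions[[ii]] <- sols
        indexed[ii] <- TRUE
      }
    }
    cycle_fraction[cy] <- mean(indexed)
  }
  list(solutions = solutions, indexed = indexed,
       cycle_fraction = cycle_fraction)
}
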