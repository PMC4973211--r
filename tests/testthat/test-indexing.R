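test_that("candidate pairs apply the one-degree angle agreement rule", {
  # two orthogonal observed vectors on the shortest I23 family; theory
  # carries families at many angles, so agreement at 1 degree keeps only
  # assignments with a matching mutual angle
  pri <- toy_priors()
  d1 <- sqrt(2) / 106.1
  sv <- manual_vectors(rbind(c(d1, 0, 0), c(0, d1, 0)),
                       i = c(1L, 2L), j = c(3L, 4L))
  mt <- match_to_theory(sv, pri$theory, tolerance_model(fixed_tol = 1e-5),
                        toy_beam())
  cp <- candidate_pairs(mt, pri$theory, pair_angle_tol = 1)
  expect_gt(nrow(cp), 0)
  # every returned assignment has theoretical angle within 1 degree of 90
  for (r in seq_len(nrow(cp))) {
    u <- pri$theory$cart[cp$t1[r], ]; v <- pri$theory$cart[cp$t2[r], ]
    ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_lt(abs(ang - 90), 1 + 1e-9)
  }
  # assignments at 60 degrees are excluded for orthogonal observations
  expect_false(any(abs(apply(cp, 1, function(r) {
    u <- pri$theory$cart[r["t1"], ]; v <- pri$theory$cart[r["t2"], ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }) - 60) < 5))
})

test_that("candidate pairs equal exhaustive enumeration on a small image", {
  pri <- toy_priors()
  sim <- toy_clean_sim()
  keep <- which(sim$truth$label == 1)[1:8]
  img <- image_model("small", sim$image$geometry, sim$image$beam,
                     sim$image$spots[keep, , drop = FALSE])
  sv <- build_spot_vectors(img, d_max = 0.08)
  mt <- match_to_theory(sv, pri$theory, tolerance_model(fixed_tol = 5e-4),
                        toy_beam())
  cp <- candidate_pairs(mt, pri$theory, pair_angle_tol = 1,
                        min_pair_angle = 10)
  # independent oracle: plain quadruple loop
  oracle <- list()
  m <- length(mt$length)
  if (m >= 2) for (a in 1:(m - 1)) for (b in (a + 1):m) {
    va <- mt$delta[a, ]; vb <- mt$delta[b, ]
    ang <- acos(sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))) * 180 / pi
    if (ang < 10 || ang > 170) next
    for (ta in mt$matches[[a]]) for (tb in mt$matches[[b]]) {
      u <- pri$theory$cart[ta, ]; v <- pri$theory$cart[tb, ]
      angt <- acos(max(-1, min(1, sum(u * v) /
                                 sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (abs(angt - ang) <= 1)
        oracle[[length(oracle) + 1L]] <- c(a, b, ta, tb)
    }
  }
  got <- apply(cp[, c("v1", "v2", "t1", "t2")], 1, paste, collapse = "-")
  want <- vapply(oracle, paste, character(1), collapse = "-")
  expect_setequal(got, want)
})

test_that("a network grows over a noise-free single lattice", {
  pri <- toy_priors()
  sim <- toy_clean_sim()
  params <- toy_params()
  pool <- stillindex:::.indexing_pool(sim$image, params, pri)
  net <- grow_network(1, pool, params, pri, nrow(sim$image$spots))
  expect_s3_class(net, "vector_network")
  expect_gte(net$size, params$network_threshold)
  expect_lte(similarity_metric(net$consensus$U, sim$truth$U[[1]],
                               pri$lattice_ops), 0.25)
  expect_equal(net$size, length(net$members))
})

test_that("pools below the network threshold report too-small", {
  pri <- toy_priors()
  sim <- toy_clean_sim()
  keep <- which(sim$truth$label == 1)[1:6]   # 15 vectors max
  img <- image_model("tiny", sim$image$geometry, sim$image$beam,
                     sim$image$spots[keep, , drop = FALSE])
  params <- toy_params()
  pool <- stillindex:::.indexing_pool(img, params, pri)
  expect_lt(length(pool$length), 20)
  expect_null(grow_network(1, pool, params, pri, nrow(img$spots)))
})

test_that("network indexing recovers single lattices and is deterministic", {
  pri <- toy_priors()
  params <- toy_params()
  spec <- toy_spec()
  for (i in 4:5) {
    sim <- simulate_image(spec, i, pri)
    sols <- network_index(sim$image, params, pri)
    expect_length(sols, 1)
    ev <- evaluate_solutions(sim$truth, sols, pri$lattice_ops)
    expect_equal(ev$n_matched, 1)
    expect_gte(sols[[1]]$network_size, params$network_threshold)
    # determinism: identical rerun
    sols2 <- network_index(sim$image, params, pri)
    expect_equal(sols[[1]]$U, sols2[[1]]$U)
  }
})

test_that("relaxing the common-spot requirement cannot shrink a network", {
  pri <- toy_priors()
  sim <- toy_clean_sim()
  pon <- toy_params(require_common_spot = TRUE)
  poff <- toy_params(require_common_spot = FALSE)
  pool <- stillindex:::.indexing_pool(sim$image, pon, pri)
  non <- grow_network(1, pool, pon, pri, nrow(sim$image$spots))
  noff <- grow_network(1, pool, poff, pri, nrow(sim$image$spots))
  expect_gte(noff$size, non$size)
})

test_that("max_lattices bounds the solution count and empty images fail cleanly", {
  pri <- toy_priors()
  sim <- simulate_image(toy_spec(n_lattices = 2, n_noise_spots = 0), 2, pri)
  params <- toy_params(max_lattices = 1, filter_lattices = "auto",
                       l_per_lattice = 150)
  sols <- network_index(sim$image, params, pri)
  expect_lte(length(sols), 1)
  # an image emptied of spots yields no solutions
  empty <- image_model("none", sim$image$geometry, sim$image$beam,
                       sim$image$spots[0, , drop = FALSE])
  expect_length(network_index(empty, params, pri), 0)
})

test_that("cluster indexing finds the lattice of a clean cubic image", {
  pri <- toy_priors()
  sim <- toy_clean_sim()
  params <- indexing_params(method = "cluster", d_max = 0.08)
  sols <- cluster_index(sim$image, params, pri)
  expect_gte(length(sols), 1)
  expect_lte(similarity_metric(sols[[1]]$U, sim$truth$U[[1]],
                               pri$lattice_ops), 0.25)
  # ranked by neighbour count
  if (length(sols) > 1) {
    nc <- vapply(sols, function(s) s$neighbour_count, numeric(1))
    expect_true(all(diff(nc) <= 0))
  }
})

test_that("pure-noise images produce no accepted solution", {
  pri <- toy_priors()
  g <- toy_geometry(); b <- toy_beam()
  set.seed(91)
  img <- image_model("noise", g, b,
                     data.frame(id = 1:120, fast = runif(120, 0, 1023),
                                slow = runif(120, 0, 1023)))
  expect_length(network_index(img, toy_params(), pri), 0)
  expect_length(cluster_index(img, indexing_params(method = "cluster",
                                                   d_max = 0.08), pri), 0)
})

test_that("multi-cycle schedules accumulate monotonically", {
  pri <- toy_priors()
  spec <- toy_spec()
  sims <- lapply(6:8, function(i) simulate_image(spec, i, pri))
  images <- lapply(sims, `[[`, "image")
  p1 <- toy_params()
  # one cycle equals plain indexing
  mc1 <- multi_cycle(images, list(p1), pri)
  plain <- lapply(images, network_index, params = p1, priors = pri)
  expect_equal(mc1$indexed, vapply(plain, function(s) length(s) > 0,
                                   logical(1)))
  # a schedule can only add indexed images
  schedule <- list(toy_params(network_threshold = 30),
                   toy_params(network_threshold = 20),
                   toy_params(tolerance = tolerance_model(fixed_tol = 3e-4),
                              network_threshold = 15))
  mc <- multi_cycle(images, schedule, pri)
  expect_true(all(diff(mc$cycle_fraction) >= 0))
  expect_equal(mc$cycle_fraction[3], mean(mc$indexed))
})

test_that("returned solution lists never contain symmetry duplicates", {
  pri <- toy_priors()
  sim <- simulate_image(toy_spec(n_lattices = 2, n_noise_spots = 10), 5, pri)
  params <- toy_params(max_lattices = 3, filter_lattices = "auto",
                       l_per_lattice = 150)
  sols <- network_index(sim$image, params, pri)
  if (length(sols) > 1)
    for (a in 1:(length(sols) - 1)) for (b in (a + 1):length(sols))
      expect_gte(similarity_metric(sols[[a]]$U, sols[[b]]$U,
                                   pri$lattice_ops), 0.25)
  expect_gte(length(sols), 1)
})
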