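test_that("Busing-Levy matrix reproduces reciprocal cells", {
  expect_equal(busing_levy_matrix(unit_cell(106.1)), diag(3) / 106.1,
               tolerance = 1e-12)
  expect_equal(busing_levy_matrix(unit_cell(38.0, 46.9, 84.5)),
               diag(1 / c(38.0, 46.9, 84.5)), tolerance = 1e-12)
  Bh <- busing_levy_matrix(unit_cell(92.9, 92.9, 130.4, gamma = 120))
  expect_equal(sqrt(sum((Bh %*% c(1, 0, 0))^2)), 2 / (92.9 * sqrt(3)),
               tolerance = 1e-9)
  # reciprocal distance formula holds for a skew cell
  cellt <- unit_cell(40, 50, 60, alpha = 80, beta = 95, gamma = 105)
  Bt <- busing_levy_matrix(cellt)
  hkl <- c(2, -3, 1)
  # oracle: d* from the metric tensor of the direct cell
  deg <- pi / 180
  G <- matrix(c(40^2, 40 * 50 * cos(105 * deg), 40 * 60 * cos(95 * deg),
                40 * 50 * cos(105 * deg), 50^2, 50 * 60 * cos(80 * deg),
                40 * 60 * cos(95 * deg), 50 * 60 * cos(80 * deg), 60^2),
              3, 3)
  dstar <- sqrt(as.numeric(t(hkl) %*% solve(G) %*% hkl))
  expect_equal(sqrt(sum((Bt %*% hkl)^2)), dstar, tolerance = 1e-9)
  expect_error(unit_cell(10, 10, 10, alpha = 1, beta = 1, gamma = 179))
})

test_that("centring rules forbid the right index classes", {
  expect_false(centring_allowed(c(1, 0, 0), "I"))
  expect_true(centring_allowed(c(1, 1, 0), "I"))
  expect_false(centring_allowed(c(1, 1, 0), "F"))
  expect_true(centring_allowed(c(1, 1, 1), "F"))
  expect_true(centring_allowed(c(2, 2, 2), "F"))
  expect_true(all(centring_allowed(matrix(c(1, 0, 0, 1, 2, 3), 2,
                                          byrow = TRUE), "P")))
  expect_true(centring_allowed(c(3, 1, 1), "A"))
  expect_false(centring_allowed(c(3, 1, 2), "A"))
  expect_true(centring_allowed(c(1, 3, 1), "B"))
  expect_true(centring_allowed(c(1, 1, 7), "C"))
  expect_true(centring_allowed(c(0, 1, 2), "R"))
  expect_false(centring_allowed(c(0, 1, 1), "R"))
  expect_error(centring_allowed(c(1, 1, 1), "Q"), "unknown centring")
})

test_that("theoretical vector enumeration matches a brute-force grid", {
  cell <- toy_cell()
  sg <- space_group_info("I23")
  d_max <- 0.03
  th <- enumerate_theoretical_vectors(cell, sg, d_max)
  # shortest allowed length is sqrt(2)/a; 1/a (i.e. (1,0,0)) is absent
  expect_equal(th$length[1], sqrt(2) / 106.1, tolerance = 1e-12)
  expect_false(any(abs(th$length - 1 / 106.1) < 1e-9))
  # independent brute force: triple loop with explicit parity rule
  lens <- c()
  hmax <- ceiling(d_max * 106.1)
  for (h in -hmax:hmax) for (k in -hmax:hmax) for (l in -hmax:hmax) {
    if (h == 0 && k == 0 && l == 0) next
    if ((h + k + l) %% 2 != 0) next
    d <- sqrt(h^2 + k^2 + l^2) / 106.1
    if (d <= d_max) lens <- c(lens, d)
  }
  expect_equal(sort(th$length), sort(lens), tolerance = 1e-12)
  # every dhkl has its negation in the table
  key <- paste(th$dhkl[, 1], th$dhkl[, 2], th$dhkl[, 3])
  neg <- paste(-th$dhkl[, 1], -th$dhkl[, 2], -th$dhkl[, 3])
  expect_true(all(neg %in% key))
})

test_that("enumeration edge cases behave", {
  sg <- space_group_info("F23")
  th <- enumerate_theoretical_vectors(unit_cell(437), sg, 0.006)
  expect_equal(th$length[1], sqrt(3) / 437, tolerance = 1e-12)
  empty <- enumerate_theoretical_vectors(unit_cell(106.1),
                                         space_group_info("I23"), 0.01)
  expect_equal(length(empty$length), 0)
  expect_error(enumerate_theoretical_vectors(unit_cell(437),
                                             sg, 0.5, cap = 1e4),
               "cap")
})

test_that("point-group rotations close and have the documented orders", {
  cases <- list(list("P212121", unit_cell(38, 46.9, 84.5), 4),
                list("I23", toy_cell(), 12),
                list("P6122", unit_cell(92.9, 92.9, 130.4, gamma = 120), 12))
  for (cs in cases) {
    sg <- space_group_info(cs[[1]])
    ops <- rotational_symmetry_ops(sg, cs[[2]])
    expect_length(ops, cs[[3]])
    expect_true(any(vapply(ops, function(o) max(abs(o - diag(3))) < 1e-12,
                           logical(1))))
    # orthogonal, det +1, closed under multiplication
    keyf <- function(m) paste(round(m, 9), collapse = ",")
    keys <- vapply(ops, keyf, character(1))
    for (o in ops) {
      expect_equal(o %*% t(o), diag(3), tolerance = 1e-9)
      expect_equal(det(o), 1, tolerance = 1e-9)
      for (p in ops[1:2])
        expect_true(keyf(o %*% p) %in% keys)
    }
  }
})

test_that("I23 operators generate six images of the (1,0,0) axis", {
  ops <- rotational_symmetry_ops(space_group_info("I23"), toy_cell())
  imgs <- unique(round(t(sapply(ops, function(o) o %*% c(1, 0, 0))), 9))
  expect_equal(nrow(imgs), 6)
})

test_that("lattice holohedry extends 23 to 432 but leaves 222 and 622 alone", {
  expect_length(rotational_symmetry_ops(space_group_info("I23"), toy_cell(),
                                        lattice = TRUE), 24)
  expect_length(rotational_symmetry_ops(space_group_info("P212121"),
                                        unit_cell(38, 46.9, 84.5),
                                        lattice = TRUE), 4)
  expect_length(rotational_symmetry_ops(
    space_group_info("P6122"), unit_cell(92.9, 92.9, 130.4, gamma = 120),
    lattice = TRUE), 12)
})

test_that("custom space groups accept explicit generators", {
  sg <- space_group_info(centring = "C",
                         rotations = list(diag(c(-1, -1, 1))))
  expect_equal(sg$centring, "C")
  expect_length(sg$rotations, 2)
  expect_error(space_group_info("X999"), "unsupported")
})

test_that("theoretical pattern collates lengths with multiplicities", {
  th <- enumerate_theoretical_vectors(toy_cell(), space_group_info("I23"),
                                      0.025)
  tp <- theoretical_pattern(th)
  expect_equal(tp$length[1:3],
               sqrt(c(2, 4, 6)) / 106.1, tolerance = 1e-9)
  # first family is the 12 permutations of (1,1,0) with signs
  expect_equal(tp$multiplicity[1], 12)
  expect_equal(sum(tp$multiplicity), length(th$length))
  empty <- enumerate_theoretical_vectors(toy_cell(),
                                         space_group_info("I23"), 0.012)
  expect_equal(nrow(theoretical_pattern(empty)), 0)
})
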