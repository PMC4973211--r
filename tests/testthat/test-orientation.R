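test_that("axis-angle rotations behave as a right-handed group", {
  expect_equal(rotation_about_axis(c(1, 1, 1), 0), diag(3))
  expect_equal(as.numeric(rotation_about_axis(c(0, 0, 1), pi / 2) %*%
                            c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  r1 <- rotation_about_axis(c(2, -1, 3), 0.4)
  r2 <- rotation_about_axis(c(2, -1, 3), 0.9)
  expect_equal(r1 %*% r2, rotation_about_axis(c(2, -1, 3), 1.3),
               tolerance = 1e-12)
  expect_error(rotation_about_axis(c(0, 0, 0), 1), "zero")
})

test_that("orientation from a fabricated vector pair recovers the rotation", {
  B <- busing_levy_matrix(toy_cell())
  it <- c(0.02, 0.003, -0.01); jt <- c(-0.004, 0.015, 0.008)
  # identity case
  sol <- matrix_from_vector_pair(it, jt, it, jt, B)
  expect_equal(sol$U, diag(3), tolerance = 1e-9)
  expect_equal(sol$R, sol$U %*% B)
  set.seed(31)
  for (k in 1:25) {
    G <- random_orientation()
    a <- rnorm(3, sd = 0.02); b <- rnorm(3, sd = 0.02)
    # skip accidentally degenerate draws
    cosab <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    if (abs(cosab) > 0.99) next
    sol <- matrix_from_vector_pair(as.numeric(G %*% a), as.numeric(G %*% b),
                                   a, b, B)
    # misorientation angle <= 1e-6 rad: metric = 2 sqrt(2) sin(angle/2)
    expect_lt(similarity_metric(sol$U, G), 2 * sqrt(2) * sin(5e-7))
    expect_equal(sol$U %*% t(sol$U), diag(3), tolerance = 1e-9)
    expect_equal(det(sol$U), 1, tolerance = 1e-9)
  }
})

test_that("degenerate and antiparallel pair geometries are handled", {
  B <- busing_levy_matrix(toy_cell())
  i <- c(0.02, 0, 0); j <- c(0.04, 1e-9, 0)
  expect_error(matrix_from_vector_pair(i, j, i, j, B), "degenerate")
  # antiparallel first vector: still an exact alignment
  it <- c(0.02, 0, 0); jt <- c(0, 0.015, 0)
  sol <- matrix_from_vector_pair(-it, -jt, it, jt, B)
  expect_equal(as.numeric(sol$U %*% it) / 0.02, c(-1, 0, 0),
               tolerance = 1e-9)
})

test_that("similarity metric matches its angular calibration", {
  set.seed(33)
  ax <- rnorm(3)
  expect_equal(similarity_metric(diag(3), diag(3)), 0)
  m10 <- similarity_metric(diag(3), rotation_about_axis(ax, 10 * pi / 180))
  m12 <- similarity_metric(diag(3), rotation_about_axis(ax, 12 * pi / 180))
  expect_lte(m10, 0.25)
  expect_gt(m12, 0.25)
  # symmetry-equivalent settings have metric zero
  pri <- toy_priors()
  P <- random_orientation()
  for (O in pri$ops[c(2, 7, 12)])
    expect_equal(similarity_metric(P %*% O, P, pri$ops), 0,
                 tolerance = 1e-12)
  # symmetric in its arguments for a group-closed operator set
  Q <- random_orientation()
  expect_equal(similarity_metric(P, Q, pri$ops),
               similarity_metric(Q, P, pri$ops), tolerance = 1e-12)
  # monotone in the rotation angle on 0..60 degrees
  angs <- seq(0, 60, by = 5)
  vals <- sapply(angs, function(a)
    similarity_metric(diag(3), rotation_about_axis(ax, a * pi / 180)))
  expect_true(all(diff(vals) > 0))
})

test_that("angular thresholds convert consistently to metric units", {
  expect_equal(angle_threshold_to_metric(0), 0)
  expect_lte(angle_threshold_to_metric(10), 0.25)
  expect_lt(angle_threshold_to_metric(8), angle_threshold_to_metric(10))
  # agreement with the metric of an actual rotation
  expect_equal(angle_threshold_to_metric(23),
               similarity_metric(diag(3),
                                 rotation_about_axis(c(1, 2, 3),
                                                     23 * pi / 180)),
               tolerance = 1e-12)
})

test_that("polar projection maps orientations to sphere angles", {
  p0 <- polar_projection(diag(3))
  expect_equal(as.numeric(p0), c(90, 0))
  p1 <- polar_projection(rotation_about_axis(c(0, 0, 1), pi / 2))
  expect_equal(as.numeric(p1), c(90, 90))
  # symmetry images of a random orientation land on 6 distinct points
  set.seed(34)
  U <- random_orientation()
  pri <- toy_priors()
  pts <- t(sapply(pri$ops, function(O) polar_projection(U %*% O)))
  expect_equal(nrow(unique(round(pts, 6))), 6)
})

test_that("misorientation of recovered orientations grows with jitter", {
  B <- busing_levy_matrix(toy_cell())
  set.seed(35)
  err_at <- function(sigma) {
    e <- replicate(40, {
      G <- random_orientation()
      a <- c(0.03, 0.004, -0.012); b <- c(-0.006, 0.025, 0.01)
      oa <- as.numeric(G %*% a) + rnorm(3, sd = sigma)
      ob <- as.numeric(G %*% b) + rnorm(3, sd = sigma)
      similarity_metric(matrix_from_vector_pair(oa, ob, a, b, B)$U, G)
    })
    mean(e)
  }
  e1 <- err_at(1e-5); e2 <- err_at(1e-4)
  expect_lt(e1, e2)
  # roughly linear scaling at small noise: a decade of noise gives an
  # order-of-magnitude larger misorientation (within a loose factor)
  expect_gt(e2 / e1, 3)
})
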