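test_that("fixture trees give exact Sholl intersection vectors", {
  rad <- sholl(simulate_morphology("radial", length_um = 23))
  expect_identical(rad$radius_um, seq(5, 25, by = 5))
  expect_identical(rad$intersections, c(1L, 1L, 1L, 1L, 0L))

  yb <- sholl(simulate_morphology("y_branch", length_um = 30, branch_at_um = 12))
  expect_identical(yb$intersections, c(1L, 1L, 2L, 2L, 2L, 2L))

  soma <- sholl(simulate_morphology("soma_only"))
  expect_true(all(soma$intersections == 0L))
})

test_that("Sholl counts are invariant under rigid rotation about the soma", {
  set.seed(17)
  tree <- random_tree(40)
  base <- sholl(tree)$intersections
  # random rotation matrix via QR of a Gaussian matrix
  qr_rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_rot) < 0) qr_rot[, 1] <- -qr_rot[, 1]
  rot <- as.matrix(tree[, c("x", "y", "z")]) %*% t(qr_rot)
  tree2 <- tree
  tree2$x <- rot[, 1]
  tree2$y <- rot[, 2]
  tree2$z <- rot[, 3]
  expect_identical(sholl(tree2)$intersections, base)
  expect_equal(
    total_neurite_length(tree2), total_neurite_length(tree),
    tolerance = 1e-9
  )
})

test_that("Sholl agrees with the exhaustive segment-shell oracle", {
  set.seed(18)
  for (i in 1:100) {
    tree <- random_tree(sample(2:25, 1))
    prof <- sholl(tree)
    expect_identical(
      prof$intersections,
      oracle_sholl_counts(tree, prof$radius_um)
    )
  }
})

test_that("primary neurite count appears at the innermost shell", {
  yb <- simulate_morphology("y_branch", length_um = 30, branch_at_um = 12)
  tiny <- sholl(yb, step_um = 0.25)
  expect_identical(tiny$intersections[1], 1L) # one soma-incident neurite
})

test_that("total neurite length is exact and additive", {
  two <- tibble::tibble(
    id = 1:2, type = c(1L, 3L), x = c(0, 3), y = 0, z = 0,
    radius = 1, parent = c(-1L, 1L)
  )
  expect_equal(total_neurite_length(two), 3)
  expect_equal(total_neurite_length(simulate_morphology("soma_only")), 0)

  yb <- simulate_morphology("y_branch", length_um = 30, branch_at_um = 12)
  segs <- yb[yb$parent != -1, ]
  pidx <- match(segs$parent, yb$id)
  hand <- sum(sqrt(
    (segs$x - yb$x[pidx])^2 + (segs$y - yb$y[pidx])^2 + (segs$z - yb$z[pidx])^2
  ))
  expect_equal(total_neurite_length(yb), hand, tolerance = 1e-12)
})

test_that("SWC files round-trip and invalid trees are rejected", {
  tree <- simulate_morphology("y_branch", length_um = 18, branch_at_um = 6)
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(tree, path)
  back <- read_swc(path)
  expect_equal(as.data.frame(back), as.data.frame(tree), tolerance = 1e-9)

  orphan <- tree
  orphan$parent[5] <- 999L
  expect_error(validate_neuron_tree(orphan), "missing parent")
  tworoot <- tree
  tworoot$parent[3] <- -1L
  expect_error(validate_neuron_tree(tworoot), "one root")
  cyc <- tibble::tibble(
    id = 1:3, type = 3L, x = 0, y = 0, z = 0, radius = 1,
    parent = c(-1L, 3L, 2L)
  )
  expect_error(validate_neuron_tree(cyc), "Cycle")
})

test_that("soma metrics match analytic circle, ellipse, and triangle", {
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  circ <- soma_metrics(tibble::tibble(x_um = 10 * cos(th), y_um = 10 * sin(th)))
  expect_equal(circ$area_um2, pi * 100, tolerance = 0.005 * pi * 100)
  expect_equal(circ$major_axis_um, 20, tolerance = 0.1)
  expect_equal(circ$minor_axis_um, 20, tolerance = 0.1)
  expect_equal(circ$aspect_ratio, 1, tolerance = 0.005)

  ell <- soma_metrics(tibble::tibble(x_um = 10 * cos(th), y_um = 5 * sin(th)))
  expect_equal(ell$area_um2, pi * 50, tolerance = 0.005 * pi * 50)
  expect_equal(ell$major_axis_um, 20, tolerance = 0.1)
  expect_equal(ell$minor_axis_um, 10, tolerance = 0.1)
  expect_equal(ell$aspect_ratio, 2, tolerance = 0.01)

  tri <- soma_metrics(tibble::tibble(x_um = c(0, 4, 0), y_um = c(0, 0, 3)))
  expect_equal(tri$area_um2, 6, tolerance = 1e-12)
  expect_gte(tri$aspect_ratio, 1)
})

test_that("metrics are orientation- and direction-independent", {
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  x <- 8 * cos(th)
  y <- 3 * sin(th)
  ccw <- soma_metrics(tibble::tibble(x_um = x, y_um = y))
  cw <- soma_metrics(tibble::tibble(x_um = rev(x), y_um = rev(y)))
  expect_equal(cw, ccw, tolerance = 1e-9)
  phi <- 0.7
  rot <- soma_metrics(tibble::tibble(
    x_um = cos(phi) * x - sin(phi) * y,
    y_um = sin(phi) * x + cos(phi) * y
  ))
  expect_equal(rot$area_um2, ccw$area_um2, tolerance = 1e-9)
  expect_equal(rot$major_axis_um, ccw$major_axis_um, tolerance = 1e-9)
})

test_that("self-intersecting contours are rejected", {
  bow <- tibble::tibble(x_um = c(0, 2, 0, 2), y_um = c(0, 2, 2, 0))
  expect_error(soma_metrics(bow), "self-intersecting")
})
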