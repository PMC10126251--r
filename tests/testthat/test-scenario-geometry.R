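# Vegetation patch layouts, grain mixtures and grid generation.

test_that("hexagonal arrays: degenerate, first shell, and ring growth", {
  p1 <- build_hex_array(c(0, 0), spacing = 1, n_roots = 1, diameter = 0.3)
  expect_equal(p1$patch_diameter, 0.3)
  expect_equal(p1$phi, 1)

  p7 <- build_hex_array(c(2, 3), spacing = 0.6, n_roots = 7, diameter = 0.2)
  d <- as.matrix(dist(p7$centers))
  nn <- apply(d + diag(Inf, 7), 1, min)
  expect_true(all(abs(nn - 0.6) < 1e-9))
  # center root has six neighbors at exactly one spacing
  expect_equal(as.numeric(sort(d[1, -1])), rep(0.6, 6), tolerance = 1e-12)
})

test_that("interior lattice points have six nearest neighbors at the spacing", {
  p <- build_hex_array(c(0, 0), spacing = 0.5, n_roots = 61, diameter = 0.1)
  d <- as.matrix(dist(p$centers))
  ctr <- sqrt(rowSums(p$centers^2))
  interior <- which(ctr < max(ctr) - 0.55)  # at least one ring from the edge
  for (i in interior) {
    nb <- sort(d[i, -i])[1:6]
    expect_true(all(abs(nb - 0.5) < 1e-9))
  }
})

test_that("overlapping roots are rejected", {
  expect_error(build_hex_array(c(0, 0), spacing = 0.15, n_roots = 7,
                               diameter = 0.2), "overlap")
})

test_that("patch density matches a Monte-Carlo point-in-circle oracle", {
  p <- build_hex_array(c(0, 0), spacing = 0.55, n_roots = 37, diameter = 0.2)
  # oracle: count patch-circle area on a fine grid
  gx <- seq(-3, 3, by = 0.01)
  inside <- outer(gx^2, gx^2, `+`) <= (p$patch_diameter / 2)^2
  area_mc <- sum(inside) * 0.01^2
  expect_equal(p$density, p$n_roots / area_mc, tolerance = 0.01)
  # all roots lie within the patch circle
  r <- sqrt(rowSums(sweep(p$centers, 2, p$center)^2)) + p$diameter / 2
  expect_true(all(r <= p$patch_diameter / 2 + 1e-9))
})

test_that("solid volume fraction follows N (d/D)^2", {
  expect_equal(solid_volume_fraction(1, 2, 2), 1)
  expect_equal(solid_volume_fraction(37, 0.2, 4), 37 * 0.05^2)
  expect_equal(solid_volume_fraction(9, 0.1, 1), 0.09)
  expect_error(solid_volume_fraction(3, 2, 1), "geometry")
})

test_that("phi is invariant under rigid rotation and translation", {
  p <- build_hex_array(c(0, 0), spacing = 0.6, n_roots = 19, diameter = 0.2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- root_patch(p$centers %*% R + matrix(c(5, -2), p$n_roots, 2,
                                               byrow = TRUE),
                      p$diameter, p$spacing)
  expect_equal(moved$phi, p$phi, tolerance = 1e-12)
  expect_equal(moved$patch_diameter, p$patch_diameter, tolerance = 1e-9)
})

test_that("grain mixture hits the target D50 and mean-diameter identity", {
  m <- build_grain_mixture(0.001e-3, 34e-3, 3.2e-3, n_classes = 8)
  expect_equal(sum(m$fractions), 1, tolerance = 1e-12)
  expect_true(all(diff(m$class_diameters) > 0))
  # interpolated cumulative curve crosses 0.5 at d50
  cum <- c(0, cumsum(m$fractions))
  at50 <- approx(log(m$edges), cum, xout = log(3.2e-3))$y
  expect_equal(at50, 0.5, tolerance = 1e-6)
  # d_m equals the direct summation oracle
  expect_equal(m$mean_diameter, sum(m$fractions * m$class_diameters))
  expect_true(all(m$settling_velocities > 0))
})

test_that("single-class mixture degenerates to the D50 grain", {
  m <- build_grain_mixture(1e-3, 10e-3, 3.2e-3, n_classes = 1)
  expect_equal(m$class_diameters, 3.2e-3)
  expect_equal(m$fractions, 1)
})

test_that("cumulative curve is monotone; halving classes barely moves d_m", {
  m16 <- build_grain_mixture(0.001e-3, 34e-3, 3.2e-3, n_classes = 16)
  m8 <- build_grain_mixture(0.001e-3, 34e-3, 3.2e-3, n_classes = 8)
  expect_true(all(diff(c(0, cumsum(m16$fractions))) >= 0))
  expect_lt(abs(m8$mean_diameter - m16$mean_diameter) / m16$mean_diameter,
            0.05)
})

test_that("infeasible d50 is a parameter error", {
  expect_error(build_grain_mixture(1e-3, 2e-3, 5e-3, 4), "parameter")
})

test_that("grid: uniform without patches, graded and masked with one root", {
  g0 <- tiny_grid(10, 4, 0.5)
  expect_true(all(abs(g0$dx - g0$dx[1]) < 1e-9))
  expect_equal(sum(g0$mask), 0)
  expect_equal(sum(cell_areas(g0)), 10 * 4, tolerance = 1e-9)

  p <- root_patch(matrix(c(5, 3), 1), 0.2)
  g <- build_grid(c(10, 6), p, near_cell_area = 0.001, far_cell_area = 0.25)
  masked_area <- sum(cell_areas(g)[g$mask == 1L])
  expect_lt(abs(masked_area - pi * 0.1^2) / (pi * 0.1^2), 0.20)
  # grading: adjacent cell size ratio bounded
  expect_true(all(g$dx[-1] / g$dx[-g$nx] <= 1.3 + 1e-9))
  expect_true(all(g$dx[-g$nx] / g$dx[-1] <= 1.3 + 1e-9))
  expect_true(all(g$dy[-1] / g$dy[-g$ny] <= 1.3 + 1e-9))
  # unmasked area complements the root footprint up to discretization
  expect_equal(sum(cell_areas(g)[g$mask == 0L]),
               60 - pi * 0.1^2, tolerance = 0.01)
})

test_that("obstacle mask area converges with resolution", {
  p <- root_patch(matrix(c(5, 3), 1), 0.4)
  err <- vapply(c(0.0064, 0.0016, 4e-4, 1e-4), function(a) {
    g <- build_grid(c(10, 6), p, near_cell_area = a, far_cell_area = 0.25)
    abs(sum(cell_areas(g)[g$mask == 1L]) - pi * 0.2^2)
  }, numeric(1))
  # oscillatory first-order convergence: every refined level beats the
  # coarsest, and refined errors are within 2% of the footprint
  expect_true(all(err[-1] < err[1]))
  expect_true(all(err[-1] / (pi * 0.2^2) < 0.02))
})

test_that("a root thinner than two near-zone cells is a resolution error", {
  p <- root_patch(matrix(c(5, 3), 1), 0.05)
  expect_error(build_grid(c(10, 6), p, 0.0016, 0.25), "resolution")
})

test_that("boundary conditions validate their ranges", {
  bc <- boundary_conditions(Q = 40, stage = 1)
  expect_equal(bc$Q, 40)
  expect_error(boundary_conditions(Q = -1), "Q")
  expect_error(boundary_conditions(stage = 0), "stage")
})

test_that("scenario presets produce the documented layouts", {
  s1 <- scenario_preset("tree_without_knees")
  expect_equal(s1$patches[[1]]$n_roots, 1)
  expect_equal(s1$patches[[1]]$diameter, 0.4)
  expect_equal(s1$Q, 40)
  expect_equal(s1$flood_duration, 25000)
  expect_equal(s1$spin_up, 500)

  s2 <- scenario_preset("tree_with_knees")
  expect_equal(s2$patches[[1]]$diameter[1], 0.4)   # trunk
  expect_true(all(s2$patches[[1]]$diameter[-1] == 0.2))

  s3 <- scenario_preset("two_patch_gap", list(gap = 0))
  expect_length(s3$patches, 2)
  expect_equal(s3$patches[[1]]$n_roots, 37)
  expect_true(all(s3$patches[[1]]$diameter == 0.2))
  # aligned edges: same streamwise extent, cross-stream edge gap = 0
  r1 <- range(s3$patches[[1]]$centers[, 1])
  r2 <- range(s3$patches[[2]]$centers[, 1])
  expect_equal(r1, r2, tolerance = 1e-9)
  sep <- s3$patches[[2]]$center[2] - s3$patches[[1]]$center[2]
  expect_equal(sep, (s3$patches[[1]]$patch_diameter +
                       s3$patches[[2]]$patch_diameter) / 2, tolerance = 1e-9)

  s4 <- scenario_preset("trunk_knee_mixture", list(trunk_d = 0.8))
  dvec <- s4$patches[[1]]$diameter
  expect_true(any(dvec == 0.8) && any(dvec == 0.1))

  expect_error(scenario_preset("no_such_preset"))
})

test_that("scenario configs round-trip through structured text", {
  sc <- test_scenario()
  f <- tempfile(fileext = ".json")
  write_scenario_config(sc, f)
  sc2 <- read_scenario_config(f)
  expect_equal(sc2$patches[[1]]$centers, sc$patches[[1]]$centers)
  expect_equal(sc2$patches[[1]]$diameter, sc$patches[[1]]$diameter)
  expect_equal(sc2$Q, sc$Q)
  expect_equal(sc2$thresholds, sc$thresholds)
})
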