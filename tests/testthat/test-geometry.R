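test_that("sphere overlap uses the strict-inequality (touching allowed) convention", {
  expect_false(spheres_overlap(c(0, 0, 0), 1, c(3, 0, 0), 1))
  expect_true(spheres_overlap(c(0, 0, 0), 1, c(1.9, 0, 0), 1))
  expect_false(spheres_overlap(c(0, 0, 0), 1, c(2, 0, 0), 1))
})

test_that("aqueous-region predicate handles the obvious cases", {
  g <- tiny_geometry()
  # open bulk far from the membrane
  expect_true(in_aqueous_region(c(0, 0, 15), 1, g))
  # inside the toroid body
  expect_false(in_aqueous_region(c(8, 0, 2), 0.5, g))
  # on the axis inside the SF with clearance
  expect_true(in_aqueous_region(c(0, 0, 0), g$sf_radius - 0.5, g))
  # sticking out of the outer cell wall
  expect_false(in_aqueous_region(c(11.5, 0, 15), 1, g))
  expect_error(in_aqueous_region(c(NA, 0, 0), 1, g), "non-finite")
})

test_that("aqueous-region predicate agrees with brute-force surface distances", {
  g <- tiny_geometry()
  surf <- oracle_surface_points(g)
  set.seed(101)
  n_checked <- 0
  for (i in 1:1000) {
    p <- c(runif(1, -11, 11), runif(1, -11, 11), runif(1, -19, 19))
    radius <- runif(1, 0.2, 2.5)
    r <- sqrt(p[1]^2 + p[2]^2)
    if (r > 11.9 || abs(p[3]) > 19.5) next
    inside_solid <- abs(p[3]) <= g$sf_half_length + g$arc_radius &&
      r >= oracle_wall_radius(g, p[3])
    d_surf <- if (inside_solid) 0 else
      min(sqrt(colSums((t(surf) - p)^2)))
    ok_wall <- (r + radius <= g$cell_radius) &&
      (abs(p[3]) + radius <= g$cell_half_length)
    expected <- ok_wall && d_surf >= radius
    # skip probes closer to the decision boundary than the surface sampling
    if (abs(d_surf - radius) < 0.05 ||
        abs(r + radius - g$cell_radius) < 0.05 ||
        abs(abs(p[3]) + radius - g$cell_half_length) < 0.05) next
    n_checked <- n_checked + 1
    expect_identical(in_aqueous_region(p, radius, g), expected)
  }
  expect_gt(n_checked, 500)
})

test_that("predicates are pure", {
  g <- tiny_geometry()
  p <- c(0.3, -0.2, 1)
  expect_identical(in_aqueous_region(p, 1, g), in_aqueous_region(p, 1, g))
})

test_that("SF bottleneck diameter matches the single-ring closed form", {
  g <- csc_geometry(12, 20, 6.5, 4, 4)
  ring <- pore_wall_atoms("r", cbind(c(5, 0, -5, 0), c(0, 5, 0, -5), 0),
                          1.4, -0.1, 1)
  expect_equal(sf_min_accessible_diameter(g, ring), 2 * (5 - 1.4),
               tolerance = 1e-8)
})

test_that("SF bottleneck is governed by the narrowest ring and shrinks with atom radii", {
  g <- csc_geometry(12, 20, 6.5, 4, 4)
  wide <- cbind(c(5.5, 0, -5.5, 0), c(0, 5.5, 0, -5.5), 2)
  narrow <- cbind(c(4.5, 0, -4.5, 0), c(0, 4.5, 0, -4.5), -2)
  atoms <- pore_wall_atoms("r", rbind(wide, narrow), 1.4, -0.1, 1)
  expect_equal(sf_min_accessible_diameter(g, atoms), 2 * (4.5 - 1.4),
               tolerance = 1e-8)
  for (rad in c(0.8, 1.2, 1.6)) {
    a1 <- pore_wall_atoms("r", rbind(wide, narrow), rad, -0.1, 1)
    a2 <- pore_wall_atoms("r", rbind(wide, narrow), rad + 0.2, -0.1, 1)
    expect_gt(sf_min_accessible_diameter(g, a1),
              sf_min_accessible_diameter(g, a2))
  }
})

test_that("SF bottleneck agrees with an independent sphere-growing grid search", {
  g <- csc_geometry(12, 20, 5.8, 5, 5)
  set.seed(7)
  # two staggered rings of unequal radial distance plus a jittered atom
  mk <- function(rho, z, n, jitter = 0) {
    a <- 2 * pi * seq_len(n) / n + jitter
    cbind(rho * cos(a), rho * sin(a), z)
  }
  base <- rbind(mk(4.2, 1.2, 4), mk(3.9, -1.8, 4, 0.4),
                c(3.8, 0.4, -0.2))
  atoms <- pore_wall_atoms("a", base, 1.4, -0.1, 1)
  got <- sf_min_accessible_diameter(g, atoms)
  # oracle: explicit scan over axial positions and diameters at 0.01 A
  zg <- seq(-g$sf_half_length, g$sf_half_length, by = 0.01)
  clear <- sapply(zg, function(z)
    min(min(sqrt(base[, 1]^2 + base[, 2]^2 + (z - base[, 3])^2) - 1.4),
        g$sf_radius))
  expect_equal(got, 2 * min(clear), tolerance = 1e-6)
})

test_that("fits_in_sf follows the bottleneck and tolerates touching", {
  g <- csc_geometry(12, 20, 6.5, 4, 4)
  ring <- pore_wall_atoms("r", cbind(c(4.2, 0, -4.2, 0), c(0, 4.2, 0, -4.2),
                                     0), 1.4, -1, 1)
  sf_min <- sf_min_accessible_diameter(g, ring)  # 5.6
  expect_true(fits_in_sf(0, g, ring, sf_min = sf_min))
  expect_true(fits_in_sf(5.44, g, ring, sf_min = sf_min))   # Na at x = 4
  expect_true(fits_in_sf(sf_min, g, ring, sf_min = sf_min))
  expect_false(fits_in_sf(6.21, g, ring, sf_min = sf_min))  # K at x = 4
  expect_false(fits_in_sf(2 * g$sf_radius + 0.1, g, ring))
})

test_that("fully occluded pores report zero with a warning", {
  g <- csc_geometry(12, 20, 5, 4, 4)
  blocker <- pore_wall_atoms("b", matrix(c(0.5, 0, 0), 1, 3), 2, -1, 1)
  expect_warning(d <- sf_min_accessible_diameter(g, blocker), "occlude")
  expect_identical(d, 0)
})

test_that("geometry constructor enforces the invariants", {
  expect_error(csc_geometry(5, 20, 6, 4, 4), "sf_radius")
  expect_error(csc_geometry(12, 7, 5, 4, 4), "membrane")
  expect_error(csc_geometry(12, 20, -1, 4, 4), "positive")
})
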