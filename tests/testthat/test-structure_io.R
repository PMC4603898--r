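test_that("B-factor conversion follows <u^2> = B / (8 pi^2)", {
  expect_equal(bfactor_to_spring(8 * pi^2), 1)
  expect_equal(bfactor_to_spring(20), 2 * bfactor_to_spring(40))
  expect_equal(spring_to_bfactor(bfactor_to_spring(17.3)), 17.3)
  expect_error(bfactor_to_spring(-1), "positive")
  expect_error(bfactor_to_spring(0), "positive")
})

test_that("tethered wall atoms reproduce their input B-factors by equipartition", {
  # two isolated uncharged atoms on the axis: no mutual contacts, and the
  # boundary cylinder is wide enough that the harmonic wells are untruncated
  B_in <- c(15, 30)
  wall <- pore_wall_atoms(c("a1", "a2"), rbind(c(0, 0, -3), c(0, 0, 3)),
                          1.4, 0, bfactor_to_spring(B_in))
  g <- csc_geometry(12, 20, 5, 4.5, 4)
  sys <- csc_system(g, ideal_types(1e-6), wall_atoms = wall)
  wt <- c(displace = 1, insert = 0, delete = 0, swap = 0)
  # burn in, then measure <|r - r_base|^2> on frames 300 steps apart
  state <- csc_run(sys, 4000, seed = 40, sample_every = 1000,
                   step_size = 0.9, weights = wt)$final_state
  u2 <- matrix(0, 0, 2)
  for (rep in 1:400) {
    run2 <- csc_run(sys, 300, seed = 41 + rep, init = state,
                    sample_every = 300, step_size = 0.9, weights = wt)
    state <- run2$final_state
    d <- state$wall_pos - cbind(wall$x, wall$y, wall$z)
    u2 <- rbind(u2, rowSums(d^2))
  }
  # <u^2> = 3/k per atom; implied B compared at 3 SE
  for (a in 1:2) {
    B_est <- 8 * pi^2 * mean(u2[, a]) / 3
    B_se <- 8 * pi^2 * (stats::sd(u2[, a]) / sqrt(nrow(u2))) / 3
    expect_lt(abs(B_est - B_in[a]), 3 * B_se)
  }
})

test_that("PDB ingestion resolves selectors, roles, charges and recentring", {
  # synthetic fixture: one subunit = 2 carbonyl O + a 2-oxygen carboxylate,
  # displaced from the origin to exercise recentring
  pdb <- tempfile(fileext = ".pdb")
  xyz <- rbind(c(13.0, 20.0, 31.0),    # carbonyl O, resno 1
               c(13.0, 20.0, 34.0),    # carbonyl O, resno 2
               c(12.5, 21.5, 36.0),    # carboxylate OE1 (nearer the axis)
               c(14.5, 22.5, 36.2))    # carboxylate OE2 (nearer the wall)
  bio3d::write.pdb(file = pdb, xyz = as.vector(t(xyz)),
                   resno = c(1, 2, 3, 3), resid = c("GLY", "GLY", "GLU",
                                                    "GLU"),
                   chain = rep("A", 4), elety = c("O", "O", "OE1", "OE2"),
                   b = c(20, 25, 30, 30))
  sel <- list(list(chain = "A", resno = 1, elety = "O", role = "carbonyl_O"),
              list(chain = "A", resno = 2, elety = "O", role = "carbonyl_O"),
              list(chain = "A", resno = 3, elety = c("OE1", "OE2"),
                   role = "carboxylate_O"))
  atoms <- read_sf_atoms(pdb, sel)
  expect_identical(nrow(atoms), 3L)                       # pair reduced to 1
  expect_equal(sort(unique(atoms$charge)), c(-1.0, -0.1))
  expect_equal(sum(atoms$charge == -1), 1)
  # recentring: the centroid of the selected records maps to the origin
  ctr <- colMeans(xyz)
  expect_equal(atoms$x[1:2], xyz[1:2, 1] - ctr[1], tolerance = 1e-3)
  expect_equal(atoms$z[1:2], xyz[1:2, 3] - ctr[3], tolerance = 1e-3)
  # kept carboxylate oxygen is the one farther from the pore axis (OE2)
  kept <- atoms[atoms$charge == -1, ]
  expect_equal(kept$z, xyz[4, 3] - ctr[3], tolerance = 1e-3)
  # spring constants from the B-factors
  expect_equal(atoms$k[1], bfactor_to_spring(20), tolerance = 1e-6)
  # determinism
  expect_identical(read_sf_atoms(pdb, sel), atoms)
  # unresolved selector errors out with the offender
  expect_error(read_sf_atoms(pdb, list(list(chain = "B", resno = 1,
                                            elety = "O",
                                            role = "carbonyl_O"))),
               "resolved to 0")
})

test_that("four-fold symmetry replication produces exact rotational copies", {
  pdb <- tempfile(fileext = ".pdb")
  xyz <- rbind(c(3.5, 0.5, 1.0), c(2.8, -1.2, -1.0))
  bio3d::write.pdb(file = pdb, xyz = as.vector(t(xyz)),
                   resno = 1:2, resid = c("GLY", "VAL"), chain = "A",
                   elety = c("O", "O"), b = c(20, 25))
  sel <- list(list(chain = "A", resno = 1, elety = "O",
                   role = "carbonyl_O"),
              list(chain = "A", resno = 2, elety = "O",
                   role = "carbonyl_O"))
  atoms <- read_sf_atoms(pdb, sel, symmetry = 4)
  expect_identical(nrow(atoms), 8L)
  # replicas of each source atom: same radius and z, angles pi/2 apart
  for (i in 1:2) {
    rep_i <- atoms[seq(i, 8, by = 2), ]
    r <- sqrt(rep_i$x^2 + rep_i$y^2)
    expect_equal(max(r) - min(r), 0, tolerance = 1e-9)
    expect_equal(rep_i$z, rep(rep_i$z[1], 4), tolerance = 1e-9)
    angles <- sort(atan2(rep_i$y, rep_i$x) %% (2 * pi))
    expect_equal(diff(angles), rep(pi / 2, 3), tolerance = 1e-6)
    expect_equal(rep_i$k, rep(rep_i$k[1], 4), tolerance = 1e-9)
  }
})

test_that("the round trip through the fixture writer preserves the wall atoms", {
  toy <- build_toy_channel("neutral-pore")
  pdb <- tempfile(fileext = ".pdb")
  write_toy_pdb(toy$wall_atoms, pdb)
  sel <- lapply(seq_len(nrow(toy$wall_atoms)), function(i)
    list(chain = "A", resno = i, elety = "O", role = "carbonyl_O"))
  back <- read_sf_atoms(pdb, sel)
  # base positions already centred, so they survive (to PDB precision)
  expect_equal(back$x, toy$wall_atoms$x, tolerance = 2e-3)
  expect_equal(back$z, toy$wall_atoms$z, tolerance = 2e-3)
  expect_equal(back$k, toy$wall_atoms$k, tolerance = 1e-2)
})

test_that("toy presets satisfy the generator contracts", {
  charged <- build_toy_channel("charged-pore")
  expect_equal(sum(charged$wall_atoms$charge[charged$wall_atoms$charge == -1]),
               -4)
  expect_equal(sum(charged$wall_atoms$charge), -4.8)
  tab <- default_species_table()
  wide <- build_toy_channel("wide-pore")
  for (sp in tab)
    expect_identical(select_states(sp, wide$sf_min_diameter)$n_max, 6L)
  for (preset in c("neutral-pore", "charged-pore", "wide-pore")) {
    toy <- build_toy_channel(preset)
    expect_s3_class(toy$geometry, "csc_geometry")
    expect_true(all(in_aqueous_region(cbind(toy$wall_atoms$x,
                                            toy$wall_atoms$y,
                                            toy$wall_atoms$z), 0,
                                      toy$geometry)))
    expect_gt(toy$sf_min_diameter, 0)
    # boundary sizing rule: radial extent + hard radius + 0.1 margin
    expect_equal(toy$geometry$sf_radius,
                 max(sqrt(toy$wall_atoms$x^2 + toy$wall_atoms$y^2) +
                       toy$wall_atoms$radius) + 0.1)
  }
  expect_error(build_toy_channel("no-such"), "unknown preset")
})
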