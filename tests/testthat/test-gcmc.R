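test_that("grand-canonical acceptance probabilities follow the muVT formulas", {
  expect_identical(metropolis_accept(Inf, "displace"), 0)
  expect_identical(metropolis_accept(Inf, "insert", N = 0, V = 100, mu = 5), 0)
  expect_identical(metropolis_accept(0, "displace"), 1)
  expect_equal(metropolis_accept(1.3, "displace"), exp(-1.3))
  expect_equal(metropolis_accept(0.5, "insert", N = 3, V = 200, mu = -2),
               min(1, 200 / 4 * exp(-2 - 0.5)))
  expect_equal(metropolis_accept(-0.5, "delete", N = 3, V = 200, mu = -2),
               min(1, 3 / 200 * exp(2 + 0.5)))
  expect_equal(metropolis_accept(0, "swap", mu = log(2.2e-2)), 2.2e-2)
})

test_that("runs are reproducible and conserve N without insertions", {
  sys <- csc_system(csc_bulk_cell(10, 15), ideal_types(0.5))
  r1 <- csc_run(sys, 4000, seed = 4, sample_every = 5)
  r2 <- csc_run(sys, 4000, seed = 4, sample_every = 5)
  expect_identical(r1$hist, r2$hist)
  expect_identical(r1$Nblock, r2$Nblock)
  expect_identical(r1$acceptance, r2$acceptance)
  # displacement-only run conserves particle number
  tab <- default_species_table()
  ty <- build_types(tab, include = list(Na = 6),
                    concentrations = c(Na = 0.2))
  sys2 <- csc_system(csc_bulk_cell(12, 16), ty)
  st <- random_state(sys2, 4, seed = 2)
  r3 <- csc_run(sys2, 3000, seed = 5, init = st,
                weights = c(displace = 1, insert = 0, delete = 0, swap = 0))
  expect_equal(unname(colSums(r3$Nblock) / r3$nsamples),
               tabulate(st$type, nrow(ty)))
})

test_that("ideal-gas GCMC reproduces <N> = V exp(mu) and Poisson fluctuations", {
  sys <- csc_system(csc_bulk_cell(10, 15), ideal_types(0.4))
  run <- csc_run(sys, 40000, seed = 8, sample_every = 4,
                 weights = c(displace = 0.2, insert = 0.4, delete = 0.4,
                             swap = 0))
  mc <- mean_counts(run)
  expN <- sys$volume * exp(sys$types$mu[1])
  expect_lt(abs(mc$N_mean - expN), 3 * mc$N_se)
  # detailed balance on the enumerable side: N is Poisson, var(N) = <N>
  m1 <- sum(run$Nblock) / run$nsamples
  v <- run$Nsq[1] / run$nsamples - m1^2
  expect_lt(abs(v / m1 - 1), 0.1)
})

test_that("SF-biased insertion leaves the ideal-gas equation of state intact", {
  g <- tiny_geometry()
  sys <- csc_system(g, ideal_types(0.3))
  run <- csc_run(sys, 40000, seed = 9, sample_every = 4, sf_bias = 0.5,
                 weights = c(displace = 0.2, insert = 0.4, delete = 0.4,
                             swap = 0))
  mc <- mean_counts(run)
  # aqueous volume: cylinder minus the protein/membrane solid
  H <- g$sf_half_length + g$arc_radius
  v_solid <- pi * g$cell_radius^2 * 2 * H -
    stats::integrate(function(z) pi * aqueous_radius(g, z)^2, -H, H,
                     rel.tol = 1e-9)$value
  expN <- (sys$volume - v_solid) * exp(sys$types$mu[1])
  expect_lt(abs(mc$N_mean - expN), 3 * mc$N_se)
})

test_that("hydration-swap moves sample the configured state populations", {
  tab <- default_species_table()
  ty <- build_types(tab, include = list(K = c(6, 5)),
                    concentrations = c(K = 0.15))
  sys <- csc_system(csc_bulk_cell(16, 24), ty)
  run <- csc_run(sys, 120000, seed = 2, equil = 8000,
                 weights = c(displace = 0.5, insert = 0.2, delete = 0.2,
                             swap = 0.1), sample_every = 10)
  mc <- mean_counts(run)
  ratio <- mc$N_mean[2] / mc$N_mean[1]
  se <- ratio * sqrt((mc$N_se[1] / mc$N_mean[1])^2 +
                       (mc$N_se[2] / mc$N_mean[2])^2)
  expect_lt(abs(ratio - 2.2e-2), 3 * se)
})

test_that("bulk runs are symmetric across the membrane and near-neutral", {
  tab <- default_species_table()
  ty <- build_types(tab, include = list(Na = 6),
                    concentrations = c(Na = 0.2))
  sys <- csc_system(csc_bulk_cell(14, 20), ty)
  run <- csc_run(sys, 60000, seed = 13, equil = 4000, sample_every = 10,
                 weights = c(displace = 0.4, insert = 0.3, delete = 0.3,
                             swap = 0))
  zc <- (run$bin_edges[-1] + run$bin_edges[-length(run$bin_edges)]) / 2
  tot <- apply(run$hist, 1, sum)
  n_up <- sum(tot[zc > 0]); n_dn <- sum(tot[zc < 0])
  # binomial 3-sigma on the half-cell split (correlated samples: be generous)
  expect_lt(abs(n_up - n_dn), 6 * sqrt(n_up + n_dn))
  expect_lt(abs(run$mean_total_charge), 1.5)
})

test_that("checkpointed runs resume bit-identically", {
  sys <- csc_system(csc_bulk_cell(10, 15), ideal_types(0.4))
  full <- csc_run(sys, 6000, seed = 21, sample_every = 5,
                  weights = c(displace = 0.3, insert = 0.35, delete = 0.35,
                              swap = 0))
  ck <- tempfile(fileext = ".rds")
  half <- csc_run(sys, 6000, seed = 21, sample_every = 5,
                  weights = c(displace = 0.3, insert = 0.35, delete = 0.35,
                              swap = 0),
                  checkpoint_file = ck, checkpoint_every = 3500)
  resumed <- csc_resume(sys, ck, 6000, sample_every = 5,
                        weights = c(displace = 0.3, insert = 0.35,
                                    delete = 0.35, swap = 0))
  expect_identical(resumed$hist, full$hist)
  expect_identical(resumed$Nblock, full$Nblock)
  expect_identical(resumed$final_state$pos, full$final_state$pos)
  expect_error(suppressWarnings(csc_resume(sys, tempfile(), 6000)),
               "cannot open|corrupt")
})

test_that("cached energies track full recomputation through a charged channel run", {
  toy <- build_toy_channel("charged-pore")
  tab <- default_species_table()
  op <- assemble_icc_operator(build_mesh(toy$geometry, 2.2, n_theta = 12))
  ty <- build_types(tab, include = list(Na = 4), concentrations = c(Na = 1))
  sys <- csc_system(toy$geometry, ty, wall_atoms = toy$wall_atoms, icc = op)
  run <- csc_run(sys, 8000, seed = 30, sf_bias = 0.5, sample_every = 10,
                 check_every = 1000,
                 weights = c(displace = 0.5, insert = 0.25, delete = 0.25,
                             swap = 0))
  expect_lt(run$consistency_max_rel_dev, 1e-8)
  # no stored frame may contain an overlap or region violation
  fs <- run$final_state
  expect_false(cscmc:::any_overlap(sys, fs))
})

test_that("chemical-potential calibration is exact for an ideal gas and monotone in the target", {
  # concentrations high enough that one verification run resolves 2%
  sys <- csc_system(csc_bulk_cell(12, 18), ideal_types(2))
  cal <- calibrate_mu(sys, seed = 100, n_steps = 50000, sample_every = 5,
                      weights = c(displace = 0.2, insert = 0.4,
                                  delete = 0.4, swap = 0))
  expect_true(cal$converged)
  # the Lambda-free closed form mu = ln(rho) is recovered unchanged
  expect_equal(unname(cal$mu), log(molar_to_density(2)), tolerance = 1e-12)
  sys2 <- csc_system(csc_bulk_cell(12, 18), ideal_types(4))
  cal2 <- calibrate_mu(sys2, seed = 100, n_steps = 50000, sample_every = 5,
                       weights = c(displace = 0.2, insert = 0.4,
                                   delete = 0.4, swap = 0))
  expect_gt(cal2$mu[1], cal$mu[1])
})
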