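# helper: build a csc_profile directly from per-bin concentrations
fake_profile <- function(z, conc_by_type, species, x = NULL, se = NULL,
                         counts = NULL, bin_width = NULL, vols = NULL,
                         nsamples = 1000, smoothed = FALSE) {
  if (is.null(bin_width)) bin_width <- diff(z[1:2])
  if (is.null(x)) x <- rep(NA_integer_, length(species))
  out <- do.call(rbind, lapply(seq_along(species), function(t) {
    data.frame(z = z, type = sprintf("%s.%s", species[t], t),
               species = species[t], x = x[t],
               conc = conc_by_type[[t]],
               se = if (is.null(se)) rep(1e-4, length(z)) else se[[t]],
               counts = if (is.null(counts)) rep(10, length(z)) else
                 counts[[t]],
               stringsAsFactors = FALSE)
  }))
  structure(out, bin_width = bin_width, nsamples = nsamples,
            smoothed = smoothed,
            slab_volumes = if (is.null(vols)) rep(50, length(z)) else vols,
            class = c("csc_profile", "data.frame"))
}

test_that("moving-average smoothing matches a brute-force windowed mean", {
  z <- seq(-9.95, 9.95, by = 0.1)
  const <- fake_profile(z, list(rep(2.5, length(z))), "A")
  expect_equal(smooth_profile(const, 2)$conc, rep(2.5, length(z)))
  # an interior single-bin spike keeps its mass
  spike <- rep(0, length(z)); spike[100] <- 7
  p <- fake_profile(z, list(spike), "A")
  sm <- smooth_profile(p, 2)
  expect_equal(sum(sm$conc), sum(spike), tolerance = 1e-12)
  # random profile against a direct loop oracle
  set.seed(12)
  v <- runif(length(z))
  p2 <- fake_profile(z, list(v), "A")
  sm2 <- smooth_profile(p2, 2)
  k <- 20; half <- (k - 1) %/% 2
  ora <- sapply(seq_along(v), function(i) {
    lo <- max(1, i - half); hi <- min(length(v), i + half)
    mean(v[lo:hi])
  })
  expect_equal(sm2$conc, ora, tolerance = 1e-12)
  expect_error(smooth_profile(p2, 0.05), "at least one bin")
})

test_that("profile minima land on edges, vertices, and match exhaustive scans", {
  z <- seq(-9.95, 9.95, by = 0.1)
  mono <- fake_profile(z, list(1 + (z + 10) / 20), "A", smoothed = TRUE)
  m <- profile_min(mono, c(-5, -1), "A")
  expect_equal(m$z_at_min, -4.95)
  expect_equal(m$value, 1 + (-4.95 + 10) / 20)
  parab <- fake_profile(z, list(2 + (z + 3)^2), "A", smoothed = TRUE)
  m2 <- profile_min(parab, c(-6, 0), "A")
  expect_equal(m2$z_at_min, -2.95, tolerance = 0.11)
  expect_equal(m2$value, min((2 + (z + 3)^2)[z >= -6 & z <= 0]))
  # two hydration states are summed per species before the scan
  set.seed(4)
  v1 <- runif(length(z)); v2 <- runif(length(z))
  p <- fake_profile(z, list(v1, v2), c("A", "A"), x = c(4, 3),
                    smoothed = TRUE)
  m3 <- profile_min(p, c(-3, 3), "A")
  tot <- v1 + v2
  expect_equal(m3$value, min(tot[z >= -3 & z <= 3]), tolerance = 1e-12)
  expect_error(profile_min(p, c(15, 16), "A"), "empty")
  expect_error(profile_min(p, c(-3, 3), "B"), "not in profile")
})

test_that("empty windows report the 95% Poisson upper bound", {
  z <- seq(-9.95, 9.95, by = 0.1)
  empty <- fake_profile(z, list(rep(0, length(z))), "A",
                        counts = list(rep(0, length(z))), smoothed = TRUE,
                        nsamples = 2000)
  m <- profile_min(empty, c(-2, 2), "A")
  expect_true(m$bound)
  nbin_w <- sum(z >= -2 & z <= 2)
  expect_equal(m$value, -log(0.05) / (2000 * nbin_w * 50) * 1e27 /
                 6.02214076e23, tolerance = 1e-9)
})

test_that("alpha_hat_sim is 1 for identical ions and scale-invariant", {
  expect_equal(alpha_sim_hat(0.3, 0.3, 2, 2)$value, 1)
  a1 <- alpha_sim_hat(0.4, 0.1, 2, 3)$value
  a2 <- alpha_sim_hat(0.4, 0.1, 2 * 7, 3 * 7)$value
  expect_equal(a1, a2, tolerance = 1e-12)
  lb <- alpha_sim_hat(list(value = 0.4, bound = FALSE),
                      list(value = 0.1, bound = TRUE), 2, 3)
  expect_identical(lb$bound, "lower")
})

test_that("alpha_hat_sim recovers the constructed ratio of Boltzmann profiles exactly", {
  # two species in known external potentials; no sampling noise anywhere
  z <- seq(-9.995, 9.995, by = 0.01)
  U_A <- 1.2 * cos(z / 3) + 0.4 * z^2 / 50
  U_B <- 2.1 * cos(z / 3 + 0.2)
  bulk_A <- 0.07; bulk_B <- 0.21
  p <- fake_profile(z, list(bulk_A * exp(-U_A), bulk_B * exp(-U_B)),
                    c("A", "B"), smoothed = TRUE)
  win <- c(-4, 1)
  mA <- profile_min(p, win, "A")
  mB <- profile_min(p, win, "B")
  got <- alpha_sim_hat(mA, mB, bulk_A, bulk_B)$value
  inw <- z >= win[1] & z <= win[2]
  want <- exp(-max(U_A[inw])) / exp(-max(U_B[inw]))
  expect_lt(abs(got - want), 1e-10)
})

test_that("alpha_hyd and alpha_sim reproduce the tabulated decompositions", {
  tab <- default_species_table()
  expect_equal(round(alpha_hyd(tab$Na, tab$K, c(4, 3), c(4, 3)), 1), 0.3)
  expect_equal(signif(alpha_hyd(tab$Ca, tab$Na, 4, 4), 1), 3e-29)
  # alpha_sim = alpha_hyd x alpha_hat_sim, exactly, and preserves bounds
  expect_equal(alpha_total(0.1, 49000), 4900)
  expect_equal(alpha_total(600, 1), 600)
  expect_equal(alpha_total(12.34, 1), 12.34)
  b <- alpha_total(list(value = 2, bound = "lower"), 0.3)
  expect_equal(b$value, 0.6)
  expect_identical(b$bound, "lower")
})

test_that("run aggregation weights replicates by inverse variance", {
  sys <- csc_system(csc_bulk_cell(10, 15), ideal_types(1))
  wt <- c(displace = 0.3, insert = 0.35, delete = 0.35, swap = 0)
  runs <- lapply(1:2, function(s)
    csc_run(sys, 15000, seed = 200 + s, sample_every = 5, weights = wt))
  # single replicate: identity
  expect_identical(aggregate_runs(runs[1]), density_profile(runs[[1]]))
  comb <- aggregate_runs(runs)
  p1 <- density_profile(runs[[1]]); p2 <- density_profile(runs[[2]])
  # hand-computed inverse-variance weighted mean, bin by bin
  i <- which(p1$counts > 0 & p2$counts > 0)[1]
  w <- c(1 / p1$se[i]^2, 1 / p2$se[i]^2)
  expect_equal(comb$conc[i],
               sum(w * c(p1$conc[i], p2$conc[i])) / sum(w),
               tolerance = 1e-12)
  expect_equal(comb$se[i], sqrt(1 / sum(w)), tolerance = 1e-12)
  # identical replicates: same mean, SE shrunk by sqrt(2)
  twin <- aggregate_runs(list(runs[[1]], runs[[1]]))
  expect_equal(twin$conc, p1$conc, tolerance = 1e-12)
  j <- which(p1$se > 0)
  expect_equal(twin$se[j], p1$se[j] / sqrt(2), tolerance = 1e-12)
  # incompatible configurations are refused
  sys2 <- csc_system(csc_bulk_cell(11, 15), ideal_types(1))
  r3 <- csc_run(sys2, 5000, seed = 7, sample_every = 5, weights = wt)
  expect_error(aggregate_runs(list(runs[[1]], r3)), "share configuration")
})

test_that("profile concentrations integrate back to the mean particle counts", {
  sys <- csc_system(csc_bulk_cell(10, 15), ideal_types(1))
  run <- csc_run(sys, 20000, seed = 33, sample_every = 5,
                 weights = c(displace = 0.3, insert = 0.35, delete = 0.35,
                             swap = 0))
  prof <- density_profile(run)
  vols <- attr(prof, "slab_volumes")
  n_from_profile <- sum(prof$conc * vols) / (1e27 / 6.02214076e23)
  mc <- mean_counts(run)
  expect_equal(n_from_profile, mc$N_mean, tolerance = 0.02)
  # far-field totals match the configured bulk concentration within 3 SE
  mb <- measure_bulk_concentration(run)
  expect_lt(abs(mb$conc - 1), 3 * mb$se + 0.02)
})

test_that("selectivity objects serialize to JSON and TSV", {
  z <- seq(-9.95, 9.95, by = 0.1)
  p <- fake_profile(z, list(0.3 + z^2 / 100, 0.2 + (z + 1)^2 / 80),
                    c("A", "B"), smoothed = TRUE)
  tsv <- tempfile(fileext = ".tsv")
  write_profile_tsv(p, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(p))
  expect_equal(back$conc, p$conc, tolerance = 1e-9)
})
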