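# Grand-canonical Metropolis Monte Carlo: displacement, insertion, deletion
# and the hydration-state swap move, plus chemical-potential calibration.
#
# mu convention: Lambda-free, i.e. mu = ln(rho * Angstrom^3) for an ideal
# gas.  Only mu differences and mu - ln(rho) are observable, so the thermal
# wavelength drops out of every acceptance ratio.

#' Grand-canonical acceptance probability
#'
#' Standard muVT Metropolis acceptance (beta = 1 in kT units):
#' displacement `min(1, exp(-dH))`; insertion
#' `min(1, V/(N+1) exp(mu - dH))`; deletion `min(1, N/V exp(-mu - dH))`;
#' hydration swap `min(1, exp(mu_new - mu_old - dH))` (the volume and count
#' factors of the concatenated deletion + insertion at a fixed location
#' cancel).  An infinite `dH` always rejects.
#'
#' @param dH energy difference in kT (may be `+Inf`).
#' @param kind one of `"displace"`, `"insert"`, `"delete"`, `"swap"`.
#' @param N current particle count of the affected type.
#' @param V cell volume (Angstrom^3).
#' @param mu chemical potential of the affected type (kT); for `"swap"` give
#'   `mu_new - mu_old`.
#' @return Acceptance probability in `[0, 1]`.
#' @export
metropolis_accept <- function(dH, kind = c("displace", "insert", "delete",
                                           "swap"),
                              N = NULL, V = NULL, mu = NULL) {
  kind <- match.arg(kind)
  if (is.infinite(dH) && dH > 0) return(0)
  la <- switch(kind,
               displace = -dH,
               insert = mu - dH + log(V / (N + 1)),
               delete = -mu - dH + log(N / V),
               swap = mu - dH)
  min(1, exp(la))
}

# mixture proposal density of the (optionally SF-biased) insertion position
insert_density <- function(p, bias) {
  base <- (1 - bias$p_sf) / bias$V_cell
  if (bias$p_sf > 0) {
    r2 <- p[1]^2 + p[2]^2
    if (r2 <= bias$r_sf^2 && p[3] >= bias$z_lo && p[3] <= bias$z_hi)
      return(base + bias$p_sf / bias$V_sf)
  }
  base
}

uic_from_cache <- function(op, b0, tv) {
  if (is.null(op) || op$chi == 0) return(0)
  h <- drop(op$Minv %*% ((op$chi / op$eps_water) * b0))
  0.5 * .csc_coulomb_kT * sum(tv * h)
}

# Build the mutable engine environment from a system + state.
engine_init <- function(sys, state, opts) {
  E <- new.env(parent = emptyenv())
  m <- if (is.null(sys$wall)) 0L else nrow(sys$wall)
  n <- nrow(state$pos)
  E$m <- m
  E$P <- rbind(state$wall_pos, state$pos)        # wall rows first
  E$R <- c(if (m) sys$wall$radius else numeric(0),
           sys$types$radius[state$type])
  E$Q <- c(if (m) sys$wall$charge else numeric(0),
           sys$types$charge[state$type])
  E$typ <- as.integer(state$type)                 # ions only (rows m+1..m+n)
  E$n <- n
  E$Nt <- tabulate(E$typ, nrow(sys$types))
  # energies + ICC caches
  E$U_mob <- mobility_energy(sys$wall, E$P[seq_len(m), , drop = FALSE])
  E$U_C <- {
    keep <- E$Q != 0
    if (sum(keep) >= 2)
      coulomb_energy(E$P[keep, , drop = FALSE], E$Q[keep], sys$eps_water)
    else 0
  }
  if (!is.null(sys$icc)) {
    keep <- which(E$Q != 0)
    s <- icc_sums(sys$icc, E$P[keep, , drop = FALSE], E$Q[keep])
    E$b0 <- s$b0; E$tv <- s$t
    E$U_IC <- uic_from_cache(sys$icc, E$b0, E$tv)
  } else {
    E$b0 <- NULL; E$tv <- NULL; E$U_IC <- 0
  }
  E$att <- c(displace = 0, insert = 0, delete = 0, swap = 0)
  E$acc <- c(displace = 0, insert = 0, delete = 0, swap = 0)
  E$max_dev <- 0
  E
}

engine_state <- function(sys, E) {
  m <- E$m
  csc_state(sys,
            pos = E$P[m + seq_len(E$n), , drop = FALSE],
            type = E$typ,
            wall_pos = E$P[seq_len(m), , drop = FALSE])
}

# one full recomputation of the cached energies; returns max relative
# deviation and refreshes the caches
engine_check <- function(sys, E) {
  keep <- which(E$Q != 0)
  U_C <- if (length(keep) >= 2)
    coulomb_energy(E$P[keep, , drop = FALSE], E$Q[keep], sys$eps_water) else 0
  U_mob <- mobility_energy(sys$wall, E$P[seq_len(E$m), , drop = FALSE])
  dev <- abs(U_C - E$U_C) / max(abs(U_C), 1)
  if (!is.null(sys$icc)) {
    s <- icc_sums(sys$icc, E$P[keep, , drop = FALSE], E$Q[keep])
    U_IC <- uic_from_cache(sys$icc, s$b0, s$t)
    dev <- max(dev, abs(U_IC - E$U_IC) / max(abs(U_IC), 1))
    E$b0 <- s$b0; E$tv <- s$t; E$U_IC <- U_IC
  }
  dev <- max(dev, abs(U_mob - E$U_mob) / max(abs(U_mob), 1))
  E$U_C <- U_C
  E$U_mob <- U_mob
  E$max_dev <- max(E$max_dev, dev)
  invisible(dev)
}

# one Monte Carlo step; mutates E
engine_step <- function(sys, E, opts) {
  u <- stats::runif(1)
  kind <- opts$kind_names[findInterval(u, opts$kind_cum) + 1L]
  op <- sys$icc
  eps <- sys$eps_water
  nb <- E$m + E$n

  if (kind == "displace") {
    E$att["displace"] <- E$att["displace"] + 1
    if (nb == 0) return(invisible())
    j <- sample.int(nb, 1)
    old <- E$P[j, ]
    pnew <- old + (stats::runif(3) - 0.5) * 2 * E$step
    if (!in_aqueous_region(pnew, E$R[j], sys$geometry)) return(invisible())
    d2 <- (E$P[, 1] - pnew[1])^2 + (E$P[, 2] - pnew[2])^2 +
      (E$P[, 3] - pnew[3])^2
    d2[j] <- Inf
    if (nb > 1 && any(d2 < (E$R + E$R[j])^2 - 1e-12)) return(invisible())
    qi <- E$Q[j]
    dU <- 0
    if (qi != 0 && nb > 1) {
      keep <- which(E$Q != 0); keep <- keep[keep != j]
      if (length(keep)) {
        others <- E$P[keep, , drop = FALSE]
        qo <- E$Q[keep]
        d_old <- sqrt((others[, 1] - old[1])^2 + (others[, 2] - old[2])^2 +
                        (others[, 3] - old[3])^2)
        d_new <- sqrt(d2[keep])
        dU <- (.csc_coulomb_kT / eps) * qi * sum(qo / d_new - qo / d_old)
      }
    }
    dmob <- 0
    if (j <= E$m) {
      wb <- c(sys$wall$x[j], sys$wall$y[j], sys$wall$z[j])
      dmob <- 0.5 * sys$wall$k[j] * (sum((pnew - wb)^2) - sum((old - wb)^2))
    }
    dic <- 0
    if (!is.null(op) && qi != 0) {
      dw <- qi * (icc_field_vec(op, pnew) - icc_field_vec(op, old))
      dv <- qi * (icc_pot_vec(op, pnew) - icc_pot_vec(op, old))
      b0n <- E$b0 + dw; tvn <- E$tv + dv
      uic_new <- uic_from_cache(op, b0n, tvn)
      dic <- uic_new - E$U_IC
    }
    dH <- dU + dmob + dic
    if (dH <= 0 || stats::runif(1) < exp(-dH)) {
      E$P[j, ] <- pnew
      E$U_C <- E$U_C + dU
      E$U_mob <- E$U_mob + dmob
      if (!is.null(op) && qi != 0) { E$b0 <- b0n; E$tv <- tvn; E$U_IC <- uic_new }
      E$acc["displace"] <- E$acc["displace"] + 1
    }
    return(invisible())
  }

  if (kind == "insert") {
    E$att["insert"] <- E$att["insert"] + 1
    t <- sample.int(opts$n_types, 1)
    bias <- opts$bias
    if (bias$p_sf > 0 && stats::runif(1) < bias$p_sf) {
      rr <- bias$r_sf * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      pnew <- c(rr * cos(th), rr * sin(th),
                stats::runif(1, bias$z_lo, bias$z_hi))
    } else {
      rr <- sys$geometry$cell_radius * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      pnew <- c(rr * cos(th), rr * sin(th),
                stats::runif(1, -sys$geometry$cell_half_length,
                             sys$geometry$cell_half_length))
    }
    ri <- opts$r_t[t]; qi <- opts$q_t[t]
    if (!in_aqueous_region(pnew, ri, sys$geometry)) return(invisible())
    if (nb > 0) {
      d2 <- (E$P[, 1] - pnew[1])^2 + (E$P[, 2] - pnew[2])^2 +
        (E$P[, 3] - pnew[3])^2
      if (any(d2 < (E$R + ri)^2 - 1e-12)) return(invisible())
    }
    dU <- 0
    if (qi != 0 && nb > 0) {
      keep <- which(E$Q != 0)
      if (length(keep))
        dU <- (.csc_coulomb_kT / eps) * qi *
          sum(E$Q[keep] / sqrt(d2[keep]))
    }
    dic <- 0
    if (!is.null(op) && qi != 0) {
      b0n <- E$b0 + qi * icc_field_vec(op, pnew)
      tvn <- E$tv + qi * icc_pot_vec(op, pnew)
      uic_new <- uic_from_cache(op, b0n, tvn)
      dic <- uic_new - E$U_IC
    }
    dH <- dU + dic
    la <- opts$mu_t[t] - dH - log(E$Nt[t] + 1) -
      log(insert_density(pnew, bias))
    if (la >= 0 || stats::runif(1) < exp(la)) {
      E$P <- rbind(E$P, pnew, deparse.level = 0)
      E$R <- c(E$R, ri); E$Q <- c(E$Q, qi)
      E$typ <- c(E$typ, t)
      E$n <- E$n + 1L
      E$Nt[t] <- E$Nt[t] + 1L
      E$U_C <- E$U_C + dU
      if (!is.null(op) && qi != 0) { E$b0 <- b0n; E$tv <- tvn; E$U_IC <- uic_new }
      E$acc["insert"] <- E$acc["insert"] + 1
    }
    return(invisible())
  }

  if (kind == "delete") {
    E$att["delete"] <- E$att["delete"] + 1
    t <- sample.int(opts$n_types, 1)
    if (E$Nt[t] == 0L) return(invisible())
    cand <- which(E$typ == t)
    i <- cand[sample.int(length(cand), 1)]       # ion index
    j <- E$m + i                                  # body row
    p <- E$P[j, ]
    qi <- E$Q[j]
    dU <- 0
    if (qi != 0 && nb > 1) {
      keep <- which(E$Q != 0); keep <- keep[keep != j]
      if (length(keep)) {
        d <- sqrt((E$P[keep, 1] - p[1])^2 + (E$P[keep, 2] - p[2])^2 +
                    (E$P[keep, 3] - p[3])^2)
        dU <- -(.csc_coulomb_kT / eps) * qi * sum(E$Q[keep] / d)
      }
    }
    dic <- 0
    if (!is.null(op) && qi != 0) {
      b0n <- E$b0 - qi * icc_field_vec(op, p)
      tvn <- E$tv - qi * icc_pot_vec(op, p)
      uic_new <- uic_from_cache(op, b0n, tvn)
      dic <- uic_new - E$U_IC
    }
    dH <- dU + dic
    la <- -opts$mu_t[t] - dH + log(E$Nt[t]) +
      log(insert_density(p, opts$bias))
    if (la >= 0 || stats::runif(1) < exp(la)) {
      E$P <- E$P[-j, , drop = FALSE]
      E$R <- E$R[-j]; E$Q <- E$Q[-j]
      E$typ <- E$typ[-i]
      E$n <- E$n - 1L
      E$Nt[t] <- E$Nt[t] - 1L
      E$U_C <- E$U_C + dU
      if (!is.null(op) && qi != 0) { E$b0 <- b0n; E$tv <- tvn; E$U_IC <- uic_new }
      E$acc["delete"] <- E$acc["delete"] + 1
    }
    return(invisible())
  }

  # hydration swap
  E$att["swap"] <- E$att["swap"] + 1
  if (E$n == 0) return(invisible())
  i <- sample.int(E$n, 1)
  partners <- opts$swap_partners[[E$typ[i]]]
  if (length(partners) == 0) return(invisible())
  t_new <- if (length(partners) == 1) partners else
    partners[sample.int(length(partners), 1)]
  j <- E$m + i
  r_new <- opts$r_t[t_new]
  if (r_new > E$R[j]) {                           # growing sphere: check room
    p <- E$P[j, ]
    if (!in_aqueous_region(p, r_new, sys$geometry)) return(invisible())
    d2 <- (E$P[, 1] - p[1])^2 + (E$P[, 2] - p[2])^2 + (E$P[, 3] - p[3])^2
    d2[j] <- Inf
    if (nb > 1 && any(d2 < (E$R + r_new)^2 - 1e-12)) return(invisible())
  }
  la <- opts$mu_t[t_new] - opts$mu_t[E$typ[i]]    # dH = 0: charge unchanged
  if (la >= 0 || stats::runif(1) < exp(la)) {
    t_old <- E$typ[i]
    E$typ[i] <- t_new
    E$R[j] <- r_new
    E$Nt[t_old] <- E$Nt[t_old] - 1L
    E$Nt[t_new] <- E$Nt[t_new] + 1L
    E$acc["swap"] <- E$acc["swap"] + 1
  }
  invisible()
}

build_opts <- function(sys, weights, step_size, sf_bias, sf_window) {
  ty <- sys$types
  n_types <- nrow(ty)
  # swap partners: other included states of the same species
  swap_partners <- lapply(seq_len(n_types), function(t) {
    same <- which(ty$species == ty$species[t] & !is.na(ty$x))
    setdiff(same[!is.na(ty$x[same])], t)
  })
  if (all(lengths(swap_partners) == 0)) weights["swap"] <- 0
  w <- weights / sum(weights)
  geom <- sys$geometry
  if (is.null(sf_window))
    sf_window <- if (geom$type == "channel")
      c(-(geom$sf_half_length + 2), geom$sf_half_length + 2) else c(0, 0)
  r_sf <- if (geom$type == "channel") geom$sf_radius else 0
  V_sf <- pi * r_sf^2 * (sf_window[2] - sf_window[1])
  bias <- list(p_sf = if (geom$type == "channel") sf_bias else 0,
               r_sf = r_sf, z_lo = sf_window[1], z_hi = sf_window[2],
               V_sf = max(V_sf, 1e-12), V_cell = sys$volume)
  list(kind_names = names(w), kind_cum = cumsum(w)[-length(w)],
       n_types = n_types,
       q_t = ty$charge, r_t = ty$radius, mu_t = ty$mu,
       swap_partners = swap_partners, bias = bias)
}

#' Run a grand-canonical Monte Carlo simulation
#'
#' Metropolis muVT sampling of the CSC Hamiltonian with displacement,
#' insertion, deletion and hydration-swap moves.  Fully reproducible from
#' `(system, arguments, seed)`.
#'
#' @param sys a `csc_system`.
#' @param n_steps number of production MC steps.
#' @param seed integer RNG seed (mandatory: runs are reproducible).
#' @param init optional initial `csc_state`; defaults to an empty cell.
#' @param weights named move-mix weights
#'   (`displace`, `insert`, `delete`, `swap`); renormalized internally.
#' @param step_size initial maximum displacement (Angstrom).
#' @param equil number of equilibration steps (not accumulated); during the
#'   first 60\% of them the displacement step is tuned towards ~40\%
#'   acceptance, then frozen.
#' @param sample_every accumulate observables every this many steps.
#' @param n_blocks number of blocks for Monte-Carlo standard errors.
#' @param bin_width axial histogram bin width (Angstrom).
#' @param sf_bias fraction of insertion/deletion proposals restricted to a
#'   cylindrical window around the SF (0 = uniform; detailed balance holds
#'   for any value via the mixture proposal density).
#' @param sf_window z-window `c(lo, hi)` of the biased region.
#' @param check_every interval for the cached-energy consistency check.
#' @param bulk_buffer margin (Angstrom) excluded from the bulk sampling
#'   region at the cell walls.
#' @param checkpoint_file,checkpoint_every optional RDS checkpoint path and
#'   interval (steps).
#' @return Object of class `csc_run`: accumulators (axial histograms per
#'   type with block structure, particle-number samples, bulk-region counts),
#'   acceptance statistics, the final state, and an echo of the run set-up.
#' @export
csc_run <- function(sys, n_steps, seed, init = NULL,
                    weights = c(displace = 0.8, insert = 0.05,
                                delete = 0.05, swap = 0.1),
                    step_size = 0.8, equil = 0, sample_every = 10,
                    n_blocks = 25, bin_width = 0.1, sf_bias = 0,
                    sf_window = NULL, check_every = 5000, bulk_buffer = 4,
                    checkpoint_file = NULL, checkpoint_every = NULL) {
  stopifnot(n_steps >= 1, !missing(seed))
  set.seed(as.integer(seed))
  if (is.null(init)) init <- csc_state(sys)
  if (any_overlap(sys, init))
    stop("initial state contains hard-body overlaps or region violations")
  opts <- build_opts(sys, weights, step_size, sf_bias, sf_window)
  E <- engine_init(sys, init, opts)
  E$step <- step_size
  geom <- sys$geometry

  # equilibration with step tuning
  if (equil > 0) {
    tune_until <- floor(0.6 * equil)
    a0 <- 0; t0 <- 0
    for (s in seq_len(equil)) {
      engine_step(sys, E, opts)
      if (s %% 250 == 0 && s <= tune_until) {
        da <- E$acc["displace"] - a0; dt <- E$att["displace"] - t0
        if (dt > 0) {
          rate <- da / dt
          fac <- if (rate > 0.45) 1.2 else if (rate < 0.35) 0.85 else 1
          E$step <- min(max(E$step * fac, 0.05), geom$cell_radius / 2)
        }
        a0 <- E$acc["displace"]; t0 <- E$att["displace"]
      }
    }
    E$att[] <- 0; E$acc[] <- 0
  }

  # accumulators
  n_types <- nrow(sys$types)
  nbins <- ceiling(2 * geom$cell_half_length / bin_width)
  edges <- seq(-geom$cell_half_length, by = bin_width, length.out = nbins + 1)
  totsamp <- floor(n_steps / sample_every)
  spb <- max(1L, ceiling(totsamp / n_blocks))
  n_blocks <- ceiling(totsamp / spb)
  hist <- array(0, dim = c(nbins, n_types, n_blocks))
  Nblock <- matrix(0, n_blocks, n_types)
  Nsq <- numeric(n_types)                          # per-sample N^2 sums
  bulk_in <- matrix(0, n_blocks, n_types)          # counts in bulk region
  # bulk sampling region: interior cylinder away from walls and membrane
  r_in <- geom$cell_radius - bulk_buffer
  z_in_lo <- if (geom$type == "channel") geom$membrane_half + 3 else 0
  z_in_hi <- geom$cell_half_length - bulk_buffer
  V_bulk <- pi * r_in^2 * 2 * (z_in_hi - z_in_lo)
  charge_sum <- 0

  isample <- 0L
  for (s in seq_len(n_steps)) {
    engine_step(sys, E, opts)
    if (s %% sample_every == 0 && isample < totsamp) {
      isample <- isample + 1L
      blk <- 1L + (isample - 1L) %/% spb
      if (E$n > 0) {
        zs <- E$P[E$m + seq_len(E$n), 3]
        bins <- pmin(nbins, pmax(1L, 1L + (zs - edges[1]) %/% bin_width))
        for (ii in seq_len(E$n))
          hist[bins[ii], E$typ[ii], blk] <- hist[bins[ii], E$typ[ii], blk] + 1
        Nblock[blk, ] <- Nblock[blk, ] + E$Nt
        Nsq <- Nsq + as.numeric(E$Nt)^2
        rr2 <- E$P[E$m + seq_len(E$n), 1]^2 + E$P[E$m + seq_len(E$n), 2]^2
        inb <- rr2 <= r_in^2 & abs(zs) >= z_in_lo & abs(zs) <= z_in_hi
        if (any(inb)) {
          tb <- tabulate(E$typ[inb], n_types)
          bulk_in[blk, ] <- bulk_in[blk, ] + tb
        }
      }
      charge_sum <- charge_sum + sum(E$Q)
    }
    if (s %% check_every == 0) engine_check(sys, E)
    if (!is.null(checkpoint_file) && !is.null(checkpoint_every) &&
        s %% checkpoint_every == 0) {
      saveRDS(list(E = as.list(E), rng = .Random.seed, step_done = s,
                   isample = isample, hist = hist, Nblock = Nblock,
                   Nsq = Nsq, bulk_in = bulk_in, charge_sum = charge_sum),
              checkpoint_file)
    }
  }
  engine_check(sys, E)

  structure(list(
    n_steps = n_steps, seed = seed, sample_every = sample_every,
    nsamples = isample, samples_per_block = spb, n_blocks = n_blocks,
    bin_edges = edges, bin_width = bin_width,
    hist = hist, Nblock = Nblock, Nsq = Nsq, bulk_in = bulk_in,
    bulk_region = list(r = r_in, z_lo = z_in_lo, z_hi = z_in_hi,
                       volume = V_bulk),
    acceptance = data.frame(kind = names(E$att), attempted = as.numeric(E$att),
                            accepted = as.numeric(E$acc)),
    step_size = E$step, consistency_max_rel_dev = E$max_dev,
    mean_total_charge = charge_sum / max(isample, 1),
    types = sys$types, geometry = geom, volume = sys$volume,
    sf_bias = sf_bias,
    final_state = engine_state(sys, E)),
    class = "csc_run")
}

#' @export
print.csc_run <- function(x, ...) {
  cat(sprintf("CSC GCMC run: %d steps (seed %s), %d samples\n",
              x$n_steps, format(x$seed), x$nsamples))
  a <- x$acceptance
  a$rate <- ifelse(a$attempted > 0, a$accepted / a$attempted, NA)
  print(a, row.names = FALSE)
  cat(sprintf("final <N> by type: %s\n",
              paste(sprintf("%s=%.2f", x$types$type,
                            colSums(x$Nblock) / max(x$nsamples, 1)),
                    collapse = ", ")))
  cat(sprintf("mean total charge %.3f e; cached-energy max rel dev %.2e\n",
              x$mean_total_charge, x$consistency_max_rel_dev))
  invisible(x)
}

#' @export
summary.csc_run <- function(object, ...) {
  cat("Grand-canonical CSC run\n")
  print(object)
  mb <- measure_bulk_concentration(object)
  cat("bulk-region concentrations (mol/L):\n")
  print(cbind(mb, target = object$types$conc_target), row.names = FALSE)
  invisible(object)
}

#' @export
plot.csc_run <- function(x, smooth_window = 2, ...) {
  plot(smooth_profile(density_profile(x), smooth_window), ...)
}

#' Mean particle numbers with Monte-Carlo standard errors
#'
#' @param run a `csc_run`.
#' @return Data frame `type, N_mean, N_se` from block averages.
#' @export
mean_counts <- function(run) {
  bm <- run$Nblock / run$samples_per_block
  nb <- nrow(bm)
  # last block may be partial
  full <- seq_len(max(1, nb - 1))
  bm <- bm[full, , drop = FALSE]
  data.frame(type = run$types$type,
             N_mean = colMeans(bm),
             N_se = apply(bm, 2, stats::sd) / sqrt(nrow(bm)))
}

#' Bulk-region concentrations with standard errors
#'
#' Concentrations measured in the interior bulk sampling region (away from
#' hard walls and the membrane), in mol/L.
#'
#' @param run a `csc_run`.
#' @return Data frame `type, species, conc, se` (mol/L).
#' @export
measure_bulk_concentration <- function(run) {
  V <- run$bulk_region$volume
  bm <- run$bulk_in / run$samples_per_block / V * .csc_molar_per_A3
  nb <- nrow(bm)
  full <- seq_len(max(1, nb - 1))
  bm <- bm[full, , drop = FALSE]
  data.frame(type = run$types$type, species = run$types$species,
             conc = colMeans(bm),
             se = apply(bm, 2, stats::sd) / sqrt(nrow(bm)))
}

#' Resume a checkpointed run
#'
#' Restores the engine, RNG stream and accumulators from an RDS checkpoint
#' written by [csc_run()] and finishes the remaining steps; the result is
#' bit-identical to the uninterrupted run.
#'
#' @param sys the `csc_system` of the original run.
#' @param file checkpoint path.
#' @param n_steps,... the original [csc_run()] arguments.
#' @return A `csc_run`.
#' @export
csc_resume <- function(sys, file, n_steps,
                       weights = c(displace = 0.8, insert = 0.05,
                                   delete = 0.05, swap = 0.1),
                       step_size = 0.8, sample_every = 10, n_blocks = 25,
                       bin_width = 0.1, sf_bias = 0, sf_window = NULL,
                       check_every = 5000, bulk_buffer = 4) {
  ck <- readRDS(file)
  if (!is.list(ck) || is.null(ck$E) || is.null(ck$rng))
    stop("corrupt or unrecognized checkpoint file")
  opts <- build_opts(sys, weights, step_size, sf_bias, sf_window)
  E <- list2env(ck$E, new.env(parent = emptyenv()))
  assign(".Random.seed", ck$rng, envir = globalenv())
  geom <- sys$geometry
  n_types <- nrow(sys$types)
  nbins <- dim(ck$hist)[1]
  edges <- seq(-geom$cell_half_length, by = bin_width, length.out = nbins + 1)
  totsamp <- floor(n_steps / sample_every)
  spb <- max(1L, ceiling(totsamp / n_blocks))
  n_blocks <- ceiling(totsamp / spb)
  hist <- ck$hist; Nblock <- ck$Nblock; bulk_in <- ck$bulk_in
  Nsq <- if (is.null(ck$Nsq)) numeric(n_types) else ck$Nsq
  charge_sum <- ck$charge_sum
  isample <- ck$isample
  r_in <- geom$cell_radius - bulk_buffer
  z_in_lo <- if (geom$type == "channel") geom$membrane_half + 3 else 0
  z_in_hi <- geom$cell_half_length - bulk_buffer
  V_bulk <- pi * r_in^2 * 2 * (z_in_hi - z_in_lo)
  for (s in ck$step_done + seq_len(max(0, n_steps - ck$step_done))) {
    engine_step(sys, E, opts)
    if (s %% sample_every == 0 && isample < totsamp) {
      isample <- isample + 1L
      blk <- 1L + (isample - 1L) %/% spb
      if (E$n > 0) {
        zs <- E$P[E$m + seq_len(E$n), 3]
        bins <- pmin(nbins, pmax(1L, 1L + (zs - edges[1]) %/% bin_width))
        for (ii in seq_len(E$n))
          hist[bins[ii], E$typ[ii], blk] <- hist[bins[ii], E$typ[ii], blk] + 1
        Nblock[blk, ] <- Nblock[blk, ] + E$Nt
        Nsq <- Nsq + as.numeric(E$Nt)^2
        rr2 <- E$P[E$m + seq_len(E$n), 1]^2 + E$P[E$m + seq_len(E$n), 2]^2
        inb <- rr2 <= r_in^2 & abs(zs) >= z_in_lo & abs(zs) <= z_in_hi
        if (any(inb)) bulk_in[blk, ] <- bulk_in[blk, ] + tabulate(E$typ[inb],
                                                                  n_types)
      }
      charge_sum <- charge_sum + sum(E$Q)
    }
    if (s %% check_every == 0) engine_check(sys, E)
  }
  engine_check(sys, E)
  structure(list(
    n_steps = n_steps, seed = NA, sample_every = sample_every,
    nsamples = isample, samples_per_block = spb, n_blocks = n_blocks,
    bin_edges = edges, bin_width = bin_width,
    hist = hist, Nblock = Nblock, Nsq = Nsq, bulk_in = bulk_in,
    bulk_region = list(r = r_in, z_lo = z_in_lo, z_hi = z_in_hi,
                       volume = V_bulk),
    acceptance = data.frame(kind = names(E$att), attempted = as.numeric(E$att),
                            accepted = as.numeric(E$acc)),
    step_size = E$step, consistency_max_rel_dev = E$max_dev,
    mean_total_charge = charge_sum / max(isample, 1),
    types = sys$types, geometry = geom, volume = sys$volume,
    sf_bias = sf_bias,
    final_state = engine_state(sys, E)),
    class = "csc_run")
}

#' Calibrate chemical potentials to target bulk concentrations
#'
#' Iteratively adjusts the per-species chemical potential offsets so that the
#' concentrations measured in the bulk sampling region of a (typically
#' bulk-only) cell match the configured targets within `tol`.  Within a
#' species, the fixed chemical-potential differences between hydration
#' states (log population-factor ratios) are preserved.
#'
#' @param sys a `csc_system`; its `types$mu` provide the starting guess
#'   (`ln rho_target`, exact for an ideal gas).
#' @param seed RNG seed; iteration i uses `seed + i`.
#' @param n_steps MC steps per calibration iteration.
#' @param tol relative concentration tolerance (default 2\%).
#' @param max_iter maximum iterations.
#' @param damp damping factor on the log-concentration updates; values
#'   below 1 suppress oscillation when the per-iteration measurement noise
#'   is comparable to `tol`.
#' @param ... further arguments to [csc_run()].
#' @return List with `types` (updated table), `mu` (named per-type vector),
#'   `mu_se` (propagated uncertainty), `history` (per-iteration data frame)
#'   and `run` (the final verification run).
#' @export
calibrate_mu <- function(sys, seed, n_steps = 40000, tol = 0.02,
                         max_iter = 12, damp = 0.7, ...) {
  ty <- sys$types
  history <- list()
  for (it in seq_len(max_iter)) {
    sys$types <- ty
    run <- csc_run(sys, n_steps = n_steps, seed = seed + it,
                   equil = max(2000, n_steps %/% 10), ...)
    meas <- measure_bulk_concentration(run)
    agg <- stats::aggregate(cbind(conc, se) ~ species, meas, sum)
    tgt <- stats::aggregate(conc_target ~ species, ty, sum)
    cmp <- merge(agg, tgt, by = "species")
    cmp$rel <- cmp$conc / cmp$conc_target - 1
    history[[it]] <- cbind(iter = it, cmp)
    if (all(abs(cmp$rel) <= tol)) {
      mu_se <- stats::setNames(rep(NA_real_, nrow(ty)), ty$type)
      for (sp in cmp$species)
        mu_se[ty$species == sp] <- cmp$se[cmp$species == sp] /
          max(cmp$conc[cmp$species == sp], 1e-300)
      return(list(types = ty, mu = stats::setNames(ty$mu, ty$type),
                  mu_se = mu_se,
                  history = do.call(rbind, history), run = run,
                  converged = TRUE))
    }
    for (sp in unique(ty$species)) {
      me <- cmp[cmp$species == sp, ]
      dmu <- if (me$conc <= 0) log(4) else
        damp * max(min(log(me$conc_target / me$conc), 1.5), -1.5)
      ty$mu[ty$species == sp] <- ty$mu[ty$species == sp] + dmu
    }
  }
  stop(paste0("chemical-potential calibration did not converge; trace:\n",
              paste(utils::capture.output(print(do.call(rbind, history))),
                    collapse = "\n")))
}
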