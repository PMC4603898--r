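# CSC Hamiltonian: H = U_C + U_IC + U_mob + U_cp + U_overlap.
#
# U_C    direct Coulomb energy of all charges (mobile ions + wall atoms) in
#        the uniform aqueous dielectric;
# U_IC   induced-surface-charge energy at the protein/water boundary;
# U_mob  harmonic localization of the wall atoms about their crystallographic
#        base positions;
# U_overlap  hard-body term, 0 or +Inf (overlap of any two spheres, or of a
#        sphere with the protein/membrane/cell wall);
# U_cp   the chemical-potential term of the grand-canonical ensemble.  Only
#        mu*N differences are observable in muVT sampling, so U_cp is
#        book-kept inside the Monte Carlo acceptance ratios, not in the
#        stored energy.

#' Particle-type table for a grand-canonical run
#'
#' One row per insertable particle type, i.e. per (species, hydration state)
#' pair plus counter-ion species.  Within a species, chemical potentials of
#' different hydration states differ by the log of the population-factor
#' ratio, so bulk equilibrium reproduces the configured populations by
#' construction; target per-state bulk concentrations are the species total
#' times `factor_x / sum(all factors)`.
#'
#' @param species_table a `csc_species_table` (or named list of
#'   `csc_species`).
#' @param include named list: for each simulated species, the integer vector
#'   of included hydration states (e.g. from [select_states()]).
#' @param concentrations named numeric vector of total bulk concentrations in
#'   mol/L per species.
#' @param anion list describing the hard-sphere counter-ion:
#'   `name, diameter (A), charge`; its concentration is set by
#'   electroneutrality unless given.
#' @return Data frame of class `csc_types` with columns `type, species, x,
#'   charge, radius, factor, conc_target, mu`.
#' @export
build_types <- function(species_table, include, concentrations,
                        anion = list(name = "Cl", diameter = 3.6,
                                     charge = -1)) {
  rows <- list()
  for (sp_name in names(include)) {
    sp <- species_table[[sp_name]]
    if (is.null(sp)) stop(sprintf("species '%s' not in table", sp_name))
    conc <- concentrations[[sp_name]]
    if (is.null(conc) || !is.finite(conc) || conc <= 0)
      stop(sprintf("missing bulk concentration for %s", sp_name))
    xs <- include[[sp_name]]
    st <- sp$states
    S <- sum(st$population_factor)
    for (x in xs) {
      i <- match(x, st$x)
      if (is.na(i)) stop(sprintf("%s has no state x=%d", sp_name, x))
      rows[[length(rows) + 1L]] <- data.frame(
        type = sprintf("%s.%d", sp_name, x), species = sp_name, x = x,
        charge = sp$valence, radius = st$gate_diameter[i] / 2,
        factor = st$population_factor[i],
        conc_target = conc * st$population_factor[i] / S,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(anion)) {
    # electroneutral counter-ion concentration from the species totals
    ca <- if (!is.null(anion$conc)) anion$conc else
      sum(vapply(names(include), function(s)
        concentrations[[s]] * species_table[[s]]$valence, numeric(1))) /
      abs(anion$charge)
    df <- rbind(df, data.frame(
      type = anion$name, species = anion$name, x = NA_integer_,
      charge = anion$charge, radius = anion$diameter / 2, factor = 1,
      conc_target = ca, stringsAsFactors = FALSE))
  }
  rho <- molar_to_density(df$conc_target)
  df$mu <- log(rho)
  class(df) <- c("csc_types", "data.frame")
  df
}

#' Assemble a simulation system
#'
#' Binds geometry, wall atoms, the particle-type table and (for channel
#' geometries) the induced-charge operator into the immutable context object
#' consumed by [csc_run()], [total_energy()] and [delta_energy()].
#'
#' @param geometry a `csc_geometry`.
#' @param types a `csc_types` table from [build_types()].
#' @param wall_atoms optional `csc_wall_atoms`.
#' @param icc optional `csc_icc` operator from [assemble_icc_operator()];
#'   omit for bulk cells or zero dielectric contrast.
#' @param eps_water aqueous relative permittivity for U_C.
#' @return Object of class `csc_system`.
#' @export
csc_system <- function(geometry, types, wall_atoms = NULL, icc = NULL,
                       eps_water = 80) {
  stopifnot(inherits(geometry, "csc_geometry"), inherits(types, "csc_types"))
  if (!is.null(wall_atoms) && geometry$type != "channel")
    stop("wall atoms require a channel geometry")
  structure(list(geometry = geometry, types = types,
                 wall = wall_atoms, icc = icc, eps_water = eps_water,
                 volume = pi * geometry$cell_radius^2 *
                   2 * geometry$cell_half_length),
            class = "csc_system")
}

#' @export
print.csc_system <- function(x, ...) {
  cat(sprintf("CSC system (%s cell, V = %.0f A^3)\n", x$geometry$type,
              x$volume))
  cat(sprintf("  %d particle types, %d wall atoms, ICC: %s\n",
              nrow(x$types), if (is.null(x$wall)) 0L else nrow(x$wall),
              if (is.null(x$icc)) "off" else
                sprintf("%d patches", x$icc$n_patches)))
  invisible(x)
}

#' Mobile-particle state
#'
#' @param pos n x 3 matrix of ion positions (Angstrom).
#' @param type integer row indices into the system's type table.
#' @param wall_pos m x 3 matrix of current wall-atom positions (defaults to
#'   the base positions).
#' @param sys the `csc_system` (used for defaults/validation).
#' @return List of class `csc_state`.
#' @export
csc_state <- function(sys, pos = matrix(numeric(0), 0, 3),
                      type = integer(0), wall_pos = NULL) {
  pos <- rbind(pos)
  if (is.null(wall_pos))
    wall_pos <- if (is.null(sys$wall)) matrix(numeric(0), 0, 3) else
      cbind(sys$wall$x, sys$wall$y, sys$wall$z)
  stopifnot(nrow(pos) == length(type))
  structure(list(pos = pos, type = as.integer(type), wall_pos = rbind(wall_pos)),
            class = "csc_state")
}

# All hard spheres (ions then wall atoms): positions, radii, charges.
state_bodies <- function(sys, state) {
  ty <- sys$types
  list(pos = rbind(state$pos, state$wall_pos),
       radius = c(ty$radius[state$type],
                  if (is.null(sys$wall)) numeric(0) else sys$wall$radius),
       charge = c(ty$charge[state$type],
                  if (is.null(sys$wall)) numeric(0) else sys$wall$charge))
}

# TRUE if any hard-body overlap or region violation exists.
any_overlap <- function(sys, state) {
  b <- state_bodies(sys, state)
  n <- nrow(b$pos)
  if (n == 0) return(FALSE)
  if (!all(in_aqueous_region(b$pos, b$radius, sys$geometry))) return(TRUE)
  if (n >= 2) {
    d <- as.matrix(stats::dist(b$pos))
    rs <- outer(b$radius, b$radius, "+")
    iu <- upper.tri(d)
    if (any(d[iu] < rs[iu] - 1e-12)) return(TRUE)
  }
  FALSE
}

#' Harmonic localization energy of the wall atoms (U_mob)
#'
#' `sum_a 0.5 k_a |r_a - r_base,a|^2`, in kT; zero when every atom sits at
#' its base position.
#'
#' @param wall_atoms a `csc_wall_atoms` data frame.
#' @param positions m x 3 matrix of current positions; defaults to base.
#' @return Energy in kT.
#' @export
mobility_energy <- function(wall_atoms, positions = NULL) {
  if (is.null(wall_atoms) || nrow(wall_atoms) == 0) return(0)
  if (is.null(positions)) return(0)
  dx <- positions[, 1] - wall_atoms$x
  dy <- positions[, 2] - wall_atoms$y
  dz <- positions[, 3] - wall_atoms$z
  sum(0.5 * wall_atoms$k * (dx^2 + dy^2 + dz^2))
}

#' Total configurational energy of a state
#'
#' `U_C + U_IC + U_mob`, with `+Inf` if any hard-body overlap or region
#' violation; the chemical-potential term enters only the grand-canonical
#' acceptance ratios.
#'
#' @param sys a `csc_system`.
#' @param state a `csc_state`.
#' @return List with `U` (total, kT) and components `U_C, U_IC, U_mob,
#'   overlap`.
#' @export
total_energy <- function(sys, state) {
  if (any_overlap(sys, state))
    return(list(U = Inf, U_C = NA_real_, U_IC = NA_real_, U_mob = NA_real_,
                overlap = TRUE))
  b <- state_bodies(sys, state)
  keep <- b$charge != 0
  U_C <- coulomb_energy(b$pos[keep, , drop = FALSE], b$charge[keep],
                        sys$eps_water)
  U_IC <- if (is.null(sys$icc)) 0 else
    induced_energy(sys$icc, b$pos[keep, , drop = FALSE], b$charge[keep])
  U_mob <- mobility_energy(sys$wall, state$wall_pos)
  if (!is.finite(U_C) || !is.finite(U_IC) || !is.finite(U_mob))
    stop("non-finite energy component in an overlap-free state")
  list(U = U_C + U_IC + U_mob, U_C = U_C, U_IC = U_IC, U_mob = U_mob,
       overlap = FALSE)
}

#' Apply a move to a state
#'
#' @param state a `csc_state`.
#' @param move a move list: `kind` one of `"displace"`, `"insert"`,
#'   `"delete"`, `"swap"`, `"displace_wall"`; `idx` particle (or wall-atom)
#'   index; `new_pos` for displacement/insertion; `type` for
#'   insertion; `new_type` for swaps.
#' @return The updated `csc_state`.
#' @export
apply_move <- function(state, move) {
  s <- state
  switch(move$kind,
         displace = { s$pos[move$idx, ] <- move$new_pos },
         displace_wall = { s$wall_pos[move$idx, ] <- move$new_pos },
         insert = {
           s$pos <- rbind(s$pos, move$new_pos)
           s$type <- c(s$type, move$type)
         },
         delete = {
           s$pos <- s$pos[-move$idx, , drop = FALSE]
           s$type <- s$type[-move$idx]
         },
         swap = { s$type[move$idx] <- move$new_type },
         stop("unknown move kind"))
  s
}

#' Energy difference of a proposed move
#'
#' `Delta H = H(after) - H(before)`, computed incrementally (single-particle
#' Coulomb sums; full re-solve of the induced-charge energy with the cached
#' operator), with early exit to `+Inf` on any hard overlap or region
#' violation of the moved body.
#'
#' @inheritParams total_energy
#' @param move a move list (see [apply_move()]).
#' @param U_IC_before optionally the cached induced-charge energy of `state`,
#'   to avoid one re-solve.
#' @return Energy difference in kT (possibly `+Inf`).
#' @export
delta_energy <- function(sys, state, move, U_IC_before = NULL) {
  b <- state_bodies(sys, state)
  n_ion <- nrow(state$pos)
  eps <- sys$eps_water
  # identify moved/inserted body, new position, radius, charge
  if (move$kind == "swap") {
    new_r <- sys$types$radius[move$new_type]
    p <- state$pos[move$idx, ]
    others <- setdiff(seq_along(b$radius), move$idx)
    if (!in_aqueous_region(p, new_r, sys$geometry)) return(Inf)
    if (length(others)) {
      d <- sqrt(colSums((t(b$pos[others, , drop = FALSE]) - p)^2))
      if (any(d < b$radius[others] + new_r - 1e-12)) return(Inf)
    }
    return(0)  # same charge, same position: only the hard core changes
  }
  if (move$kind == "delete") {
    i <- move$idx
    others <- setdiff(seq_len(nrow(b$pos)), i)
    dU_C <- -coulomb_one(b$pos[i, ], b$charge[i],
                         b$pos[others, , drop = FALSE], b$charge[others], eps)
    dU_IC <- delta_uic(sys, b, state, move, U_IC_before)
    return(dU_C + dU_IC)
  }
  # displace / displace_wall / insert
  if (move$kind == "insert") {
    qi <- sys$types$charge[move$type]
    ri <- sys$types$radius[move$type]
    others <- seq_len(nrow(b$pos))
    u_old <- 0
    mob <- 0
  } else if (move$kind == "displace") {
    i <- move$idx
    qi <- b$charge[i]; ri <- b$radius[i]
    others <- setdiff(seq_len(nrow(b$pos)), i)
    u_old <- coulomb_one(b$pos[i, ], qi, b$pos[others, , drop = FALSE],
                         b$charge[others], eps)
    mob <- 0
  } else { # displace_wall
    i <- n_ion + move$idx
    qi <- b$charge[i]; ri <- b$radius[i]
    others <- setdiff(seq_len(nrow(b$pos)), i)
    u_old <- coulomb_one(b$pos[i, ], qi, b$pos[others, , drop = FALSE],
                         b$charge[others], eps)
    wa <- sys$wall[move$idx, ]
    mob <- 0.5 * wa$k * (sum((move$new_pos - c(wa$x, wa$y, wa$z))^2) -
                           sum((state$wall_pos[move$idx, ] -
                                  c(wa$x, wa$y, wa$z))^2))
  }
  p <- move$new_pos
  if (!in_aqueous_region(p, ri, sys$geometry)) return(Inf)
  if (length(others)) {
    d2 <- colSums((t(b$pos[others, , drop = FALSE]) - p)^2)
    rs <- b$radius[others] + ri
    if (any(d2 < rs^2 - 1e-12)) return(Inf)
    u_new <- coulomb_one(p, qi, b$pos[others, , drop = FALSE],
                         b$charge[others], eps)
  } else u_new <- 0
  dU_C <- u_new - u_old
  dU_IC <- delta_uic(sys, b, state, move, U_IC_before)
  dU_C + dU_IC + mob
}

# Induced-charge energy difference by full re-solve (operator factorization
# is cached in the system).
delta_uic <- function(sys, b, state, move, U_IC_before = NULL) {
  if (is.null(sys$icc)) return(0)
  keep <- b$charge != 0
  if (is.null(U_IC_before))
    U_IC_before <- induced_energy(sys$icc, b$pos[keep, , drop = FALSE],
                                  b$charge[keep])
  after <- apply_move(state, move)
  b2 <- state_bodies(sys, after)
  keep2 <- b2$charge != 0
  U_IC_after <- induced_energy(sys$icc, b2$pos[keep2, , drop = FALSE],
                               b2$charge[keep2])
  U_IC_after - U_IC_before
}
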