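# Structure ingestion: PDB -> pore-wall atom definitions, B-factor ->
# harmonic tether constants, and the synthetic toy-channel generator used
# throughout the tests.

#' Convert a crystallographic B-factor to a harmonic spring constant
#'
#' Isotropic conversion: the per-axis mean-square displacement is
#' `<u^2> = B / (8 pi^2)`, so the per-axis harmonic constant that reproduces
#' it at temperature T is `k = kT / <u^2>`, i.e. `8 pi^2 / B` in kT/Angstrom^2
#' units.
#'
#' @param B B-factor(s) in Angstrom^2; must be positive.
#' @return Spring constant(s) in kT/Angstrom^2.
#' @export
#' @examples
#' bfactor_to_spring(8 * pi^2)  # 1 kT/A^2
bfactor_to_spring <- function(B) {
  if (any(!is.finite(B) | B <= 0)) stop("B-factors must be positive")
  8 * pi^2 / B
}

#' @rdname bfactor_to_spring
#' @param k spring constant(s) in kT/Angstrom^2.
#' @export
spring_to_bfactor <- function(k) {
  if (any(!is.finite(k) | k <= 0)) stop("spring constants must be positive")
  8 * pi^2 / k
}

#' Read selectivity-filter atoms from a PDB structure
#'
#' Ingests the pore-lining atoms named by `selection` from a PDB file,
#' recentres them so the pore axis is z (xy mean at the origin) and the SF
#' midpoint is z = 0, attaches charges by role (carbonyl oxygen -0.1 e,
#' carboxylate oxygen -1 e) and converts B-factors to spring constants.
#' A carboxylate selector matching the two carboxyl oxygens is reduced to the
#' single oxygen nearest the pore wall (largest radial distance from the
#' axis).
#'
#' @param pdb_file path to a PDB-format file (parsed with \pkg{bio3d}).
#' @param selection list of selectors, each a list with elements `chain`,
#'   `resno`, `elety` (atom name(s)) and `role` (`"carbonyl_O"` or
#'   `"carboxylate_O"`).
#' @param symmetry rotational replication count about z applied after
#'   recentring (e.g. 4 when the selection covers one subunit of a four-fold
#'   channel); 1 means no replication.
#' @param hard_radius hard-sphere radius assigned to the atoms (Angstrom).
#' @return A `csc_wall_atoms` data frame.
#' @export
read_sf_atoms <- function(pdb_file, selection, symmetry = 1,
                          hard_radius = 1.4) {
  pdb <- bio3d::read.pdb(pdb_file)
  at <- pdb$atom
  picked <- list()
  for (sel in selection) {
    role <- match.arg(sel$role, c("carbonyl_O", "carboxylate_O"))
    keep <- rep(TRUE, nrow(at))
    if (!is.null(sel$chain)) keep <- keep & at$chain %in% sel$chain
    if (!is.null(sel$resno)) keep <- keep & at$resno %in% sel$resno
    if (!is.null(sel$elety)) keep <- keep & at$elety %in% sel$elety
    hit <- at[keep, , drop = FALSE]
    n_expect <- if (role == "carboxylate_O") 2L else 1L
    if (nrow(hit) != n_expect)
      stop(sprintf(
        "selector (chain %s, resno %s, elety %s) resolved to %d atoms, expected %d",
        paste(sel$chain, collapse = "/"), paste(sel$resno, collapse = "/"),
        paste(sel$elety, collapse = "/"), nrow(hit), n_expect))
    if (any(is.na(hit$b)) || any(hit$b <= 0))
      stop(sprintf("missing or non-positive B-factor for selector (resno %s)",
                   paste(sel$resno, collapse = "/")))
    hit$role <- role
    picked[[length(picked) + 1L]] <- hit
  }
  all_at <- do.call(rbind, picked)
  # recentre: pore axis -> z through the xy centroid, SF midpoint -> z = 0
  ctr <- c(mean(all_at$x), mean(all_at$y), mean(all_at$z))
  all_at$x <- all_at$x - ctr[1]
  all_at$y <- all_at$y - ctr[2]
  all_at$z <- all_at$z - ctr[3]
  # reduce each carboxylate pair to the oxygen nearest the pore wall
  out <- list()
  i <- 1L
  while (i <= nrow(all_at)) {
    if (all_at$role[i] == "carboxylate_O") {
      pair <- all_at[i + 0:1, ]
      rad <- sqrt(pair$x^2 + pair$y^2)
      out[[length(out) + 1L]] <- pair[which.max(rad), ]
      i <- i + 2L
    } else {
      out[[length(out) + 1L]] <- all_at[i, ]
      i <- i + 1L
    }
  }
  red <- do.call(rbind, out)
  charge <- ifelse(red$role == "carboxylate_O", -1.0, -0.1)
  base <- cbind(red$x, red$y, red$z)
  label <- sprintf("%s%d_%s", red$resid, red$resno, red$elety)
  if (symmetry > 1) {
    rot <- function(m, ang) cbind(m[, 1] * cos(ang) - m[, 2] * sin(ang),
                                  m[, 1] * sin(ang) + m[, 2] * cos(ang),
                                  m[, 3])
    bases <- lapply(seq_len(symmetry) - 1L,
                    function(s) rot(base, 2 * pi * s / symmetry))
    base <- do.call(rbind, bases)
    label <- as.vector(vapply(seq_len(symmetry) - 1L,
                              function(s) paste0(label, ".", s + 1L),
                              character(length(label))))
    charge <- rep(charge, symmetry)
    red <- red[rep(seq_len(nrow(red)), symmetry), ]
  }
  pore_wall_atoms(label, base, hard_radius, charge, bfactor_to_spring(red$b))
}

#' Write a minimal PDB file for a wall-atom set
#'
#' Fixture generator: writes the base positions, roles and B-factors of a
#' `csc_wall_atoms` table (plus role metadata) as a standard PDB file via
#' \pkg{bio3d}, so the ingestion path can be exercised round-trip on purely
#' synthetic structures.
#'
#' @param wall a `csc_wall_atoms` data frame.
#' @param file output path.
#' @param resid residue name to write (default GLY for carbonyl-like atoms).
#' @param bfactor B-factors to write; default derived from the spring
#'   constants.
#' @return `file`, invisibly.
#' @export
write_toy_pdb <- function(wall, file, resid = "GLY",
                          bfactor = spring_to_bfactor(wall$k)) {
  n <- nrow(wall)
  xyz <- as.vector(t(cbind(wall$x, wall$y, wall$z)))
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = seq_len(n), resid = rep(resid, n),
                   chain = rep("A", n),
                   elety = rep("O", n),
                   b = round(rep_len(bfactor, n), 2))
  invisible(file)
}

toy_presets <- function() {
  list(
    # KcsA-like: carbonyl-lined narrow pore, only dehydrated cations fit
    "neutral-pore" = list(
      rings = list(
        list(z = -3.0, rho = 2.95, n = 4, radius = 1.4, charge = -0.1, B = 20),
        list(z = 0.0, rho = 2.95, n = 4, radius = 1.4, charge = -0.1, B = 20),
        list(z = 3.0, rho = 2.95, n = 4, radius = 1.4, charge = -0.1, B = 20)),
      cell = list(cell_radius = 12, cell_half_length = 22,
                  sf_half_length = 5, arc_radius = 5)),
    # NavAb-like: EEEE carboxylate ring gating the pore at 5.6 A, lining
    # carbonyls set slightly wider so the high-field locus alone controls
    # the bottleneck; admits partially hydrated Na+ (x = 4) but not K+ at
    # x = 4
    "charged-pore" = list(
      rings = list(
        list(z = 1.5, rho = 4.2, n = 4, radius = 1.4, charge = -1, B = 30,
             offset = pi / 4),
        list(z = -1.5, rho = 5.2, n = 4, radius = 1.4, charge = -0.1, B = 20),
        list(z = -4.0, rho = 5.2, n = 4, radius = 1.4, charge = -0.1, B = 20,
             offset = pi / 4)),
      cell = list(cell_radius = 13, cell_half_length = 22,
                  sf_half_length = 5, arc_radius = 5)),
    # CavAb-like: charged ring in a pore wide enough for fully hydrated
    # ions; the charged site sits in the upper (extracellular) half so the
    # rate-determining barrier below it stays sterically accessible
    "wide-pore" = list(
      rings = list(
        list(z = 2.5, rho = 6.0, n = 4, radius = 1.4, charge = -1, B = 30,
             offset = pi / 4),
        list(z = 0, rho = 6.0, n = 4, radius = 1.4, charge = -0.1, B = 20),
        list(z = 5.0, rho = 6.0, n = 4, radius = 1.4, charge = -0.1, B = 20)),
      cell = list(cell_radius = 15, cell_half_length = 24,
                  sf_half_length = 6.5, arc_radius = 5)))
}

#' Generate a synthetic toy channel
#'
#' Builds a complete runnable channel definition (geometry plus wall atoms)
#' from ring specifications, or from one of the named presets:
#' `"neutral-pore"` (carbonyl-only narrow pore), `"charged-pore"` (four-fold
#' carboxylate ring over carbonyl rings) and `"wide-pore"` (charged ring, no
#' dehydration needed).  The SF boundary-cylinder radius follows the sizing
#' rule: maximal radial wall-atom extent plus hard radius plus a 0.1 Angstrom
#' margin.
#'
#' @param spec preset name, or a list with elements `rings` (each a list
#'   `z, rho, n, radius, charge, B`, optionally `offset` for the azimuthal
#'   phase) and `cell` (`cell_radius, cell_half_length, sf_half_length,
#'   arc_radius`).
#' @return List of class `csc_toy_channel` with elements `geometry`,
#'   `wall_atoms`, `sf_min_diameter` and `config`.
#' @export
build_toy_channel <- function(spec = "charged-pore") {
  if (is.character(spec)) {
    presets <- toy_presets()
    if (!spec %in% names(presets))
      stop(sprintf("unknown preset '%s' (have: %s)", spec,
                   paste(names(presets), collapse = ", ")))
    name <- spec
    spec <- presets[[spec]]
  } else name <- "custom"
  atoms <- list()
  for (rg in spec$rings) {
    ang <- 2 * pi * (seq_len(rg$n) - 1) / rg$n +
      (if (is.null(rg$offset)) 0 else rg$offset)
    atoms[[length(atoms) + 1L]] <- data.frame(
      label = sprintf("ring_z%+.1f_%d", rg$z, seq_len(rg$n)),
      x = rg$rho * cos(ang), y = rg$rho * sin(ang), z = rg$z,
      radius = rg$radius, charge = rg$charge,
      k = bfactor_to_spring(rg$B), stringsAsFactors = FALSE)
  }
  wa <- do.call(rbind, atoms)
  wall <- pore_wall_atoms(wa$label, cbind(wa$x, wa$y, wa$z), wa$radius,
                          wa$charge, wa$k)
  rad_ext <- max(sqrt(wall$x^2 + wall$y^2) + wall$radius)
  geom <- csc_geometry(cell_radius = spec$cell$cell_radius,
                       cell_half_length = spec$cell$cell_half_length,
                       sf_radius = rad_ext + 0.1,
                       sf_half_length = spec$cell$sf_half_length,
                       arc_radius = spec$cell$arc_radius)
  if (max(abs(wall$z)) > geom$sf_half_length)
    stop("wall atoms extend beyond the SF boundary cylinder")
  if (!all(in_aqueous_region(cbind(wall$x, wall$y, wall$z),
                             0, geom)))
    stop("wall-atom base positions must lie inside the aqueous SF pore")
  dd <- as.matrix(stats::dist(cbind(wall$x, wall$y, wall$z)))
  rs <- outer(wall$radius, wall$radius, "+")
  if (any(dd[upper.tri(dd)] < rs[upper.tri(rs)] - 1e-9))
    stop("wall-atom base positions overlap as hard spheres")
  structure(list(name = name,
                 geometry = geom, wall_atoms = wall,
                 sf_min_diameter = sf_min_accessible_diameter(geom, wall),
                 config = list(preset = name, rings = spec$rings,
                               cell = spec$cell)),
            class = "csc_toy_channel")
}

#' @export
print.csc_toy_channel <- function(x, ...) {
  cat(sprintf("Toy channel '%s': %d wall atoms, net wall charge %+.1f e\n",
              x$name, nrow(x$wall_atoms), sum(x$wall_atoms$charge)))
  cat(sprintf("  SF bottleneck diameter: %.2f A\n", x$sf_min_diameter))
  print(x$geometry)
  invisible(x)
}
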