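# Electrostatics: direct Coulomb energy in a uniform aqueous dielectric (U_C)
# and the induced-surface-charge energy at the sharp protein/water dielectric
# boundary (U_IC), solved by boundary-element collocation ("induced charge
# computation", ICC).
#
# All free charges reside in the eps_water region; the dielectric contrast
# enters only through U_IC.  The polarization surface charge density h on the
# boundary satisfies, at each collocation point s_j (normal n_j pointing from
# protein into water),
#
#   h_j = chi * [ sum_i (q_i/eps_w) n_j.(s_j - r_i)/|s_j - r_i|^3
#                 + sum_{k != j} h_k a_k n_j.(s_j - s_k)/|s_j - s_k|^3 ],
#   chi = (eps_p - eps_w) / (2 pi (eps_w + eps_p)),
#
# i.e. (I - chi G) h = chi b with the flat-patch self term omitted.  The
# induced energy is U_IC = (1/2) sum_i q_i phi_ind(r_i) with
# phi_ind(r) = sum_j h_j a_j / |r - s_j| (times the kT Coulomb prefactor).

#' Coulomb energy of a set of point charges in a uniform dielectric
#'
#' Pairwise-additive Coulomb energy, in kT at 298.15 K, of charges embedded in
#' a uniform medium of relative permittivity `eps_water`.
#'
#' @param pos n x 3 matrix of positions (Angstrom).
#' @param q vector of charges (elementary charges).
#' @param eps_water relative permittivity (default 80).
#' @return Energy in kT.
#' @export
coulomb_energy <- function(pos, q, eps_water = 80) {
  pos <- rbind(pos)
  n <- nrow(pos)
  stopifnot(length(q) == n, eps_water > 0)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(pos))
  iu <- upper.tri(d)
  if (any(d[iu] < 1e-9))
    stop("coincident charges: hard-sphere overlap should have prevented this")
  (.csc_coulomb_kT / eps_water) * sum((tcrossprod(q))[iu] / d[iu])
}

# Coulomb energy of one charge (at `p`, charge `qi`) with a set of others.
coulomb_one <- function(p, qi, pos, q, eps_water = 80) {
  if (length(q) == 0 || qi == 0) return(0)
  d2 <- (pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2 + (pos[, 3] - p[3])^2
  (.csc_coulomb_kT / eps_water) * qi * sum(q / sqrt(d2))
}

new_csc_mesh <- function(df, eps_water, eps_protein, surface_area) {
  nn <- sqrt(df$nx^2 + df$ny^2 + df$nz^2)
  if (any(df$area <= 0)) stop("mesh patch areas must be positive")
  if (any(abs(nn - 1) > 1e-8)) stop("mesh normals must be unit vectors")
  if (abs(sum(df$area) - surface_area) > 0.01 * surface_area)
    stop("mesh area does not tile the boundary surface (total area off by >1%)")
  structure(df, eps_water = eps_water, eps_protein = eps_protein,
            surface_area = surface_area,
            class = c("csc_mesh", "data.frame"))
}

#' @export
print.csc_mesh <- function(x, ...) {
  cat(sprintf("Boundary mesh: %d patches, total area %.2f A^2, eps %g/%g\n",
              nrow(x), sum(x$area), attr(x, "eps_water"),
              attr(x, "eps_protein")))
  invisible(x)
}

# Graded radial ring edges from r0 outward: rings start at half the nominal
# patch scale and grow geometrically, but are capped at a fraction of the
# local radius.  Far rings must stay small relative to the decay scale of
# the induced charge: centroid quadrature on wide outer rings otherwise
# leaves a systematic energy bias.
graded_edges <- function(r0, r1, w, g = 1.35, cap = 0.12) {
  wcur <- w / 2
  e <- r0
  repeat {
    rho <- e[length(e)]
    if (rho >= r1 - 1e-9) break
    wk <- min(wcur, max(cap * rho, w / 2))
    e <- c(e, min(rho + wk, r1))
    wcur <- wcur * g
  }
  e
}

#' Discretize the protein dielectric boundary into patches
#'
#' Tiles the flattened-toroid boundary surface (SF cylinder, joining arcs and
#' flat membrane faces out to the cell wall) with quadrilateral patches for
#' the induced-charge solver.  Patch areas are exact band areas of the surface
#' of revolution, so the mesh area matches the analytic surface area; the
#' tiling is fine near the SF and coarsens (geometrically) towards the cell
#' wall.
#'
#' @param geometry a channel `csc_geometry`.
#' @param patch_scale characteristic patch edge length (Angstrom) near the SF.
#' @param n_theta number of azimuthal divisions; by default scaled so the
#'   azimuthal patch edge on the SF cylinder is about `patch_scale`.
#' @param eps_water,eps_protein relative permittivities of the two media.
#' @param grade geometric growth factor of radial patch widths on the faces.
#' @return A `csc_mesh` data frame with columns
#'   `cx, cy, cz, nx, ny, nz, area`.
#' @export
build_mesh <- function(geometry, patch_scale, n_theta = NULL,
                       eps_water = 80, eps_protein = 10, grade = 1.35) {
  stopifnot(geometry$type == "channel", patch_scale > 0)
  if (is.null(n_theta))
    n_theta <- min(64L, max(12L, ceiling(2 * pi * geometry$sf_radius /
                                           patch_scale)))
  stopifnot(n_theta >= 8)
  L <- geometry$sf_half_length
  H <- geometry$membrane_half
  Ra <- geometry$arc_radius
  Rsf <- geometry$sf_radius
  Rc <- Rsf + Ra
  Rcell <- geometry$cell_radius
  th_e <- seq(0, 2 * pi, length.out = n_theta + 1)
  th_c <- (th_e[-1] + th_e[-length(th_e)]) / 2
  dth <- 2 * pi / n_theta

  rows <- list()
  add_band <- function(rc, zc, nr, nz_, band_area) {
    # one band of n_theta patches: rc = centroid radius, (nr, nz_) meridian
    # normal components, band_area = exact area of the full band
    rows[[length(rows) + 1L]] <<- data.frame(
      cx = rc * cos(th_c), cy = rc * sin(th_c), cz = zc,
      nx = nr * cos(th_c), ny = nr * sin(th_c), nz = nz_,
      area = band_area / n_theta)
  }

  # SF cylinder
  nzc <- max(2L, ceiling(2 * L / patch_scale))
  ze <- seq(-L, L, length.out = nzc + 1)
  for (i in seq_len(nzc)) {
    zc <- (ze[i] + ze[i + 1]) / 2
    add_band(Rsf, zc, -1, 0, Rsf * (ze[i + 1] - ze[i]) * 2 * pi)
  }
  # toroid arcs (upper t in [pi/2, pi]; lower mirrored)
  nt <- max(3L, ceiling(Ra * (pi / 2) / patch_scale))
  te <- seq(pi / 2, pi, length.out = nt + 1)
  for (i in seq_len(nt)) {
    tm <- (te[i] + te[i + 1]) / 2
    dt <- te[i + 1] - te[i]
    band <- 2 * pi * Ra * (Rc * dt + Ra * (sin(te[i + 1]) - sin(te[i])))
    rc <- Rc + Ra * cos(tm)
    zup <- L + Ra * sin(tm)
    add_band(rc, zup, cos(tm), sin(tm), band)        # upper arc
    add_band(rc, -zup, cos(tm), -sin(tm), band)      # lower arc
  }
  # flat membrane faces
  re <- graded_edges(Rc, Rcell, patch_scale, grade)
  for (i in seq_len(length(re) - 1)) {
    a <- re[i]; b <- re[i + 1]
    band <- pi * (b^2 - a^2)
    rc <- (2 / 3) * (b^3 - a^3) / (b^2 - a^2)        # area centroid radius
    add_band(rc, H, 0, 1, band)
    add_band(rc, -H, 0, -1, band)
  }
  df <- do.call(rbind, rows)
  # analytic surface area of the configured surface of revolution
  area_exact <- 2 * pi * Rsf * 2 * L +
    2 * (2 * pi * Ra * (Rc * pi / 2 - Ra)) +
    2 * pi * (Rcell^2 - Rc^2)
  new_csc_mesh(df, eps_water, eps_protein, area_exact)
}

#' Planar-interface test mesh
#'
#' Disk mesh of a flat dielectric interface at z = 0 (water above, protein
#' below), graded finely near the origin.  This test geometry exists to
#' validate the induced-charge solver against the closed-form image-charge
#' energy of a point charge above a dielectric half-space.
#'
#' @param r_max disk radius (Angstrom).
#' @param patch_scale patch edge length near the centre (Angstrom).
#' @param n_theta azimuthal divisions.
#' @param eps_water,eps_protein relative permittivities.
#' @param grade radial growth factor.
#' @return A `csc_mesh`.
#' @export
build_plane_mesh <- function(r_max, patch_scale, n_theta = 24,
                             eps_water = 80, eps_protein = 10, grade = 1.3) {
  stopifnot(r_max > 0, patch_scale > 0)
  th_e <- seq(0, 2 * pi, length.out = n_theta + 1)
  th_c <- (th_e[-1] + th_e[-length(th_e)]) / 2
  re <- graded_edges(0, r_max, patch_scale, grade)
  rows <- list()
  for (i in seq_len(length(re) - 1)) {
    a <- re[i]; b <- re[i + 1]
    band <- pi * (b^2 - a^2)
    rc <- (2 / 3) * (b^3 - a^3) / (b^2 - a^2)
    rows[[length(rows) + 1L]] <- data.frame(
      cx = rc * cos(th_c), cy = rc * sin(th_c), cz = 0,
      nx = 0, ny = 0, nz = 1, area = band / n_theta)
  }
  df <- do.call(rbind, rows)
  new_csc_mesh(df, eps_water, eps_protein, pi * r_max^2)
}

#' Assemble the induced-charge collocation operator
#'
#' Builds and factorizes (dense inverse) the patch-patch influence matrix of
#' the boundary-element induced-charge method.  The factorization depends on
#' geometry and permittivities only, so it is assembled once per run and
#' reused for every Monte Carlo move.
#'
#' @param mesh a `csc_mesh`.
#' @return An object of class `csc_icc` holding the mesh arrays, the contrast
#'   factor `chi` and the inverse influence matrix.
#' @export
assemble_icc_operator <- function(mesh) {
  stopifnot(inherits(mesh, "csc_mesh"))
  eps_w <- attr(mesh, "eps_water")
  eps_p <- attr(mesh, "eps_protein")
  s <- cbind(mesh$cx, mesh$cy, mesh$cz)
  nrm <- cbind(mesh$nx, mesh$ny, mesh$nz)
  a <- mesh$area
  np <- nrow(s)
  chi <- (eps_p - eps_w) / (2 * pi * (eps_w + eps_p))
  dx <- outer(s[, 1], s[, 1], "-")
  dy <- outer(s[, 2], s[, 2], "-")
  dz <- outer(s[, 3], s[, 3], "-")
  r2 <- dx^2 + dy^2 + dz^2
  diag(r2) <- Inf
  r3 <- r2^1.5
  G <- (nrm[, 1] * dx + nrm[, 2] * dy + nrm[, 3] * dz) / r3
  G <- sweep(G, 2, a, "*")
  M <- diag(np) - chi * G
  Minv <- tryCatch(solve(M), error = function(e) {
    dg <- order(abs(diag(M)))[seq_len(min(5, np))]
    stop(sprintf("singular ICC influence matrix (degenerate patches: %s)",
                 paste(dg, collapse = ", ")))
  })
  structure(list(s = s, nrm = nrm, area = a, chi = chi,
                 eps_water = eps_w, eps_protein = eps_p,
                 M = M, Minv = Minv, n_patches = np),
            class = "csc_icc")
}

#' @export
print.csc_icc <- function(x, ...) {
  cat(sprintf("ICC operator: %d patches, eps %g/%g, chi = %.5f\n",
              x$n_patches, x$eps_water, x$eps_protein, x$chi))
  invisible(x)
}

# Normal-field coupling of one charge position to all patches:
# w_j = n_j.(s_j - r)/|s_j - r|^3
icc_field_vec <- function(op, p) {
  dx <- op$s[, 1] - p[1]; dy <- op$s[, 2] - p[2]; dz <- op$s[, 3] - p[3]
  r3 <- (dx^2 + dy^2 + dz^2)^1.5
  (op$nrm[, 1] * dx + op$nrm[, 2] * dy + op$nrm[, 3] * dz) / r3
}

# Area-weighted inverse-distance vector: v_j = a_j/|s_j - r|
icc_pot_vec <- function(op, p) {
  dx <- op$s[, 1] - p[1]; dy <- op$s[, 2] - p[2]; dz <- op$s[, 3] - p[3]
  op$area / sqrt(dx^2 + dy^2 + dz^2)
}

# Raw field sum b0_j = sum_i q_i w_j(r_i) and potential sum
# t_j = a_j sum_i q_i/|r_i - s_j| for a charge set.
icc_sums <- function(op, pos, q) {
  b0 <- numeric(op$n_patches)
  tv <- numeric(op$n_patches)
  for (i in seq_along(q)) {
    if (q[i] == 0) next
    b0 <- b0 + q[i] * icc_field_vec(op, pos[i, ])
    tv <- tv + q[i] * icc_pot_vec(op, pos[i, ])
  }
  list(b0 = b0, t = tv)
}

#' Induced surface-charge density for a set of source charges
#'
#' @param operator a `csc_icc` operator.
#' @param pos n x 3 matrix of source positions (Angstrom).
#' @param q source charges (elementary charges).
#' @return Per-patch induced surface charge density (e/Angstrom^2).
#' @export
induced_charge_density <- function(operator, pos, q) {
  pos <- rbind(pos)
  b <- (operator$chi / operator$eps_water) * icc_sums(operator, pos, q)$b0
  drop(operator$Minv %*% b)
}

#' Induced-surface-charge energy U_IC
#'
#' Solves for the polarization charge on the dielectric boundary induced by
#' the given source charges and returns the interaction energy
#' (1/2) sum_i q_i phi_induced(r_i) in kT.  Positive for a charge approaching
#' the low-permittivity protein region.
#'
#' @inheritParams induced_charge_density
#' @param tol residual tolerance for the linear solve check.
#' @return Energy in kT.
#' @export
induced_energy <- function(operator, pos, q, tol = 1e-8) {
  pos <- rbind(pos)
  if (length(q) == 0 || all(q == 0) || operator$chi == 0) return(0)
  sums <- icc_sums(operator, pos, q)
  b <- (operator$chi / operator$eps_water) * sums$b0
  h <- drop(operator$Minv %*% b)
  res <- max(abs(drop(operator$M %*% h) - b))
  if (!all(is.finite(h)) || res > tol * max(max(abs(b)), 1e-12))
    stop(sprintf("ICC solve residual above tolerance: %g", res))
  0.5 * .csc_coulomb_kT * sum(sums$t * h)
}

#' Closed-form image-charge energy at a planar dielectric interface
#'
#' Energy, in kT, of a point charge at height `d` above an infinite planar
#' interface between water (`eps_water`, containing the charge) and protein
#' (`eps_protein`).  Used as the analytic oracle for the ICC solver.
#'
#' @param q charge (elementary charges).
#' @param d distance from the interface (Angstrom).
#' @param eps_water,eps_protein relative permittivities.
#' @return Energy in kT (positive when `eps_protein < eps_water`).
#' @export
planar_image_energy <- function(q, d, eps_water = 80, eps_protein = 10) {
  stopifnot(d > 0)
  f <- (eps_water - eps_protein) / (eps_water + eps_protein)
  .csc_coulomb_kT * q^2 * f / (4 * d * eps_water)
}
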