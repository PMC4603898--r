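# Simulation-cell geometry: cylindrical cell, virtual membrane, and the
# flattened-toroid dielectric boundary around the selectivity filter (SF).
#
# Axis convention: the pore/rotation axis is z, the extracellular side is
# z > 0, the virtual membrane sits at z = 0 and splits the cell into two
# equal halves connected only through the SF pore.
#
# The solid (protein + membrane) region is the surface of revolution
#   r >= r_wall(|z|),  |z| <= H
# where H = sf_half_length + arc_radius is the membrane half-thickness,
# r_wall = sf_radius inside the SF (|z| <= sf_half_length) and follows a
# circular arc of radius arc_radius out to the flat membrane faces.

#' Channel simulation-cell geometry
#'
#' Constructs the cylindrical simulation cell with an embedded flattened-toroid
#' protein region.  The toroid surface is the dielectric boundary between the
#' aqueous medium and the protein; its narrow central section is a cylinder of
#' radius `sf_radius` and half-length `sf_half_length` that encloses the
#' selectivity filter.  Circular arcs of radius `arc_radius` join the SF
#' cylinder smoothly to the flat membrane faces at `|z| = sf_half_length +
#' arc_radius`.
#'
#' @param cell_radius radius of the outer cylindrical cell wall (Angstrom).
#' @param cell_half_length half-length of the cell along z (Angstrom).
#' @param sf_radius radius of the SF boundary cylinder (Angstrom).
#' @param sf_half_length half-length of the SF boundary cylinder (Angstrom).
#' @param arc_radius radius of the circular arcs joining the SF cylinder to the
#'   membrane faces (Angstrom).  The exact value has little influence on
#'   selectivity; it is exposed for sensitivity checks.
#' @return An object of class `csc_geometry`.
#' @export
csc_geometry <- function(cell_radius, cell_half_length,
                         sf_radius, sf_half_length, arc_radius = 5) {
  vals <- c(cell_radius, cell_half_length, sf_radius, sf_half_length,
            arc_radius)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all geometry lengths must be finite and positive")
  membrane_half <- sf_half_length + arc_radius
  if (sf_radius >= cell_radius)
    stop("sf_radius must be smaller than cell_radius")
  if (membrane_half >= cell_half_length)
    stop("membrane (sf_half_length + arc_radius) must fit inside the cell")
  if (sf_radius + arc_radius >= cell_radius)
    stop("toroid arc must close before the outer cell wall")
  structure(list(type = "channel",
                 cell_radius = cell_radius,
                 cell_half_length = cell_half_length,
                 sf_radius = sf_radius,
                 sf_half_length = sf_half_length,
                 arc_radius = arc_radius,
                 membrane_half = membrane_half),
            class = "csc_geometry")
}

#' Bulk-only simulation cell
#'
#' A plain cylindrical cell with no membrane and no protein: used for chemical
#' potential calibration and bulk-equilibrium checks.
#'
#' @param radius,half_length cylinder dimensions (Angstrom).
#' @return An object of class `csc_geometry` with `type = "bulk"`.
#' @export
csc_bulk_cell <- function(radius, half_length) {
  stopifnot(is.finite(radius), radius > 0,
            is.finite(half_length), half_length > 0)
  structure(list(type = "bulk",
                 cell_radius = radius,
                 cell_half_length = half_length),
            class = "csc_geometry")
}

#' @export
print.csc_geometry <- function(x, ...) {
  if (x$type == "bulk") {
    cat(sprintf("Bulk cylindrical cell: radius %.2f A, half-length %.2f A\n",
                x$cell_radius, x$cell_half_length))
  } else {
    cat("Channel simulation cell (lengths in Angstrom)\n")
    cat(sprintf("  outer cell:      radius %.2f, half-length %.2f\n",
                x$cell_radius, x$cell_half_length))
    cat(sprintf("  SF boundary:     radius %.2f, half-length %.2f\n",
                x$sf_radius, x$sf_half_length))
    cat(sprintf("  toroid arc:      radius %.2f (membrane half-thickness %.2f)\n",
                x$arc_radius, x$membrane_half))
  }
  invisible(x)
}

#' Aqueous boundary radius of the pore at a given |z|
#'
#' Radius of the aqueous region at height z: `sf_radius` inside the SF,
#' widening along the toroid arc, and the full cell radius beyond the
#' membrane.
#'
#' @param geometry a `csc_geometry`.
#' @param z axial coordinate(s), Angstrom.
#' @return Vector of radii (Angstrom).
#' @export
aqueous_radius <- function(geometry, z) {
  az <- abs(z)
  if (geometry$type == "bulk") return(rep(geometry$cell_radius, length(z)))
  L <- geometry$sf_half_length
  H <- geometry$membrane_half
  Ra <- geometry$arc_radius
  Rc <- geometry$sf_radius + Ra
  r <- rep(geometry$cell_radius, length(z))
  in_sf <- az <= L
  r[in_sf] <- geometry$sf_radius
  in_arc <- az > L & az <= H
  r[in_arc] <- Rc - sqrt(pmax(0, Ra^2 - (az[in_arc] - L)^2))
  r
}

# Signed distance from points to the protein/membrane solid region.
# `pts` is an n x 3 matrix.  Positive outside (distance to the surface),
# negative inside (penetration depth).
solid_distance <- function(geometry, pts) {
  pts <- rbind(pts)
  if (geometry$type == "bulk") return(rep(Inf, nrow(pts)))
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  az <- abs(pts[, 3])
  L <- geometry$sf_half_length
  H <- geometry$membrane_half
  Ra <- geometry$arc_radius
  Rsf <- geometry$sf_radius
  Rc <- Rsf + Ra

  inside <- az <= H & r >= aqueous_radius(geometry, az)
  # piece A: SF cylinder surface {rho = Rsf, |zeta| <= L}
  dA <- sqrt((r - Rsf)^2 + pmax(0, az - L)^2)
  # piece B: toroid arc, centre (Rc, L), radius Ra, polar angle in [90, 180] deg
  vx <- r - Rc
  vz <- az - L
  ang_ok <- vx <= 0 & vz >= 0
  dB <- ifelse(ang_ok, abs(sqrt(vx^2 + vz^2) - Ra), Inf)
  # piece C: flat membrane faces {zeta = H, rho in [Rc, cell_radius]}
  drC <- pmax(0, Rc - r) + pmax(0, r - geometry$cell_radius)
  dC <- sqrt((az - H)^2 + drC^2)
  d <- pmin(dA, dB, dC)
  d[inside] <- -d[inside]
  d
}

#' Test whether a sphere lies entirely in the aqueous region
#'
#' TRUE iff a sphere of the given radius centred at `point` overlaps neither
#' the protein toroid, the membrane, nor the outer cell wall.  Touching
#' (distance exactly equal to the radius) is permitted.
#'
#' @param point numeric length-3 vector, or an n x 3 matrix of centres.
#' @param radius sphere radius (Angstrom); 0 gives the point-containment test.
#' @param geometry a `csc_geometry`.
#' @return Logical vector.
#' @export
in_aqueous_region <- function(point, radius, geometry) {
  pts <- rbind(point)
  if (!all(is.finite(pts)) || !all(is.finite(radius)) || any(radius < 0))
    stop("non-finite coordinates or invalid radius")
  eps <- 1e-9
  radius <- rep_len(radius, nrow(pts))
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  ok <- (r + radius <= geometry$cell_radius + eps) &
    (abs(pts[, 3]) + radius <= geometry$cell_half_length + eps)
  if (geometry$type == "channel") {
    need <- which(ok)
    if (length(need))
      ok[need] <- solid_distance(geometry, pts[need, , drop = FALSE]) >=
        radius[need] - eps
  }
  unname(ok)
}

#' Hard-sphere overlap predicate
#'
#' Two spheres overlap iff their centre distance is strictly smaller than the
#' sum of their radii; touching spheres do not overlap.
#'
#' @param center_a,center_b numeric length-3 centres (Angstrom).
#' @param radius_a,radius_b sphere radii (Angstrom).
#' @return Logical flag.
#' @export
spheres_overlap <- function(center_a, radius_a, center_b, radius_b) {
  stopifnot(radius_a > 0, radius_b > 0)
  sum((center_a - center_b)^2) < (radius_a + radius_b)^2 - 1e-12
}

#' Pore-wall atom set
#'
#' Builds the set of localized hard spheres representing the SF-lining atoms.
#' Carbonyl oxygens carry a partial charge of -0.1 e; carboxylate oxygens a
#' full -1 e.  Spring constants (kT/Angstrom^2) derive from crystallographic
#' B-factors via [bfactor_to_spring()].
#'
#' @param label character labels.
#' @param base_position n x 3 matrix of base (tether) positions, Angstrom.
#' @param hard_radius hard-sphere radii, Angstrom (default 1.4 for oxygen).
#' @param charge charges in elementary-charge units.
#' @param spring_constant harmonic tether constants, kT/Angstrom^2.
#' @return A data frame of class `csc_wall_atoms` with columns
#'   `label, x, y, z, radius, charge, k`.
#' @export
pore_wall_atoms <- function(label, base_position, hard_radius = 1.4,
                            charge, spring_constant) {
  base_position <- rbind(base_position)
  n <- nrow(base_position)
  hard_radius <- rep_len(hard_radius, n)
  charge <- rep_len(charge, n)
  spring_constant <- rep_len(spring_constant, n)
  if (any(!is.finite(base_position)) || any(hard_radius <= 0))
    stop("wall atoms need finite positions and positive radii")
  if (any(spring_constant <= 0))
    stop("spring_constant must be > 0 for all localized atoms")
  out <- data.frame(label = as.character(rep_len(label, n)),
                    x = base_position[, 1], y = base_position[, 2],
                    z = base_position[, 3],
                    radius = hard_radius, charge = charge,
                    k = spring_constant, stringsAsFactors = FALSE)
  class(out) <- c("csc_wall_atoms", "data.frame")
  out
}

#' Narrowest accessible diameter of the SF
#'
#' Largest diameter of a sphere that can be centred on the pore axis at the
#' narrowest SF cross-section without overlapping any wall atom at its base
#' position or the SF boundary cylinder.  This is the gate size that decides
#' which cation hydration states can pass.
#'
#' @param geometry a channel `csc_geometry`.
#' @param wall_atoms a `csc_wall_atoms` data frame.
#' @param dz axial grid resolution for the bottleneck search (Angstrom).
#' @return Diameter in Angstrom (0, with a warning, if the axis is occluded).
#' @export
sf_min_accessible_diameter <- function(geometry, wall_atoms, dz = 0.01) {
  stopifnot(nrow(wall_atoms) >= 1)
  L <- if (geometry$type == "channel") geometry$sf_half_length
       else max(abs(wall_atoms$z)) + 2
  zg <- seq(-L, L, by = dz)
  rho2 <- wall_atoms$x^2 + wall_atoms$y^2
  # clearance radius at axial position z: nearest wall-atom surface
  cmin <- rep(Inf, length(zg))
  for (a in seq_len(nrow(wall_atoms))) {
    d <- sqrt(rho2[a] + (zg - wall_atoms$z[a])^2) - wall_atoms$radius[a]
    cmin <- pmin(cmin, d)
  }
  if (geometry$type == "channel")
    cmin <- pmin(cmin, aqueous_radius(geometry, zg))
  bottleneck <- min(cmin)
  if (bottleneck <= 0) {
    warning("wall atoms occlude the pore axis entirely")
    return(0)
  }
  2 * bottleneck
}

#' Does a sphere of given diameter fit through the SF?
#'
#' @param diameter sphere diameter (Angstrom).
#' @param geometry a channel `csc_geometry`.
#' @param wall_atoms a `csc_wall_atoms` data frame.
#' @param sf_min optional precomputed value of [sf_min_accessible_diameter()].
#' @return Logical flag; touching counts as fitting.
#' @export
fits_in_sf <- function(diameter, geometry, wall_atoms, sf_min = NULL) {
  stopifnot(diameter >= 0)
  if (is.null(sf_min))
    sf_min <- sf_min_accessible_diameter(geometry, wall_atoms)
  diameter <= sf_min + 1e-9
}
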