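# Shared fixtures, all generated in code.

# single uncharged point-particle type (ideal gas)
ideal_types <- function(conc = 0.2) {
  ty <- data.frame(type = "X", species = "X", x = NA_integer_, charge = 0,
                   radius = 0, factor = 1, conc_target = conc,
                   stringsAsFactors = FALSE)
  ty$mu <- log(molar_to_density(conc))
  class(ty) <- c("csc_types", "data.frame")
  ty
}

# small channel geometry used across geometry/electrostatics tests
tiny_geometry <- function() csc_geometry(cell_radius = 12,
                                         cell_half_length = 20,
                                         sf_radius = 5, sf_half_length = 4,
                                         arc_radius = 4)

# independent meridian wall-profile (re-derived in the tests, not taken from
# aqueous_radius): aqueous boundary radius at |z|
oracle_wall_radius <- function(g, z) {
  az <- abs(z)
  L <- g$sf_half_length; Ra <- g$arc_radius; H <- L + Ra
  if (az <= L) return(g$sf_radius)
  if (az <= H) return(g$sf_radius + Ra - sqrt(Ra^2 - (az - L)^2))
  g$cell_radius
}

# dense point sampling of the boundary surface for brute-force distances
oracle_surface_points <- function(g, n_theta = 180, n_prof = 400) {
  L <- g$sf_half_length; Ra <- g$arc_radius; H <- L + Ra
  Rc <- g$sf_radius + Ra
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-1]
  prof <- list()
  z <- seq(-L, L, length.out = n_prof)
  prof$cyl <- cbind(g$sf_radius, z)
  t <- seq(pi / 2, pi, length.out = n_prof)
  prof$arc_up <- cbind(Rc + Ra * cos(t), L + Ra * sin(t))
  prof$arc_dn <- cbind(Rc + Ra * cos(t), -(L + Ra * sin(t)))
  r <- seq(Rc, g$cell_radius, length.out = n_prof)
  prof$face_up <- cbind(r, H)
  prof$face_dn <- cbind(r, -H)
  pr <- do.call(rbind, prof)
  out <- do.call(rbind, lapply(th, function(a)
    cbind(pr[, 1] * cos(a), pr[, 1] * sin(a), pr[, 2])))
  out
}

# a reproducible random overlap-free state of charged hard spheres in a system
random_state <- function(sys, n, seed) {
  set.seed(seed)
  ty <- sys$types
  geom <- sys$geometry
  pos <- matrix(NA_real_, 0, 3)
  type <- integer(0)
  wall_r <- if (is.null(sys$wall)) numeric(0) else sys$wall$radius
  wall_p <- if (is.null(sys$wall)) matrix(numeric(0), 0, 3) else
    cbind(sys$wall$x, sys$wall$y, sys$wall$z)
  tries <- 0
  while (nrow(pos) < n && tries < 20000) {
    tries <- tries + 1
    t <- sample.int(nrow(ty), 1)
    rr <- geom$cell_radius * sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    p <- c(rr * cos(th), rr * sin(th),
           runif(1, -geom$cell_half_length, geom$cell_half_length))
    if (!in_aqueous_region(p, ty$radius[t], geom)) next
    allp <- rbind(pos, wall_p)
    allr <- c(ty$radius[type], wall_r)
    if (nrow(allp) > 0) {
      d <- sqrt(colSums((t(allp) - p)^2))
      if (any(d < allr + ty$radius[t])) next
    }
    pos <- rbind(pos, p)
    type <- c(type, t)
  }
  stopifnot(nrow(pos) == n)
  csc_state(sys, pos, type)
}

# independent dense ICC solve (reference implementation used as oracle)
oracle_icc_energy <- function(mesh, pos, q) {
  eps_w <- attr(mesh, "eps_water"); eps_p <- attr(mesh, "eps_protein")
  chi <- (eps_p - eps_w) / (2 * pi * (eps_w + eps_p))
  s <- cbind(mesh$cx, mesh$cy, mesh$cz)
  nrm <- cbind(mesh$nx, mesh$ny, mesh$nz)
  a <- mesh$area
  np <- nrow(s)
  G <- matrix(0, np, np)
  for (j in seq_len(np)) for (k in seq_len(np)) {
    if (j == k) next
    d <- s[j, ] - s[k, ]
    G[j, k] <- sum(nrm[j, ] * d) / sum(d^2)^1.5 * a[k]
  }
  pos <- rbind(pos)
  b <- numeric(np)
  for (i in seq_along(q)) {
    d <- t(t(s) - pos[i, ])
    r3 <- rowSums(d^2)^1.5
    b <- b + (q[i] / eps_w) * rowSums(nrm * d) / r3
  }
  h <- solve(diag(np) - chi * G, chi * b)
  phi <- 0
  for (i in seq_along(q)) {
    d <- sqrt(rowSums(t(t(s) - pos[i, ])^2))
    phi <- phi + q[i] * sum(h * a / d)
  }
  coul <- cscmc::bjerrum_length(1)   # e^2/(4 pi eps0 kT) in Angstrom
  list(h = h, U = 0.5 * coul * phi)
}

# brute-force total energy: double-loop Coulomb + dense ICC + U_mob
oracle_total_energy <- function(sys, state, mesh = NULL) {
  b <- rbind(state$pos, state$wall_pos)
  q <- c(sys$types$charge[state$type],
         if (is.null(sys$wall)) numeric(0) else sys$wall$charge)
  coul <- cscmc::bjerrum_length(1)
  U_C <- 0
  n <- nrow(b)
  if (n >= 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      U_C <- U_C + (coul / sys$eps_water) * q[i] * q[j] /
        sqrt(sum((b[i, ] - b[j, ])^2))
  U_IC <- if (is.null(mesh)) 0 else {
    keep <- q != 0
    oracle_icc_energy(mesh, b[keep, , drop = FALSE], q[keep])$U
  }
  U_mob <- 0
  if (!is.null(sys$wall)) {
    dd <- state$wall_pos - cbind(sys$wall$x, sys$wall$y, sys$wall$z)
    U_mob <- sum(0.5 * sys$wall$k * rowSums(dd^2))
  }
  U_C + U_IC + U_mob
}
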