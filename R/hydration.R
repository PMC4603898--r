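# Discrete cation hydration-state model.
#
# Each cation species is split into hydration states x = number of retained
# first-shell waters.  Every state is a hard sphere with its own "gate size"
# diameter (the cross-section the ion-plus-waters cluster occludes moving
# along the pore axis) and a bulk population factor
# [M<x>]_bulk/[M]_bulk = exp(-dG_x) set by the stepwise dehydration free
# energy dG_x (kT, zero at full hydration).
#
# Geometry of the gate sizes: the first shell is taken as octahedral with two
# waters always oriented along the pore axis (removed last); the four
# remaining waters sit in a plane perpendicular to the axis.  Fully hydrated,
# d_{M,6} = 2 (r_MO + r_OO/2) from the cation-oxygen and water oxygen-oxygen
# distances; losing one planar water does not shrink the circumcircle, so
# d_{M,5} = d_{M,6}; with two or fewer waters (both axial) the occluded
# cross-section is the bare ion, d_{M,x<=2} = bare diameter.  The
# intermediate x = 4, 3 circumcircle diameters ship as data.

#' Construct an ion species with hydration states
#'
#' @param name short species name (e.g. "Na").
#' @param valence integer charge in elementary charges.
#' @param states data frame with columns `x` (water count, 0..6) and
#'   `population_factor` and/or `delta_G` (kT, relative to full hydration),
#'   plus optionally `gate_diameter` (Angstrom).
#' @param r_MO cation-water oxygen distance (Angstrom), used for the fully
#'   hydrated gate diameter.
#' @param r_OO water oxygen-oxygen distance (Angstrom).
#' @param bare_diameter bare ion diameter (Angstrom), the gate size at x <= 2.
#' @return An object of class `csc_species`.
#' @export
ion_species <- function(name, valence, states, r_MO = NA, r_OO = NA,
                        bare_diameter = NA) {
  stopifnot(is.character(name), length(name) == 1,
            valence == round(valence), nrow(states) >= 1)
  if (!all(states$x == round(states$x)) || any(states$x < 0 | states$x > 6))
    stop("hydration states must have integer water count x in 0..6")
  states <- states[order(-states$x), , drop = FALSE]
  if (is.null(states$population_factor) && !is.null(states$delta_G))
    states$population_factor <-
      population_factors_from_energies(stats::setNames(states$delta_G,
                                                       states$x))
  if (is.null(states$population_factor))
    stop("states need population_factor or delta_G")
  if (!is.null(states$delta_G) && !is.null(states$population_factor)) {
    implied <- exp(-(states$delta_G - states$delta_G[1]))
    rel <- abs(implied - states$population_factor) /
      pmax(states$population_factor, 1e-300)
    if (any(rel > 0.05))
      stop(sprintf("population factors and delta_G disagree (state x=%d)",
                   states$x[which.max(rel)]))
  }
  pf <- states$population_factor
  if (abs(pf[1] - 1) > 1e-12)
    stop("population factor must equal 1 at the fully hydrated reference state")
  if (any(diff(pf) >= 0))
    stop("population factors must decrease strictly with decreasing x")
  if (any(pf <= 0 | pf > 1))
    stop("population factors must lie in (0, 1]")
  sp <- structure(list(name = name, valence = as.integer(valence),
                       r_MO = r_MO, r_OO = r_OO,
                       bare_diameter = bare_diameter,
                       states = states),
                  class = "csc_species")
  # diameter monotonicity over all defined states
  d <- vapply(states$x, function(x) gate_diameter(sp, x), numeric(1))
  if (any(diff(d) > 1e-9))
    stop("gate diameters must be non-increasing as x decreases")
  sp$states$gate_diameter <- d
  sp
}

#' @export
print.csc_species <- function(x, ...) {
  cat(sprintf("%s (valence %+d)\n", x$name, x$valence))
  df <- x$states
  df$gate_diameter <- sprintf("%.2f", df$gate_diameter)
  print(df[, c("x", "gate_diameter", "population_factor")], row.names = FALSE)
  invisible(x)
}

#' Population factors from stepwise dehydration free energies
#'
#' Boltzmann factors `exp(-dG_x)` of the partial-dehydration free energies,
#' normalized so the fully hydrated reference state has factor 1.
#'
#' @param delta_G named numeric vector of free energies in kT (names = water
#'   count x); must be 0 at the reference (largest x) and increase as x
#'   decreases.
#' @return Named vector of population factors.
#' @export
population_factors_from_energies <- function(delta_G) {
  x <- as.integer(names(delta_G))
  if (any(is.na(x))) stop("delta_G must be named by water count x")
  o <- order(-x)
  dg <- delta_G[o]
  if (abs(dg[1]) > 1e-12)
    stop("delta_G must be 0 at the fully hydrated reference state")
  if (any(dg < 0))
    stop("negative delta_G for a partial state would invert the reference")
  if (any(diff(dg) <= 0))
    stop("delta_G must increase as x decreases")
  stats::setNames(exp(-dg), names(delta_G)[o])
}

#' Gate-size diameter of a hydration state
#'
#' Cross-sectional ("gate size") diameter of the cation plus retained waters:
#' `2 * (r_MO + r_OO/2)` at x = 6 and x = 5, the bare ion diameter at
#' x <= 2, and the tabulated circumcircle diameter for x = 4, 3.
#'
#' @param species a `csc_species`.
#' @param x integer water count, 0..6.
#' @return Diameter in Angstrom.
#' @export
gate_diameter <- function(species, x) {
  if (length(x) > 1)
    return(vapply(x, function(xi) gate_diameter(species, xi), numeric(1)))
  if (!(x %in% 0:6)) stop("hydration state x must be in 0..6")
  st <- species$states
  if (x >= 5 && is.finite(species$r_MO) && is.finite(species$r_OO))
    return(2 * (species$r_MO + species$r_OO / 2))
  if (x <= 2 && is.finite(species$bare_diameter))
    return(species$bare_diameter)
  i <- match(x, st$x)
  if (is.na(i) || is.null(st$gate_diameter) || !is.finite(st$gate_diameter[i]))
    stop(sprintf("no gate diameter defined for %s at x=%d", species$name, x))
  st$gate_diameter[i]
}

#' Packaged hydration-state table
#'
#' Reads the packaged species table (K+, Na+, Ca2+): per-state gate diameters
#' and bulk population factors computed from experimental gas-phase stepwise
#' dehydration energies and solution radial-distribution-function distances.
#'
#' @param file path to a TSV with columns `species, valence, r_MO, r_OO,
#'   bare_diameter, x, gate_diameter, population_factor`; defaults to the
#'   table shipped with the package.
#' @return Named list of `csc_species`, class `csc_species_table`.
#' @export
default_species_table <- function(file = system.file("extdata",
                                                     "hydration_states.tsv",
                                                     package = "cscmc")) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  sp <- lapply(split(tab, tab$species), function(d) {
    ion_species(d$species[1], d$valence[1],
                states = d[, c("x", "gate_diameter", "population_factor")],
                r_MO = d$r_MO[1], r_OO = d$r_OO[1],
                bare_diameter = d$bare_diameter[1])
  })
  structure(sp[unique(tab$species)], class = "csc_species_table")
}

#' Select the hydration states admitted to a simulation
#'
#' Preferential sampling of the critical hydration states: the largest water
#' count whose gate diameter fits the SF bottleneck is admitted, together with
#' consecutively lower states whose bulk population factors lie within
#' `magnitude_window` orders of magnitude of the admitted maximum
#' (`rule = "relative"`), or of the cumulative sum of already included factors
#' (`rule = "cumulative"`).
#'
#' @param species a `csc_species`.
#' @param sf_min_diameter SF bottleneck diameter (Angstrom), from
#'   [sf_min_accessible_diameter()].
#' @param magnitude_window orders of magnitude (default 3).
#' @param rule window rule, `"relative"` (default) or `"cumulative"`.
#' @return List with `n_max` (the largest admitted x, NA if none) and `x`
#'   (integer vector of included states, empty with a warning if no state
#'   fits).
#' @export
select_states <- function(species, sf_min_diameter, magnitude_window = 3,
                          rule = c("relative", "cumulative")) {
  rule <- match.arg(rule)
  st <- species$states            # ordered by decreasing x
  fits <- st$gate_diameter <= sf_min_diameter + 1e-9
  if (!any(fits)) {
    warning(sprintf(
      "no hydration state of %s fits the SF (bottleneck %.2f A); %s",
      species$name, sf_min_diameter,
      "species excluded from the SF but still present in bulk"))
    return(list(n_max = NA_integer_, x = integer(0)))
  }
  i0 <- which(fits)[1]
  included <- i0
  thresh <- st$population_factor[i0] * 10^(-magnitude_window)
  if (i0 < nrow(st)) {
    for (i in (i0 + 1):nrow(st)) {
      if (rule == "cumulative")
        thresh <- sum(st$population_factor[included]) * 10^(-magnitude_window)
      if (st$population_factor[i] >= thresh) included <- c(included, i)
      else break                  # consecutively lower states only
    }
  }
  list(n_max = as.integer(st$x[i0]), x = as.integer(st$x[included]))
}

#' Bulk-population rescaling factor of an included state set
#'
#' Ratio of the summed bulk sub-populations of the states included in a
#' simulation to the full bulk population of the species,
#' `sum_included(factor) / sum_all(factor)`.
#'
#' @param species a `csc_species`.
#' @param included_x integer vector of included water counts.
#' @return Dimensionless rescaling factor in (0, 1].
#' @export
rescaling_factor <- function(species, included_x) {
  if (length(included_x) == 0) stop("non-empty state list required")
  st <- species$states
  i <- match(included_x, st$x)
  if (any(is.na(i)))
    stop(sprintf("unknown hydration state(s) for %s: %s", species$name,
                 paste(included_x[is.na(i)], collapse = ", ")))
  sum(st$population_factor[i]) / sum(st$population_factor)
}
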