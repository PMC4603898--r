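# Structured-text (YAML) run configuration: one schema shared by the
# toy-channel generator, the calibration utility, the simulator and the
# analysis step.

#' Build a run configuration
#'
#' Assembles and validates the nested configuration consumed by
#' [build_system_from_config()] and the command-line wrapper.  All lengths
#' are in Angstrom, concentrations in mol/L, energies in kT.
#'
#' @param channel either a preset name / ring specification understood by
#'   [build_toy_channel()], or a list `list(pdb = <file>, selection = ...,
#'   symmetry = ...)` for structure ingestion, or `NULL` for a bulk-only
#'   cell.
#' @param bulk_cell for `channel = NULL`: `list(radius, half_length)`.
#' @param species named list: for each simulated species either `"auto"`
#'   (state selection by the magnitude-window rule against the SF bottleneck)
#'   or an explicit integer vector of hydration states.
#' @param concentrations named numeric vector of total bulk concentrations
#'   (mol/L).
#' @param anion counter-ion description (`name`, `diameter`, `charge`).
#' @param eps_water,eps_protein dielectric constants (80/10).
#' @param patch_scale ICC mesh resolution (Angstrom).
#' @param moves named move-mix weights.
#' @param run list of sampler settings (`n_steps, equil, step_size,
#'   sample_every, sf_bias, seed`).
#' @param analysis list with `window` (minimum-search z-window) and
#'   `smooth_window`.
#' @param species_file optional TSV overriding the packaged hydration table.
#' @param magnitude_window orders of magnitude for automatic state selection.
#' @return A list of class `csc_config`.
#' @export
csc_config <- function(channel = "charged-pore", bulk_cell = NULL,
                       species = list(Na = "auto", K = "auto"),
                       concentrations = c(Na = 0.1, K = 0.1),
                       anion = list(name = "Cl", diameter = 3.6, charge = -1),
                       eps_water = 80, eps_protein = 10,
                       patch_scale = 1.2,
                       moves = c(displace = 0.8, insert = 0.05,
                                 delete = 0.05, swap = 0.1),
                       run = list(n_steps = 100000, equil = 10000,
                                  step_size = 0.8, sample_every = 10,
                                  sf_bias = 0, seed = 1),
                       analysis = list(window = c(-5, -2),
                                       smooth_window = 2),
                       species_file = NULL, magnitude_window = 3) {
  stopifnot(length(species) == length(concentrations),
            all(names(species) %in% names(concentrations)),
            eps_water > 0, eps_protein > 0, patch_scale > 0)
  structure(list(channel = channel, bulk_cell = bulk_cell,
                 species = species,
                 concentrations = as.list(concentrations), anion = anion,
                 eps_water = eps_water, eps_protein = eps_protein,
                 patch_scale = patch_scale, moves = as.list(moves),
                 run = run, analysis = analysis,
                 species_file = species_file,
                 magnitude_window = magnitude_window),
            class = "csc_config")
}

#' Read / write a configuration as YAML
#'
#' @param file path to a YAML configuration.
#' @return A `csc_config`.
#' @export
read_csc_config <- function(file) {
  raw <- yaml::read_yaml(file)
  raw$concentrations <- unlist(raw$concentrations)
  raw$moves <- unlist(raw$moves)
  do.call(csc_config, raw)
}

#' @rdname read_csc_config
#' @param config a `csc_config`.
#' @export
write_csc_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' Instantiate a simulation system from a configuration
#'
#' Builds the geometry (toy channel, ingested structure or bulk cell), the
#' boundary mesh and induced-charge operator, selects hydration states and
#' assembles the particle-type table.  The geometry echo is printed when
#' `verbose`.
#'
#' @param config a `csc_config`.
#' @param verbose print a geometry/type echo.
#' @return List with `sys` (a `csc_system`), `config`, and the selected
#'   per-species state sets.
#' @export
build_system_from_config <- function(config, verbose = FALSE) {
  spt <- if (is.null(config$species_file)) default_species_table() else
    default_species_table(config$species_file)
  if (is.null(config$channel)) {
    bc <- config$bulk_cell
    if (is.null(bc)) stop("bulk run needs a bulk_cell block")
    geom <- csc_bulk_cell(bc$radius, bc$half_length)
    wall <- NULL; op <- NULL
    sf_min <- Inf
  } else if (is.list(config$channel) && !is.null(config$channel$pdb)) {
    wall <- read_sf_atoms(config$channel$pdb, config$channel$selection,
                          symmetry = if (is.null(config$channel$symmetry)) 1
                          else config$channel$symmetry)
    cell <- config$channel$cell
    geom <- csc_geometry(cell$cell_radius, cell$cell_half_length,
                         sf_radius = max(sqrt(wall$x^2 + wall$y^2) +
                                           wall$radius) + 0.1,
                         sf_half_length = cell$sf_half_length,
                         arc_radius = cell$arc_radius)
    sf_min <- sf_min_accessible_diameter(geom, wall)
    op <- assemble_icc_operator(build_mesh(geom, config$patch_scale,
                                           eps_water = config$eps_water,
                                           eps_protein = config$eps_protein))
  } else {
    toy <- build_toy_channel(config$channel)
    geom <- toy$geometry; wall <- toy$wall_atoms
    sf_min <- toy$sf_min_diameter
    op <- if (config$eps_water == config$eps_protein) NULL else
      assemble_icc_operator(build_mesh(geom, config$patch_scale,
                                       eps_water = config$eps_water,
                                       eps_protein = config$eps_protein))
  }
  include <- list()
  for (sp in names(config$species)) {
    v <- config$species[[sp]]
    include[[sp]] <- if (identical(v, "auto")) {
      sel <- select_states(spt[[sp]], sf_min, config$magnitude_window)
      sel$x
    } else as.integer(v)
  }
  include <- include[lengths(include) > 0]
  ty <- build_types(spt, include, unlist(config$concentrations),
                    anion = config$anion)
  sys <- csc_system(geom, ty, wall_atoms = wall, icc = op,
                    eps_water = config$eps_water)
  if (verbose) {
    print(geom)
    print(sys)
    cat(sprintf("SF bottleneck: %.2f A; states: %s\n", sf_min,
                paste(vapply(names(include), function(s)
                  sprintf("%s{%s}", s, paste(include[[s]], collapse = ",")),
                  character(1)), collapse = " ")))
  }
  list(sys = sys, config = config, include = include,
       species_table = spt, sf_min = sf_min)
}
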