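#!/usr/bin/env Rscript
# Thin command-line wrapper over the cscmc package.
#
#   Rscript scripts/csc.R make-toy  --preset charged-pore --out toy.yaml
#   Rscript scripts/csc.R calibrate --config cfg.yaml --out mu.tsv
#   Rscript scripts/csc.R run       --config cfg.yaml --out run.rds
#   Rscript scripts/csc.R analyze   --run run.rds --pair Na,K \
#                                   --window=-5,-2 --out sel.json

suppressMessages({
  library(optparse)
  library(cscmc)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1)
  stop("usage: csc.R <make-toy|calibrate|run|analyze> [options]")
cmd <- args[1]
rest <- args[-1]

opts <- function(spec) parse_args(OptionParser(option_list = spec), rest)

if (cmd == "make-toy") {
  o <- opts(list(
    make_option("--preset", default = "charged-pore"),
    make_option("--out", default = "toy-config.yaml")))
  cfg <- csc_config(channel = o$preset)
  write_csc_config(cfg, o$out)
  toy <- build_toy_channel(o$preset)
  print(toy)
  cat("configuration written to", o$out, "\n")
} else if (cmd == "calibrate") {
  o <- opts(list(
    make_option("--config", type = "character"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--steps", type = "integer", default = 60000L),
    make_option("--out", default = "mu.tsv")))
  cfg <- read_csc_config(o$config)
  cfg$channel <- NULL
  if (is.null(cfg$bulk_cell)) cfg$bulk_cell <- list(radius = 16,
                                                    half_length = 24)
  built <- build_system_from_config(cfg, verbose = TRUE)
  cal <- calibrate_mu(built$sys, seed = o$seed, n_steps = o$steps)
  write.table(as.data.frame(cal$types), o$out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat("calibrated chemical potentials written to", o$out, "\n")
} else if (cmd == "run") {
  o <- opts(list(
    make_option("--config", type = "character"),
    make_option("--seed", type = "integer", default = NA_integer_),
    make_option("--out", default = "run.rds")))
  cfg <- read_csc_config(o$config)
  built <- build_system_from_config(cfg, verbose = TRUE)
  rc <- cfg$run
  seed <- if (!is.na(o$seed)) o$seed else rc$seed
  run <- csc_run(built$sys, n_steps = rc$n_steps, seed = seed,
                 weights = unlist(cfg$moves), step_size = rc$step_size,
                 equil = rc$equil, sample_every = rc$sample_every,
                 sf_bias = rc$sf_bias)
  print(run)
  saveRDS(list(run = run, config = cfg, include = built$include), o$out)
  cat("run written to", o$out, "\n")
} else if (cmd == "analyze") {
  o <- opts(list(
    make_option("--run", type = "character"),
    make_option("--pair", type = "character"),
    make_option("--window", type = "character", default = NULL),
    make_option("--out", default = "selectivity.json"),
    make_option("--profile-out", dest = "profile_out", default = NULL)))
  saved <- readRDS(o$run)
  pair <- strsplit(o$pair, ",")[[1]]
  win <- if (is.null(o$window))
    unlist(saved$config$analysis$window) else
      as.numeric(strsplit(o$window, ",")[[1]])
  spt <- default_species_table()
  sel <- selectivity(saved$run, pair = pair, window = win,
                     species_table = spt, bulk_source = "target")
  print(sel)
  write_selectivity_json(sel, o$out)
  if (!is.null(o$profile_out))
    write_profile_tsv(density_profile(saved$run), o$profile_out)
  cat("selectivity summary written to", o$out, "\n")
} else {
  stop(sprintf("unknown subcommand '%s'", cmd))
}
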