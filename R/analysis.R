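# Analysis: axial concentration profiles, density minima at the
# rate-determining barrier, and the selectivity estimators
# alpha_hyd, alpha_hat_sim and alpha_sim = alpha_hyd * alpha_hat_sim.
#
# Orientation convention (fixed by the requirement that the channel-selected
# ion A, listed first, gets alpha > 1): alpha_hat_sim is the barrier
# enrichment ratio
#     alpha_hat_sim = ([A.X]_min / [A<n>]_bulk) / ([B.X]_min / [B<m>]_bulk)
# so that  alpha_sim = alpha_hyd * alpha_hat_sim
#                    = ([A.X]_min [B]_bulk) / ([B.X]_min [A]_bulk).

# aqueous slab volume between z_lo and z_hi (point-particle accessible)
slab_volume <- function(geometry, z_lo, z_hi) {
  f <- function(z) pi * aqueous_radius(geometry, z)^2
  stats::integrate(function(z) vapply(z, f, numeric(1)), z_lo, z_hi,
                   rel.tol = 1e-8)$value
}

#' Axial concentration profile of a run
#'
#' Converts the accumulated axial histograms into concentrations per
#' (species, hydration state): counts divided by the number of samples and by
#' the accessible aqueous slab volume of each bin, in mol/L.  Per-bin
#' standard errors come from block averages.
#'
#' @param run a `csc_run` (or pre-aggregated accumulators of one).
#' @return A data frame of class `csc_profile` with columns
#'   `z, type, species, x, conc, se, counts`.
#' @export
density_profile <- function(run) {
  nbins <- length(run$bin_edges) - 1
  zc <- (run$bin_edges[-1] + run$bin_edges[-(nbins + 1)]) / 2
  vols <- vapply(seq_len(nbins), function(i)
    slab_volume(run$geometry, run$bin_edges[i], run$bin_edges[i + 1]),
    numeric(1))
  n_types <- nrow(run$types)
  nb_full <- max(1, run$n_blocks - 1)   # last block may be partial
  out <- list()
  for (t in seq_len(n_types)) {
    cnt <- run$hist[, t, , drop = FALSE]
    dim(cnt) <- c(nbins, run$n_blocks)
    blk <- sweep(cnt[, seq_len(nb_full), drop = FALSE], 1,
                 run$samples_per_block * vols, "/") * .csc_molar_per_A3
    conc <- rowMeans(blk)
    se <- apply(blk, 1, stats::sd) / sqrt(nb_full)
    out[[t]] <- data.frame(z = zc, type = run$types$type[t],
                           species = run$types$species[t],
                           x = run$types$x[t],
                           conc = conc, se = se,
                           counts = rowSums(cnt),
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  structure(df, bin_width = run$bin_width,
            nsamples = run$nsamples, smoothed = FALSE,
            slab_volumes = vols, geometry = run$geometry,
            class = c("csc_profile", "data.frame"))
}

#' Moving-average smoothing of a profile
#'
#' Centred moving average over a window of the given length; edge bins use
#' truncated windows.  The default 2 Angstrom window matches the presentation
#' of the simulated cation profiles.
#'
#' @param profile a `csc_profile`.
#' @param window window length in Angstrom.
#' @return The smoothed `csc_profile`.
#' @export
smooth_profile <- function(profile, window = 2) {
  bw <- attr(profile, "bin_width")
  if (window < bw) stop("smoothing window must be at least one bin wide")
  k <- max(1L, round(window / bw))
  half <- (k - 1L) %/% 2L
  sm <- function(v) {
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(0L, seq_len(n) - half - 1L)
    hi <- pmin(n, seq_len(n) + half)
    (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  }
  out <- profile
  for (t in unique(profile$type)) {
    i <- profile$type == t
    out$conc[i] <- sm(profile$conc[i])
    # window-mean SE assuming independent bins
    n <- sum(i)
    se2 <- profile$se[i]^2
    cs <- cumsum(c(0, se2))
    lo <- pmax(0L, seq_len(n) - half - 1L)
    hi <- pmin(n, seq_len(n) + half)
    out$se[i] <- sqrt(cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  }
  attr(out, "smoothed") <- TRUE
  attr(out, "window") <- k * bw
  out
}

#' Minimum concentration of a species inside a window
#'
#' Minimum of the (smoothed) total concentration of a species — summed over
#' its hydration states — within the axial window, i.e. the concentration at
#' the rate-determining barrier.  If the window holds no counts at all the
#' value is reported as a one-sided bound from the 95\% Poisson upper limit
#' on the empty region.
#'
#' @param profile a smoothed `csc_profile`.
#' @param window numeric `c(z_lo, z_hi)` in Angstrom.
#' @param species species name.
#' @return List `value` (mol/L), `se`, `z_at_min`, and `bound` (`TRUE` when
#'   the value is a Poisson upper bound rather than a measurement).
#' @export
profile_min <- function(profile, window, species) {
  stopifnot(length(window) == 2, window[1] < window[2])
  sub <- profile[profile$species == species, , drop = FALSE]
  if (nrow(sub) == 0) stop(sprintf("species '%s' not in profile", species))
  zs <- sort(unique(sub$z))
  inw <- zs >= window[1] & zs <= window[2]
  if (!any(inw)) stop("empty minimum window")
  tot <- tapply(sub$conc, sub$z, sum)[as.character(zs)]
  se2 <- tapply(sub$se^2, sub$z, sum)[as.character(zs)]
  cnt <- tapply(sub$counts, sub$z, sum)[as.character(zs)]
  i <- which(inw)[which.min(tot[inw])]
  if (sum(cnt[inw]) == 0) {
    # 95% Poisson upper limit on the total (zero) count in the window
    vols <- attr(profile, "slab_volumes")
    zall <- sort(unique(profile$z))
    vwin <- sum(vols[zall >= window[1] & zall <= window[2]])
    nsamp <- attr(profile, "nsamples")
    ub <- -log(0.05) / (nsamp * vwin) * .csc_molar_per_A3
    return(list(value = ub, se = NA_real_, z_at_min = unname(zs[i]),
                bound = TRUE))
  }
  list(value = unname(tot[i]), se = unname(sqrt(se2[i])),
       z_at_min = unname(zs[i]), bound = FALSE)
}

#' Simulated barrier selectivity ratio
#'
#' Enrichment of the channel-selected ion A over B at the rate-determining
#' barrier, relative to their (restricted-state) bulk concentrations:
#' `alpha_hat_sim = (min_A / bulk_A) / (min_B / bulk_B)`.  If a minimum is a
#' Poisson bound the result is flagged as the corresponding one-sided bound.
#'
#' @param min_A,min_B barrier minima (mol/L) or results of [profile_min()].
#' @param bulk_A,bulk_B simulated bulk concentrations of the admitted
#'   hydration states (mol/L).
#' @return List `value`, `bound` (`"none"`, `"lower"`, `"upper"`).
#' @export
alpha_sim_hat <- function(min_A, min_B, bulk_A, bulk_B) {
  bA <- is.list(min_A) && isTRUE(min_A$bound)
  bB <- is.list(min_B) && isTRUE(min_B$bound)
  vA <- if (is.list(min_A)) min_A$value else min_A
  vB <- if (is.list(min_B)) min_B$value else min_B
  if (vB <= 0 || bA && bB)
    stop("both minima unmeasured: no selectivity estimate possible")
  list(value = (vA / bulk_A) / (vB / bulk_B),
       bound = if (bB) "lower" else if (bA) "upper" else "none")
}

#' Hydration contribution to selectivity
#'
#' Ratio of the bulk-population rescaling factors of the two ions' admitted
#' hydration-state sets, `alpha_hyd = rescale(A) / rescale(B)`, with the
#' channel-selected ion A listed first.
#'
#' @param species_A,species_B `csc_species` objects.
#' @param states_A,states_B integer vectors of admitted hydration states.
#' @return Dimensionless factor.
#' @export
alpha_hyd <- function(species_A, species_B, states_A, states_B) {
  rescaling_factor(species_A, states_A) / rescaling_factor(species_B, states_B)
}

#' Total predicted selectivity
#'
#' `alpha_sim = alpha_hyd * alpha_hat_sim`.
#'
#' @param a_hat simulated barrier ratio (number or [alpha_sim_hat()] result).
#' @param a_hyd hydration contribution.
#' @return Number (or list with `value` and `bound` if `a_hat` carries a
#'   bound flag).
#' @export
alpha_total <- function(a_hat, a_hyd) {
  stopifnot(is.finite(a_hyd))
  if (is.list(a_hat))
    return(list(value = a_hat$value * a_hyd, bound = a_hat$bound))
  a_hat * a_hyd
}

#' Selectivity of a run or combined profile
#'
#' Computes the full selectivity decomposition for an ion pair from a
#' density profile: smoothed minima in the window, bulk terms (configured
#' targets or measured far-field concentrations), `alpha_hyd` from the
#' species' admitted states, and the product `alpha_sim`.
#'
#' @param x a `csc_run` or a `csc_profile`.
#' @param ... passed on.
#' @export
selectivity <- function(x, ...) UseMethod("selectivity")

#' @rdname selectivity
#' @param pair character vector `c(A, B)`, selected ion first.
#' @param window minimum-search window `c(z_lo, z_hi)` (Angstrom).
#' @param species_table a `csc_species_table` for the hydration factors.
#' @param types the run's type table (taken from the run automatically).
#' @param bulk_source `"target"` (configured) or `"measured"` (far-field).
#' @param run optional `csc_run` for measured bulk terms.
#' @param smooth_window smoothing window (Angstrom).
#' @export
selectivity.csc_profile <- function(x, pair, window, species_table,
                                    types, bulk_source = c("target",
                                                           "measured"),
                                    run = NULL, smooth_window = 2, ...) {
  bulk_source <- match.arg(bulk_source)
  prof <- if (isTRUE(attr(x, "smoothed"))) x else
    smooth_profile(x, smooth_window)
  A <- pair[1]; B <- pair[2]
  states <- lapply(c(A, B), function(s) sort(types$x[types$species == s],
                                             decreasing = TRUE))
  names(states) <- c(A, B)
  if (any(lengths(states) == 0))
    stop("pair species must be cation species with hydration states in the run's type table")
  bulk <- vapply(c(A, B), function(s) {
    if (bulk_source == "target")
      sum(types$conc_target[types$species == s])
    else {
      if (is.null(run)) stop("bulk_source='measured' needs the run")
      mb <- measure_bulk_concentration(run)
      sum(mb$conc[mb$species == s])
    }
  }, numeric(1))
  mA <- profile_min(prof, window, A)
  mB <- profile_min(prof, window, B)
  ah <- alpha_sim_hat(mA, mB, bulk[[1]], bulk[[2]])
  hyd <- alpha_hyd(species_table[[A]], species_table[[B]],
                   states[[A]], states[[B]])
  tot <- alpha_total(ah, hyd)
  structure(list(pair = c(A = A, B = B), window = window,
                 states = states,
                 min_A = mA, min_B = mB, bulk = bulk,
                 alpha_hat_sim = ah$value, alpha_hyd = hyd,
                 alpha_sim = if (is.list(tot)) tot$value else tot,
                 bound = ah$bound, bulk_source = bulk_source),
            class = "csc_selectivity")
}

#' @rdname selectivity
#' @export
selectivity.csc_run <- function(x, pair, window, species_table,
                                bulk_source = "target", ...) {
  selectivity(density_profile(x), pair = pair, window = window,
              species_table = species_table, types = x$types,
              bulk_source = bulk_source, run = x, ...)
}

#' @export
print.csc_selectivity <- function(x, ...) {
  cat(sprintf("Selectivity %s over %s (window [%.1f, %.1f] A)\n",
              x$pair[1], x$pair[2], x$window[1], x$window[2]))
  cat(sprintf("  [%s.X]_min = %.3g M%s   [%s.X]_min = %.3g M%s\n",
              x$pair[1], x$min_A$value,
              if (x$min_A$bound) " (95% upper bound)" else "",
              x$pair[2], x$min_B$value,
              if (x$min_B$bound) " (95% upper bound)" else ""))
  cat(sprintf("  alpha_hyd = %.3g, alpha_hat_sim = %.3g%s\n",
              x$alpha_hyd, x$alpha_hat_sim,
              if (x$bound != "none") sprintf(" (%s bound)", x$bound) else ""))
  cat(sprintf("  alpha_sim = %.3g\n", x$alpha_sim))
  invisible(x)
}

#' Aggregate replicate runs
#'
#' Inverse-variance-weighted combination of the per-run concentration
#' profiles of replicate simulations (same configuration, different seeds).
#' Bins with zero variance everywhere fall back to the plain mean.
#'
#' @param runs list of `csc_run` objects.
#' @return A combined `csc_profile`; attribute `n_runs` carries the replicate
#'   count.
#' @export
aggregate_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  ref <- runs[[1]]
  for (r in runs[-1]) {
    if (!identical(r$types$type, ref$types$type) ||
        !identical(r$bin_edges, ref$bin_edges) ||
        !identical(r$geometry, ref$geometry))
      stop("replicates must share configuration (types, bins, geometry)")
  }
  profs <- lapply(runs, density_profile)
  if (length(runs) == 1) return(profs[[1]])
  out <- profs[[1]]
  concs <- sapply(profs, function(p) p$conc)
  ses <- sapply(profs, function(p) p$se)
  counts <- sapply(profs, function(p) p$counts)
  w <- 1 / ses^2
  ok <- is.finite(w) & w > 0
  wc <- numeric(nrow(out)); wse <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    wi <- w[i, ]; ci <- concs[i, ]
    if (any(ok[i, ])) {
      wi <- wi[ok[i, ]]; ci <- ci[ok[i, ]]
      wc[i] <- sum(wi * ci) / sum(wi)
      wse[i] <- sqrt(1 / sum(wi))
    } else {
      wc[i] <- mean(ci)
      wse[i] <- 0
    }
  }
  out$conc <- wc
  out$se <- wse
  out$counts <- rowSums(counts)
  attr(out, "nsamples") <- sum(vapply(runs, function(r) r$nsamples,
                                      numeric(1)))
  attr(out, "n_runs") <- length(runs)
  out
}

#' Write a profile as TSV
#'
#' @param profile a `csc_profile`.
#' @param file output path.
#' @export
write_profile_tsv <- function(profile, file) {
  utils::write.table(as.data.frame(profile), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a selectivity summary as JSON
#'
#' @param sel a `csc_selectivity`.
#' @param file output path.
#' @export
write_selectivity_json <- function(sel, file) {
  jsonlite::write_json(list(
    pair = as.list(sel$pair), window = sel$window,
    states = sel$states,
    min_A = sel$min_A$value, min_B = sel$min_B$value,
    bulk_A = sel$bulk[[1]], bulk_B = sel$bulk[[2]],
    alpha_hyd = sel$alpha_hyd, alpha_hat_sim = sel$alpha_hat_sim,
    alpha_sim = sel$alpha_sim, bound = sel$bound),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Plot an axial concentration profile
#'
#' Base-graphics plot of the per-species total concentrations (summed over
#' hydration states) along the pore axis.
#'
#' @param x a `csc_profile`.
#' @param window optional minimum window to shade.
#' @param log_y plot on a log concentration axis.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.csc_profile <- function(x, window = NULL, log_y = FALSE, ...) {
  zs <- sort(unique(x$z))
  sps <- unique(x$species)
  m <- sapply(sps, function(s) {
    sub <- x[x$species == s, ]
    tapply(sub$conc, sub$z, sum)[as.character(zs)]
  })
  graphics::matplot(zs, m, type = "l", lty = 1, lwd = 2,
                    xlab = "z (Angstrom)", ylab = "concentration (mol/L)",
                    log = if (log_y) "y" else "", ...)
  if (!is.null(window))
    graphics::abline(v = window, lty = 3)
  graphics::legend("topright", legend = sps, lty = 1, lwd = 2,
                   col = seq_along(sps), bty = "n")
  invisible(x)
}
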