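#' Simulation configuration
#'
#' @param n_haplotypes number of haploid genomes to sample (>= 2).
#' @param sequence_length sequence length in bp.
#' @param r per-site per-generation recombination rate.
#' @param selfing selfing rate sigma in `[0, 1)`; handled by rescaling the
#'   effective recombination rate to `r_eff = r (1 - F)` with `F = sigma / (2 - sigma)`
#'   (standard partial-selfing coalescent rescaling).
#' @param markers list of [marker_spec()]; genome fractions must sum to 1.
#' @param region length-one list or a [region_model()] describing region-level
#'   epimutation (methylome simulations only); `NULL` for none.
#' @param meth_fraction fraction of the sequence carrying annotated methylable
#'   CG sites (methylome simulations; 0.02 to 0.2 in the experiments).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_haplotypes, sequence_length, r,
                       selfing = 0, markers = list(),
                       region = NULL, meth_fraction = 0.02) {
  if (n_haplotypes < 2) stop("`n_haplotypes` must be >= 2")
  if (sequence_length <= 0) stop("zero-length sequence")
  if (r < 0) stop("`r` must be >= 0")
  if (selfing < 0 || selfing >= 1) stop("`selfing` must be in [0, 1)")
  if (length(markers)) {
    fr <- vapply(markers, function(m) m$fraction, numeric(1))
    if (abs(sum(fr) - 1) > 1e-8) stop("marker genome fractions must sum to 1")
  }
  if (!is.null(region)) stopifnot(inherits(region, "region_model"))
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 sequence_length = sequence_length, r = r, selfing = selfing,
                 markers = markers, region = region,
                 meth_fraction = meth_fraction),
            class = "sim_config")
}

#' Effective recombination rate under partial selfing
#'
#' @param r per-site recombination rate.
#' @param selfing selfing rate sigma in `[0, 1)`.
#' @return the effective rate `r_eff = r (1 - F)` with inbreeding coefficient `F = sigma / (2 - sigma)`.
#' @export
effective_recombination <- function(r, selfing) {
  F <- selfing / (2 - selfing)
  r * (1 - F)
}

#' Simulate an ancestral recombination graph (sequence of marginal trees)
#'
#' Sequential SMC' simulation: an initial coalescent tree under the
#' piecewise-constant demography, then along the sequence each recombination
#' event cuts a uniformly chosen branch point and re-coalesces the detached
#' lineage into the standing genealogy (back-coalescence leaves the marginal
#' tree unchanged and is absorbed into the current tree's span).
#'
#' @param config a [sim_config()].
#' @param dem a [demography()].
#' @return an object of class `arg_trees`: marginal trees with genomic spans
#'   (`span`), node parent indices and times (columns of `parent` / `time`,
#'   nodes `1..n` are the leaves), the true pairwise TMRCA of leaves 1 and 2
#'   per tree (`tmrca`), and event counts.
#' @export
simulate_arg <- function(config, dem) {
  stopifnot(inherits(config, "sim_config"), inherits(dem, "demography"))
  r_eff <- effective_recombination(config$r, config$selfing)
  out <- .sim_arg_full_cpp(config$n_haplotypes, config$sequence_length, r_eff,
                           dem$boundaries, dem$sizes)
  out$n <- config$n_haplotypes
  out$L <- config$sequence_length
  class(out) <- "arg_trees"
  out
}

#' @export
print.arg_trees <- function(x, ...) {
  cat(sprintf("<arg_trees> %d haplotypes, %g bp, %d marginal trees (%g recombination events, %g silent)\n",
              x$n, x$L, length(x$span), x$n_events, x$n_silent))
  invisible(x)
}

## Round-robin marker placement: deterministic interleaving with a period P
## chosen from the genome fractions; residue j of each period belongs to
## marker pattern[j + 1]. Bresenham spreading keeps minority markers evenly
## interleaved.
marker_pattern <- function(markers) {
  fr <- vapply(markers, function(m) m$fraction, numeric(1))
  P <- round(1 / min(fr))
  P <- max(P, length(markers))
  counts <- round(fr * P)
  counts[which.max(counts)] <- P - sum(counts[-which.max(counts)])
  if (any(counts < 1)) stop("marker fraction too small for placement period")
  pat <- integer(P)
  assigned <- numeric(length(markers))
  for (j in seq_len(P)) {
    want <- fr * j - assigned
    m <- which.max(want)
    pat[j] <- m
    assigned[m] <- assigned[m] + 1
  }
  list(period = P, pattern = pat)
}

siteset_for_marker <- function(pat, m) {
  list(mode = 0L, period = pat$period,
       residues = as.integer(which(pat$pattern == m) - 1L))
}

#' Overlay finite-site marker mutations on a simulated tree sequence
#'
#' Marker sites are assigned along the sequence by deterministic round-robin
#' interleaving according to each marker's genome fraction. The ancestral
#' state of each site is drawn from the marker's stationary distribution and
#' mutations are placed on branches as a Poisson process with the marker's
#' total rate (finite sites: repeated hits allowed, symmetric markers
#' resample uniformly among the other states). For hyper-mutable markers the
#' per-branch end state is drawn directly from the chain's exact transition
#' probabilities, which is distributionally identical to enumerating hits.
#'
#' @param arg an [simulate_arg()] result.
#' @param markers list of [marker_spec()].
#' @param keep_monomorphic return all sites (with their states) rather than
#'   polymorphic ones only; intended for short sequences.
#' @return object of class `sim_data`; per marker: polymorphic positions
#'   (0-based), a states matrix (haplotypes x sites, states coded `0..nbs-1`)
#'   and the total number of sites of that class.
#' @export
overlay_marker_mutations <- function(arg, markers, keep_monomorphic = FALSE) {
  stopifnot(inherits(arg, "arg_trees"))
  pat <- marker_pattern(markers)
  md <- vector("list", length(markers))
  for (m in seq_along(markers)) {
    mk <- markers[[m]]
    res <- .overlay_marker_cpp(arg, siteset_for_marker(pat, m), mk$model,
                               mu = if (mk$model == "symmetric") mk$mu else 0,
                               nbs = mk$nbs,
                               mu_gain = if (mk$model == "asymmetric") mk$mu_gain else 0,
                               mu_loss = if (mk$model == "asymmetric") mk$mu_loss else 0,
                               keep_monomorphic = keep_monomorphic)
    md[[m]] <- list(positions = res$positions, states = res$states,
                    total_sites = res$total_sites)
  }
  structure(list(n = arg$n, L = arg$L, markers = markers, marker_data = md,
                 pattern = pat, meth = NULL,
                 truth = list(span = arg$span, tmrca = arg$tmrca)),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("<sim_data> %d haplotypes, %g bp\n", x$n, x$L))
  for (m in seq_along(x$markers)) {
    cat(sprintf("  marker '%s': %d polymorphic / %g sites\n",
                x$markers[[m]]$name, length(x$marker_data[[m]]$positions),
                x$marker_data[[m]]$total_sites))
  }
  if (!is.null(x$meth)) {
    cat(sprintf("  methylome: %d annotated CG sites in %d regions\n",
                length(x$meth$positions), nrow(x$meth$regions)))
  }
  invisible(x)
}

## Seeded placement of non-overlapping genic regions covering ~frac of [0, L).
place_genic_regions <- function(L, frac, region_length) {
  if (region_length > L) stop("region length larger than sequence")
  n_reg <- max(1L, round(frac * L / region_length))
  n_slots <- floor(L / region_length)
  if (n_reg > n_slots) stop("methylable fraction too large for region length")
  slots <- sort(sample.int(n_slots, n_reg)) - 1L
  starts <- slots * region_length
  cbind(start = starts, end = starts + region_length)
}

#' Simulate a methylome on a tree sequence
#'
#' Genic regions (seeded non-overlapping intervals of the configured region
#' length covering `meth_fraction` of the sequence) carry methylable CG
#' sites; every site inside a region is annotated, all other positions carry
#' the nucleotide marker. The site-level chain (rates `mu_gain`/`mu_loss` of
#' the methylation marker) and the region-level chain (rates of
#' `config$region`) run independently; a region-level event resets all sites
#' of the region to the region's new status. When region rates are zero each
#' site evolves on its own local marginal tree; with a region process all
#' sites of a region follow the genealogy at the region midpoint.
#'
#' @param arg an [simulate_arg()] result.
#' @param config a [sim_config()] whose `markers` are
#'   `list(snp_marker, methylation_marker)` with the methylation marker
#'   asymmetric.
#' @return object of class `sim_data` with a `meth` component: annotated
#'   positions, status matrix (haplotypes x sites, 0 = U, 1 = M), genic
#'   regions, and per-region truth (leaf and ancestral region status).
#' @export
simulate_methylome <- function(arg, config) {
  stopifnot(inherits(arg, "arg_trees"), inherits(config, "sim_config"))
  mk <- config$markers
  if (length(mk) != 2L || mk[[2]]$model != "asymmetric")
    stop("expected markers = list(snp, methylation) with asymmetric methylation")
  rm_ <- config$region
  reg <- place_genic_regions(arg$L, config$meth_fraction,
                             if (!is.null(rm_)) rm_$region_length else 1000L)
  positions <- unlist(lapply(seq_len(nrow(reg)), function(i) reg[i, 1]:(reg[i, 2] - 1L)))
  site_region <- rep.int(seq_len(nrow(reg)) - 1L,
                         times = reg[, 2] - reg[, 1])
  mid <- (reg[, 1] + reg[, 2]) / 2
  res <- .overlay_methylome_cpp(arg, as.integer(positions), as.integer(site_region),
                                as.numeric(mid),
                                mu_sm = mk[[2]]$mu_gain, mu_su = mk[[2]]$mu_loss,
                                mu_rm = if (!is.null(rm_)) rm_$mu_rm else 0,
                                mu_ru = if (!is.null(rm_)) rm_$mu_ru else 0)
  ## nucleotide marker on the complement of the annotated sites
  snp <- .overlay_marker_cpp(arg, list(mode = 1L, exclude = as.integer(positions)),
                             mk[[1]]$model, mu = mk[[1]]$mu, nbs = mk[[1]]$nbs,
                             mu_gain = 0, mu_loss = 0, keep_monomorphic = FALSE)
  md <- list(list(positions = snp$positions, states = snp$states,
                  total_sites = snp$total_sites),
             list(positions = as.integer(positions), states = res$states,
                  total_sites = length(positions)))
  structure(list(n = arg$n, L = arg$L, markers = mk, marker_data = md,
                 pattern = NULL,
                 meth = list(positions = as.integer(positions),
                             states = res$states, regions = reg,
                             region_model = rm_,
                             region_leaf = res$region_leaf,
                             region_anc = res$region_anc),
                 truth = list(span = arg$span, tmrca = arg$tmrca)),
            class = "sim_data")
}

#' Simulate a complete multi-marker dataset
#'
#' Convenience wrapper: [simulate_arg()] followed by
#' [overlay_marker_mutations()] (generic markers) or [simulate_methylome()]
#' (when the second marker is asymmetric).
#'
#' @param config a [sim_config()].
#' @param dem a [demography()].
#' @param keep_monomorphic passed to [overlay_marker_mutations()].
#' @return a `sim_data` object whose `truth` records the demography.
#' @export
simulate_dataset <- function(config, dem, keep_monomorphic = FALSE) {
  arg <- simulate_arg(config, dem)
  methylome <- length(config$markers) == 2L &&
    config$markers[[2]]$model == "asymmetric"
  dat <- if (methylome) simulate_methylome(arg, config)
         else overlay_marker_mutations(arg, config$markers, keep_monomorphic)
  dat$truth$demography <- dem
  dat$truth$n_trees <- length(arg$span)
  dat$config <- config
  dat
}

#' Named simulation scenarios
#'
#' Bundled scenarios mirroring the package's simulation experiments. The
#' bottleneck interval endpoints are package defaults (documented in the
#' methods vignette), not values read off any published axis.
#'
#' @param scenario one of `"constant"`, `"bottleneck_fig2A"`,
#'   `"bottleneck_fig2B"`, `"bottleneck_fig2C"`, `"severe_fig2D"`,
#'   `"methylome_fig5"`.
#' @param seed integer seed; all randomness flows from it.
#' @param n_haplotypes,sequence_length overrides for sample size and length.
#' @param meth_fraction annotated CG fraction for the methylome scenario.
#' @return a `sim_data` object with `truth$demography` set.
#' @export
generate_fixture <- function(scenario, seed, n_haplotypes = 10,
                             sequence_length = 2e6, meth_fraction = 0.02) {
  set.seed(seed)
  two_markers <- function(mu1, mu2)
    list(marker_spec("m1", nbs = 4, mu = mu1, fraction = 0.98),
         marker_spec("m2", nbs = 2, mu = mu2, fraction = 0.02))
  sc <- match.arg(scenario,
    c("constant", "bottleneck_fig2A", "bottleneck_fig2B", "bottleneck_fig2C",
      "severe_fig2D", "methylome_fig5"))
  cfg_dem <- switch(sc,
    constant = list(
      cfg = sim_config(n_haplotypes, sequence_length, r = 1e-8,
                       markers = two_markers(1e-8, 1e-4)),
      dem = demography(0, 10000)),
    bottleneck_fig2A = list(
      cfg = sim_config(n_haplotypes, sequence_length, r = 1e-8,
                       markers = two_markers(1e-8, 1e-4)),
      dem = bottleneck_demography(10000, fold = 10, t_start = 1000, t_end = 10000)),
    bottleneck_fig2B = list(
      cfg = sim_config(n_haplotypes, sequence_length, r = 1e-8,
                       markers = two_markers(1e-8, 1e-4)),
      dem = bottleneck_demography(1000, fold = 10, t_start = 100, t_end = 1000)),
    bottleneck_fig2C = list(
      cfg = sim_config(n_haplotypes, sequence_length, r = 1e-7,
                       markers = two_markers(1e-8, 1e-4)),
      dem = bottleneck_demography(10000, fold = 10, t_start = 5000, t_end = 50000)),
    severe_fig2D = list(
      cfg = sim_config(n_haplotypes, sequence_length, r = 1e-8,
                       markers = two_markers(1e-8, 1e-4)),
      dem = demography(c(0, 500, 5000), c(2000, 10, 10000))),
    methylome_fig5 = list(
      cfg = sim_config(n_haplotypes, sequence_length, r = 3.5e-8, selfing = 0.9,
                       markers = list(
                         marker_spec("snp", nbs = 4, mu = 7e-9,
                                     fraction = 1 - meth_fraction),
                         marker_spec("meth", nbs = 2, mu_gain = 3.5e-4,
                                     mu_loss = 1.5e-3, fraction = meth_fraction)),
                       region = NULL, meth_fraction = meth_fraction),
      dem = bottleneck_demography(10000, fold = 10, t_start = 1000, t_end = 10000)))
  simulate_dataset(cfg_dem$cfg, cfg_dem$dem)
}
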