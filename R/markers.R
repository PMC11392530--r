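#' Define a heritable marker class
#'
#' A marker class is characterised by its maximum number of possible states
#' `nbs` (4 for nucleotides, 2 for CG methylation status), its (epi)mutation
#' model and the proportion of genomic sites it occupies. Two mutation models
#' are supported and are mutually exclusive:
#'
#' * symmetric: a single rate `mu` per site per generation, with equal rates
#'   between all `nbs` states (the Jukes-Cantor-type symmetric chain);
#' * asymmetric: a two-state chain with distinct gain (`mu_gain`, U to M) and
#'   loss (`mu_loss`, M to U) rates, used for methylation.
#'
#' @param name label for the marker (e.g. `"snp"`, `"meth"`).
#' @param nbs integer number of possible states, at least 2.
#' @param mu symmetric per-site per-generation mutation rate. Mutually
#'   exclusive with `mu_gain`/`mu_loss`.
#' @param mu_gain,mu_loss asymmetric two-state rates (requires `nbs = 2`).
#' @param fraction proportion of genomic sites carrying this marker, in (0, 1].
#' @return an object of class `marker_spec`.
#' @examples
#' snp <- marker_spec("snp", nbs = 4, mu = 1e-8, fraction = 0.98)
#' hyper <- marker_spec("m2", nbs = 2, mu = 1e-4, fraction = 0.02)
#' @export
marker_spec <- function(name, nbs, mu = NULL, mu_gain = NULL, mu_loss = NULL,
                        fraction = 1) {
  nbs <- as.integer(nbs)
  if (is.na(nbs) || nbs < 2L) stop("`nbs` must be an integer >= 2")
  sym <- !is.null(mu)
  asym <- !is.null(mu_gain) || !is.null(mu_loss)
  if (sym && asym) stop("symmetric `mu` and asymmetric rates are mutually exclusive")
  if (!sym && !asym) stop("supply either `mu` or both `mu_gain` and `mu_loss`")
  if (asym) {
    if (is.null(mu_gain) || is.null(mu_loss)) {
      stop("asymmetric model needs both `mu_gain` and `mu_loss`")
    }
    if (nbs != 2L) stop("asymmetric model is defined for two-state markers only")
    if (mu_gain < 0 || mu_loss < 0) stop("rates must be >= 0")
  } else {
    if (mu < 0) stop("`mu` must be >= 0")
  }
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  structure(
    list(name = as.character(name), nbs = nbs,
         model = if (sym) "symmetric" else "asymmetric",
         mu = if (sym) mu else NULL,
         mu_gain = if (asym) mu_gain else NULL,
         mu_loss = if (asym) mu_loss else NULL,
         fraction = fraction),
    class = "marker_spec")
}

#' @export
print.marker_spec <- function(x, ...) {
  rate <- if (x$model == "symmetric") {
    sprintf("mu = %g", x$mu)
  } else {
    sprintf("mu_gain = %g, mu_loss = %g", x$mu_gain, x$mu_loss)
  }
  cat(sprintf("<marker_spec '%s'> nbs = %d, %s model, %s, fraction = %g\n",
              x$name, x$nbs, x$model, rate, x$fraction))
  invisible(x)
}

#' Region-level epimutation model
#'
#' Describes the region-level methylation process: whole regions of
#' `region_length` bp gain methylation at rate `mu_rm` and lose it at rate
#' `mu_ru` per region per generation, independently of the site-level process.
#'
#' @param mu_rm per-region per-generation methylation (gain) rate.
#' @param mu_ru per-region per-generation demethylation (loss) rate.
#' @param region_length region length in bp (1000 or 150 are typical choices).
#' @return an object of class `region_model`.
#' @export
region_model <- function(mu_rm = 2e-4, mu_ru = 1e-3, region_length = 1000) {
  if (mu_rm < 0 || mu_ru < 0) stop("region rates must be >= 0")
  if (region_length <= 0) stop("`region_length` must be > 0")
  structure(list(mu_rm = mu_rm, mu_ru = mu_ru,
                 region_length = as.integer(region_length)),
            class = "region_model")
}

#' Pair emission probabilities for a symmetric marker
#'
#' Probability that a site of a symmetric `nbs`-state marker is identical or
#' segregating between two haploid genomes whose lineages coalesce `t`
#' generations ago. Both branches of the pair genealogy have length `t`, so
#'
#' \deqn{P(id) = 1/nbs + (nbs-1)/nbs \exp(-2 \mu t \, nbs/(nbs-1))}
#'
#' and `P(seg) = 1 - P(id)`.
#'
#' @param marker a [marker_spec()] using the symmetric model.
#' @param t pairwise coalescence time (TMRCA) in generations; vectorised.
#' @return matrix with columns `identical` and `segregating`, one row per `t`.
#' @export
symmetric_pair_emission <- function(marker, t) {
  stopifnot(inherits(marker, "marker_spec"))
  if (marker$model != "symmetric") stop("marker does not use the symmetric model")
  if (any(t < 0)) stop("coalescence time must be >= 0")
  k <- marker$nbs
  pid <- 1 / k + (k - 1) / k * exp(-2 * marker$mu * t * k / (k - 1))
  cbind(identical = pid, segregating = 1 - pid)
}

## Two-state asymmetric chain: transition probabilities over time t.
## States coded 0 = unmethylated (U), 1 = methylated (M).
two_state_transition <- function(mu_gain, mu_loss, t) {
  lam <- mu_gain + mu_loss
  pm <- mu_gain / lam                  # stationary P(M)
  decay <- exp(-lam * t)
  list(
    U_to_M = pm * (1 - decay),
    M_to_M = pm + (1 - pm) * decay,
    p_m_stat = pm
  )
}

#' Pair emission probabilities for an asymmetric two-state (methylation) site
#'
#' Probability of the three observable site-pair symbols for a methylable
#' site: both unmethylated (code 2), both methylated (code 3), or discordant
#' (code 4). The ancestral state at the pair MRCA is drawn from the
#' stationary distribution of the two-state chain and each lineage then
#' evolves independently for `t` generations.
#'
#' @param mu_gain methylation (U to M) rate per site per generation.
#' @param mu_loss demethylation (M to U) rate per site per generation.
#' @param t pairwise coalescence time in generations; vectorised.
#' @param ancestral optional fixed ancestral state `"U"` or `"M"` instead of
#'   the stationary draw (used for region-conditioned emissions).
#' @return matrix with columns `uu`, `mm`, `discordant` (codes 2, 3, 4).
#' @export
asymmetric_site_emission <- function(mu_gain, mu_loss, t, ancestral = NULL) {
  if (mu_gain < 0 || mu_loss < 0) stop("rates must be >= 0")
  if (mu_gain == 0 && mu_loss == 0) stop("degenerate model: both rates are zero")
  if (any(t < 0)) stop("coalescence time must be >= 0")
  tr <- two_state_transition(mu_gain, mu_loss, t)
  ## P(leaf = M | ancestor = a) for the two ancestral states
  p_m_from_m <- tr$M_to_M
  p_m_from_u <- tr$U_to_M
  if (is.null(ancestral)) {
    w_m <- tr$p_m_stat
  } else {
    w_m <- switch(match.arg(ancestral, c("U", "M")), U = 0, M = 1)
  }
  ## leaves are conditionally independent given the ancestral state
  p_mm <- w_m * p_m_from_m^2 + (1 - w_m) * p_m_from_u^2
  p_uu <- w_m * (1 - p_m_from_m)^2 + (1 - w_m) * (1 - p_m_from_u)^2
  cbind(uu = p_uu, mm = p_mm, discordant = 1 - p_mm - p_uu)
}

#' Probabilities of the region-pair methylation status
#'
#' Region status evolves on the pair genealogy like a two-state site with the
#' region-level rates: both regions unmethylated (`UU`), discordant
#' (`UM`), or both methylated (`MM`).
#'
#' @param region a [region_model()].
#' @param t pairwise coalescence time in generations; vectorised.
#' @return matrix with columns `UU`, `UM`, `MM`.
#' @export
region_pair_status_probs <- function(region, t) {
  stopifnot(inherits(region, "region_model"))
  if (region$mu_rm == 0 && region$mu_ru == 0) {
    ## degenerate: region status frozen; report the methylated-rooted case
    ## explicitly so callers must decide - treated as all-MM by convention
    stop("degenerate region process: both region rates are zero")
  }
  e <- asymmetric_site_emission(region$mu_rm, region$mu_ru, t)
  cbind(UU = e[, "uu"], UM = e[, "discordant"], MM = e[, "mm"])
}

## Site-pair symbol probabilities conditional on the region-pair status.
## Contract (isolated here so it can be swapped): the ancestral site state
## tracks the region status at the MRCA; site rates are unchanged. For a
## discordant region pair (UM) the region flip on one branch decouples the
## two lineages: one evolves from M, the other from U, independently.
site_given_region_probs <- function(mu_gain, mu_loss, status, t) {
  switch(status,
    UU = asymmetric_site_emission(mu_gain, mu_loss, t, ancestral = "U"),
    MM = asymmetric_site_emission(mu_gain, mu_loss, t, ancestral = "M"),
    UM = {
      tr <- two_state_transition(mu_gain, mu_loss, t)
      p1 <- tr$M_to_M   # lineage whose region is methylated
      p2 <- tr$U_to_M   # lineage whose region is unmethylated
      p_mm <- p1 * p2
      p_uu <- (1 - p1) * (1 - p2)
      cbind(uu = p_uu, mm = p_mm, discordant = 1 - p_mm - p_uu)
    },
    stop("unknown region status code: ", status))
}

## transition matrix of the coupled (region status, site state) chain over
## time t. Per-lineage states: 1 = (U,U), 2 = (U,M), 3 = (M,U), 4 = (M,M)
## (region first). Site flips at the site rates; a region flip resets the
## site to the region's new status. Computed by uniformization with scaling
## and squaring.
region_site_transition <- function(mu_gain, mu_loss, region, t) {
  sg <- mu_gain; sl <- mu_loss
  rg <- region$mu_rm; rl <- region$mu_ru
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- sg; Q[1, 4] <- rg
  Q[2, 1] <- sl; Q[2, 4] <- rg
  Q[3, 4] <- sg; Q[3, 1] <- rl
  Q[4, 3] <- sl; Q[4, 1] <- rl
  diag(Q) <- -rowSums(Q)
  lam <- max(-diag(Q), 1e-300)
  k <- max(0L, ceiling(log2(lam * t)))
  dt <- t / 2^k
  ## uniformized series for exp(Q dt)
  Pj <- diag(4)
  P <- Pj * exp(-lam * dt)
  term <- exp(-lam * dt)
  B <- diag(4) + Q / lam
  for (j in 1:60) {
    Pj <- Pj %*% B
    term <- term * lam * dt / j
    P <- P + term * Pj
    if (term < 1e-18) break
  }
  for (i in seq_len(k)) P <- P %*% P
  P / rowSums(P)
}

#' Region-conditioned 9-symbol emission distribution
#'
#' Joint distribution of the product coding region-pair status
#' (`UU`, `UM`, `MM`) times site-pair status (codes 2, 3, 4) for a methylable
#' site at pairwise coalescence time `t`. The coupled (region, site) chain is
#' followed exactly on each lineage: site-level epimutation at the site
#' rates, region-level events at the region rates resetting the site to the
#' region's new status. The ancestral region status is drawn from the region
#' chain's stationary distribution and the ancestral site state equals it;
#' the two lineages evolve independently given the ancestral state.
#'
#' @param mu_gain,mu_loss site-level epimutation rates.
#' @param region a [region_model()]; if its rates are both zero the region
#'   process is degenerate: the site chain reduces to the plain
#'   [asymmetric_site_emission()] and `region_status` must be supplied.
#' @param t pairwise coalescence time in generations (scalar).
#' @param region_status optional region-pair status (`"UU"`, `"UM"`, `"MM"`):
#'   returns the 3 site-symbol probabilities conditional on that leaf status
#'   instead of the joint 9-vector.
#' @return if `region_status` is `NULL`, a named 9-vector over
#'   `status:code` symbols summing to 1; otherwise a 3-vector over site codes.
#' @export
region_conditioned_emission <- function(mu_gain, mu_loss, region, t,
                                        region_status = NULL) {
  stopifnot(length(t) == 1L, t >= 0)
  statuses <- c("UU", "UM", "MM")
  if (region$mu_rm == 0 && region$mu_ru == 0) {
    ## frozen regions: no resets ever, the site chain is at its ordinary
    ## stationary state whatever the region status
    if (is.null(region_status)) {
      stop("degenerate region process: supply `region_status`")
    }
    out <- drop(asymmetric_site_emission(mu_gain, mu_loss, t))
    names(out) <- c("2", "3", "4")
    return(out)
  }
  P <- region_site_transition(mu_gain, mu_loss, region, t)
  pr_m <- region$mu_rm / (region$mu_rm + region$mu_ru)
  root <- c(1 - pr_m, 0, 0, pr_m)   # site state equals region status at root
  joint <- matrix(0, 4, 4)
  for (a in 1:4) {
    if (root[a] > 0) joint <- joint + root[a] * (P[a, ] %o% P[a, ])
  }
  reg_of <- c(1L, 1L, 2L, 2L)  # 1 = U region, 2 = M region
  site_of <- c(1L, 2L, 1L, 2L) # 1 = U site,  2 = M site
  out <- numeric(9)
  names(out) <- paste0(rep(statuses, each = 3), ":", rep(c("2", "3", "4"), 3))
  for (a in 1:4) for (b in 1:4) {
    rs <- if (reg_of[a] == 1L && reg_of[b] == 1L) "UU"
          else if (reg_of[a] == 2L && reg_of[b] == 2L) "MM" else "UM"
    sc <- if (site_of[a] == 1L && site_of[b] == 1L) "2"
          else if (site_of[a] == 2L && site_of[b] == 2L) "3" else "4"
    out[paste0(rs, ":", sc)] <- out[paste0(rs, ":", sc)] + joint[a, b]
  }
  if (!is.null(region_status)) {
    region_status <- match.arg(region_status, statuses)
    block <- out[paste0(region_status, ":", c("2", "3", "4"))]
    blk <- block / sum(block)
    names(blk) <- c("2", "3", "4")
    return(blk)
  }
  out
}

#' Per-state emission distribution of a marker at given coalescence times
#'
#' Convenience dispatcher used by the inference engine: evaluates the
#' appropriate closed-form emission model of `marker` at each time in `t`.
#'
#' @param marker a [marker_spec()].
#' @param t vector of coalescence times in generations.
#' @return matrix, one row per `t`: columns `identical`/`segregating` for
#'   symmetric markers, `uu`/`mm`/`discordant` for asymmetric ones.
#' @export
marker_emission <- function(marker, t) {
  if (marker$model == "symmetric") {
    symmetric_pair_emission(marker, t)
  } else {
    asymmetric_site_emission(marker$mu_gain, marker$mu_loss, t)
  }
}

## Stationary distribution of a marker's state chain.
marker_stationary <- function(marker) {
  if (marker$model == "symmetric") {
    rep(1 / marker$nbs, marker$nbs)
  } else {
    pm <- marker$mu_gain / (marker$mu_gain + marker$mu_loss)
    c(U = 1 - pm, M = pm)
  }
}
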