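#' Methylome matrix
#'
#' Per-haplotype methylation status at the annotated (methylable) CG sites.
#'
#' @param positions sorted 0-based positions of methylable sites.
#' @param states haplotypes x sites matrix with entries 1 (methylated, M),
#'   0 (unmethylated, U) or `NA` (missing).
#' @param regions optional genic-region intervals (matrix with columns
#'   `start`, `end`, 0-based half-open).
#' @return object of class `methylome`.
#' @export
methylome <- function(positions, states, regions = NULL) {
  positions <- as.integer(positions)
  if (is.unsorted(positions)) stop("positions must be sorted")
  states <- as.matrix(states)
  if (ncol(states) != length(positions)) stop("positions/states length mismatch")
  if (!all(states %in% c(0L, 1L, NA))) stop("status outside alphabet {M, U, missing}")
  structure(list(positions = positions, states = states, regions = regions),
            class = "methylome")
}

## extract the methylome layer of a sim_data object
as_methylome <- function(dat) {
  if (inherits(dat, "methylome")) return(dat)
  if (is.null(dat$meth)) stop("no methylome layer in this dataset")
  methylome(dat$meth$positions, dat$meth$states, dat$meth$regions)
}

#' Test for a region-level effect on methylation state
#'
#' Under site-independent epimutation the probability that two successive
#' annotated sites of one genome share their methylation status is
#' `p0 = pM^2 + pU^2` with `pM = muSM / (muSM + muSU)` the stationary
#' methylated fraction. The observed count of identical adjacent pairs
#' (pooled over genomes) is compared to this binomial expectation with a
#' two-sided exact test; a small p-value indicates spatially correlated
#' states, i.e. a region-level epimutation process.
#'
#' @param meth a [methylome()] or a `sim_data` with a methylome layer.
#' @param mu_sm,mu_su site-level methylation / demethylation rates.
#' @param threshold significance threshold (default 0.05).
#' @param min_separation only count adjacent pairs at genomic distance of at
#'   least this many bp (distance-stratified variant).
#' @return list: `p_value`, `decision` (`"region effect"` / `"independent"`),
#'   observed and expected identity fractions, and the pair count.
#' @export
region_effect_test <- function(meth, mu_sm, mu_su, threshold = 0.05,
                               min_separation = 1) {
  meth <- as_methylome(meth)
  if (length(meth$positions) < 2L) stop("fewer than 2 methylable sites")
  p_m <- mu_sm / (mu_sm + mu_su)
  p0 <- p_m^2 + (1 - p_m)^2
  d <- diff(meth$positions)
  use <- d >= min_separation
  ## disjoint adjacent pairs: overlapping pairs share a site, so their
  ## identity indicators are 1-dependent and the count is overdispersed
  ## relative to the binomial null; disjoint pairs keep the null exact
  use[seq_along(use) %% 2L == 0L] <- FALSE
  x <- 0L
  n_pairs <- 0L
  for (i in seq_len(nrow(meth$states))) {
    s <- meth$states[i, ]
    same <- s[-length(s)] == s[-1]
    keep <- use & !is.na(same)
    x <- x + sum(same[keep])
    n_pairs <- n_pairs + sum(keep)
  }
  if (n_pairs < 1L) stop("no usable adjacent site pairs")
  ht <- stats::binom.test(x, n_pairs, p = p0, alternative = "two.sided")
  list(p_value = ht$p.value,
       decision = if (ht$p.value < threshold) "region effect" else "independent",
       observed = x / n_pairs, expected = p0, n_pairs = n_pairs)
}

## stationary probability that a site is methylated given its region's
## current status, under the coupled (region, site) chain in which region
## events reset the site. Solves pi Q = 0 for the 4-state chain.
site_status_given_region <- function(mu_sm, mu_su, mu_rm, mu_ru) {
  Q <- matrix(0, 4, 4)  # states (U,U), (U,M), (M,U), (M,M), region first
  Q[1, 2] <- mu_sm; Q[1, 4] <- mu_rm
  Q[2, 1] <- mu_su; Q[2, 4] <- mu_rm
  Q[3, 4] <- mu_sm; Q[3, 1] <- mu_ru
  Q[4, 3] <- mu_su; Q[4, 1] <- mu_ru
  diag(Q) <- -rowSums(Q)
  ## least-squares solve of pi Q = 0 with sum(pi) = 1
  pi_ <- stats::coef(stats::lm.fit(rbind(base::t(Q), rep(1, 4)),
                                   c(rep(0, 4), 1)))
  pi_ <- pmax(unname(pi_), 0); pi_ <- pi_ / sum(pi_)
  c(m_given_u = pi_[2] / (pi_[1] + pi_[2]),
    m_given_m = pi_[4] / (pi_[3] + pi_[4]))
}

#' Segment the region-level methylation status of a haplotype pair
#'
#' Three-state hidden Markov model over the annotated site-pair symbols of
#' one pair of genomes: hidden region-pair status `UU`, `UM` (discordant) or
#' `MM`; emissions are the site-pair symbol probabilities (codes 2/3/4) with
#' each genome's site methylated with the stationary conditional probability
#' given its region status under the coupled region+site chain; transitions
#' follow a geometric region-length prior (switch probability
#' `1 - exp(-d / Lr)` over a gap of `d` bp). Posterior decoding yields the
#' segmentation.
#'
#' @param meth a [methylome()] or `sim_data` with methylome layer.
#' @param pair the two haplotype indices.
#' @param mu_sm,mu_su site-level epimutation rates used for the emissions.
#' @param region_rates region-level `c(mu_rm, mu_ru)` rates controlling how
#'   tightly sites track their region status.
#' @param region_length prior mean region length Lr in bp.
#' @return object of class `methyl_segmentation`: per-site posterior, decoded
#'   status per site, run-length segments (start, end, status, length in bp)
#'   and summary mean/median segment lengths.
#' @export
segment_methylation_regions <- function(meth, pair = c(1, 2),
                                        mu_sm = 3.5e-4, mu_su = 1.5e-3,
                                        region_rates = c(2e-4, 1e-3),
                                        region_length = 1000) {
  meth <- as_methylome(meth)
  S <- length(meth$positions)
  if (S < 1L) stop("empty methylome")
  s1 <- meth$states[pair[1], ]
  s2 <- meth$states[pair[2], ]
  code <- ifelse(s1 == 0 & s2 == 0, 1L, ifelse(s1 == 1 & s2 == 1, 2L, 3L))
  statuses <- c("UU", "UM", "MM")
  pc <- site_status_given_region(mu_sm, mu_su, region_rates[1], region_rates[2])
  pm <- c(UU = unname(pc["m_given_u"]), MM = unname(pc["m_given_m"]))
  pair_probs <- function(p1, p2)
    c(uu = (1 - p1) * (1 - p2), mm = p1 * p2, disc = p1 * (1 - p2) + p2 * (1 - p1))
  E <- rbind(
    UU = pair_probs(pm["UU"], pm["UU"]),
    UM = pair_probs(pm["MM"], pm["UU"]),
    MM = pair_probs(pm["MM"], pm["MM"]))
  logE <- matrix(0, S, 3)  # missing sites emit log 1 in every status
  ok <- !is.na(code)
  lE <- base::t(log(pmax(E, 1e-320)))  # codes x statuses
  logE[ok, ] <- lE[code[ok], , drop = FALSE]
  ## uniform prior over the three statuses; distance-aware switching
  d <- diff(meth$positions)
  p_switch <- 1 - exp(-d / region_length)
  ## forward-backward with per-step transition matrices (small, done in R)
  pi0 <- rep(1 / 3, 3)
  alpha <- matrix(0, S, 3)
  cvec <- numeric(S)
  e1 <- exp(logE[1, ] - max(logE[1, ]))
  alpha[1, ] <- pi0 * e1
  cvec[1] <- sum(alpha[1, ])
  alpha[1, ] <- alpha[1, ] / cvec[1]
  if (S > 1) for (i in 2:S) {
    Ai <- matrix(p_switch[i - 1] / 3, 3, 3)
    diag(Ai) <- diag(Ai) + (1 - p_switch[i - 1])
    ei <- exp(logE[i, ] - max(logE[i, ]))
    a <- (alpha[i - 1, ] %*% Ai) * ei
    cvec[i] <- sum(a)
    alpha[i, ] <- a / cvec[i]
  }
  beta <- matrix(1, S, 3)
  if (S > 1) for (i in (S - 1):1) {
    Ai <- matrix(p_switch[i] / 3, 3, 3)
    diag(Ai) <- diag(Ai) + (1 - p_switch[i])
    ei <- exp(logE[i + 1, ] - max(logE[i + 1, ]))
    beta[i, ] <- (Ai %*% (ei * beta[i + 1, ])) / cvec[i + 1]
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  decoded <- max.col(post, ties.method = "first")
  ## run-length segments in bp: a segment extends to the midpoint between
  ## the last site of one run and the first site of the next
  runs <- rle(decoded)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- c(1L, ends_idx[-length(ends_idx)] + 1L)
  pos <- meth$positions
  seg_start <- pos[starts_idx]
  seg_end <- pos[ends_idx] + 1L
  if (length(runs$lengths) > 1L) {
    mids <- floor((pos[ends_idx[-length(ends_idx)]] + pos[starts_idx[-1]]) / 2)
    seg_end[-length(seg_end)] <- mids
    seg_start[-1] <- mids
  }
  segments <- data.frame(start = seg_start, end = seg_end,
                         status = statuses[runs$values],
                         length = seg_end - seg_start)
  structure(list(positions = pos, posterior = post,
                 status = statuses[decoded], status_index = decoded,
                 segments = segments,
                 mean_length = mean(segments$length),
                 median_length = stats::median(segments$length),
                 pair = pair),
            class = "methyl_segmentation")
}

#' @export
print.methyl_segmentation <- function(x, ...) {
  cat(sprintf("<methyl_segmentation> %d sites, %d segments (mean %0.0f bp, median %0.0f bp)\n",
              length(x$positions), nrow(x$segments), x$mean_length,
              x$median_length))
  invisible(x)
}

## region-pair status (1 = UU, 2 = UM, 3 = MM) at arbitrary positions
segmentation_status_at <- function(segmentation, pos) {
  idx <- findInterval(pos, segmentation$positions)
  idx[idx < 1L] <- 1L
  segmentation$status_index[idx]
}

#' Encode a haplotype pair's observations as per-site symbols
#'
#' Observation coding along the genome for one pair of haploid genomes:
#' non-methylable site with equal nucleotides is 0, with different
#' nucleotides 1; a methylable site where both cytosines are unmethylated is
#' 2, both methylated 3, discordant 4. With a region segmentation the
#' methylation codes are lifted to the 9-symbol alphabet (region-pair status
#' `UU`/`UM`/`MM` times site codes 2/3/4). Missing states become a dedicated
#' missing symbol (`NA`) that emits equally in every hidden state.
#'
#' @param snp_states 2 x S1 matrix (or NULL) of nucleotide states at the
#'   polymorphic positions `snp_positions` for this pair; sites not listed
#'   are identical.
#' @param snp_positions 0-based positions of the nucleotide entries.
#' @param meth a [methylome()] restricted to this pair (rows 1 and 2) or
#'   `NULL`.
#' @param L sequence length.
#' @param segmentation optional [segment_methylation_regions()] result.
#' @return object of class `pair_obs`: `symbols` (integer symbol index per
#'   position, `NA` for missing) and the symbol table; suitable for the exact
#'   per-site [forward_backward()].
#' @export
encode_pair_observations <- function(snp_states, snp_positions, meth, L,
                                     segmentation = NULL) {
  nine <- !is.null(segmentation)
  labs <- data.frame(marker = 1L, code = c("id", "seg"))
  if (!is.null(meth)) {
    meth_codes <- if (nine)
      paste0(rep(c("UU", "UM", "MM"), each = 3), ":", rep(c("2", "3", "4"), 3))
    else c("2", "3", "4")
    labs <- rbind(labs, data.frame(marker = 2L, code = meth_codes))
  }
  sym <- rep.int(1L, L)  # default: identical nucleotide site
  if (!is.null(snp_states) && length(snp_positions)) {
    if (ncol(as.matrix(snp_states)) != length(snp_positions))
      stop("inconsistent lengths")
    seg <- snp_states[1, ] != snp_states[2, ]
    sym[snp_positions[which(seg)] + 1L] <- 2L
    miss <- is.na(seg)
    sym[snp_positions[which(miss)] + 1L] <- NA
  }
  if (!is.null(meth)) {
    s1 <- meth$states[1, ]
    s2 <- meth$states[2, ]
    code <- ifelse(s1 == 0 & s2 == 0, 1L, ifelse(s1 == 1 & s2 == 1, 2L, 3L))
    if (nine) {
      status <- segmentation_status_at(segmentation, meth$positions)
      code <- (status - 1L) * 3L + code
    }
    sym[meth$positions + 1L] <- code + 2L
  }
  structure(list(symbols = sym, symbols_table = labs, L = L),
            class = "pair_obs")
}

#' Decode a per-site symbol sequence
#'
#' Inverse of [encode_pair_observations()] on the defined symbol set:
#' returns, per position, the marker class and pair code.
#'
#' @param obs a `pair_obs`.
#' @return data.frame with `position`, `marker` and `code`.
#' @export
decode_pair_observations <- function(obs) {
  stopifnot(inherits(obs, "pair_obs"))
  tab <- obs$symbols_table
  data.frame(position = seq_along(obs$symbols) - 1L,
             marker = tab$marker[obs$symbols],
             code = tab$code[obs$symbols])
}

#' Full methylation-aware SMC fit (SNPs + SMPs/DMRs)
#'
#' Drives the complete methylation workflow: decide on a region-level effect
#' ([region_effect_test()]), optionally segment each pair's region status
#' and lift the coding to the 9-symbol alphabet, estimate unknown
#' epimutation rates (diversity transfer or Baum-Welch via the 1% rule),
#' and fit the pairwise SMC on the combined SNP + methylation observations.
#' With the region model off and symmetric site rates this reduces exactly
#' to the generic two-marker fit.
#'
#' @param dat a `sim_data` with a methylome layer (or compatible object with
#'   `markers`, `marker_data`, `meth`).
#' @param mu1 known nucleotide mutation rate.
#' @param site_rates known `c(mu_gain, mu_loss)` or `NULL` to estimate.
#' @param region `"auto"` (use the region test), `"on"`, or `"off"`.
#' @param region_rates known `c(mu_rm, mu_ru)` for the 9-symbol emissions
#'   (required if the region model ends up on and cannot be estimated).
#' @param region_length region length prior for segmentation, bp.
#' @param segregating_only restrict methylable sites to segregating SMPs.
#' @param method,free_parameters,n_states,bin_w,r0,selfing,max_haplotypes,...
#'   fitting options as in [fit_multimarker()].
#' @return an `smc_fit` with extra fields: `site_rates`, `rate_method`,
#'   `region_used`, `region_test`, `segmentations`.
#' @export
fit_smcm <- function(dat, mu1, site_rates = NULL,
                     region = c("auto", "off", "on"), region_rates = NULL,
                     region_length = 1000, segregating_only = FALSE,
                     method = c("bw", "lh"),
                     free_parameters = c("sizes", "r"),
                     n_states = 20, bin_w = 100, r0 = 1e-8, selfing = 0,
                     max_haplotypes = NULL, ...) {
  region <- match.arg(region)
  method <- match.arg(method)
  if (is.null(dat$meth)) stop("dataset has no methylome layer")
  mk <- dat$markers
  mk[[1]]$mu <- mu1

  rate_method <- "known"
  if (is.null(site_rates)) {
    est <- estimate_rates_auto(dat, mu1, target = 2L,
                               n_states = n_states, bin_w = bin_w,
                               max_haplotypes = max_haplotypes)
    site_rates <- c(est$estimate[["mu_gain"]], est$estimate[["mu_loss"]])
    rate_method <- est$method
  }
  mk[[2]]$mu_gain <- site_rates[1]
  mk[[2]]$mu_loss <- site_rates[2]

  rtest <- NULL
  use_region <- switch(region, off = FALSE, on = TRUE, auto = {
    rtest <- region_effect_test(dat, mk[[2]]$mu_gain, mk[[2]]$mu_loss)
    rtest$decision == "region effect"
  })
  segmentations <- NULL
  region_obj <- NULL
  if (use_region) {
    if (is.null(region_rates)) {
      stop("region model on without region rates; supply `region_rates`")
    }
    region_obj <- region_model(region_rates[1], region_rates[2], region_length)
  }

  model <- init_model(dat, mk, n_states = n_states, r = r0, selfing = selfing,
                      region = region_obj, bin_w = bin_w)
  prs <- haplotype_pairs(dat$n, max_haplotypes)
  encs <- vector("list", nrow(prs))
  if (use_region) segmentations <- vector("list", nrow(prs))
  for (i in seq_len(nrow(prs))) {
    segm <- NULL
    if (use_region) {
      segm <- segment_methylation_regions(dat, prs[i, ],
                                          mu_sm = mk[[2]]$mu_gain,
                                          mu_su = mk[[2]]$mu_loss,
                                          region_rates = region_rates,
                                          region_length = region_length)
      segmentations[[i]] <- segm
    }
    encs[[i]] <- bin_pair_observations(dat, prs[i, ], bin_w = bin_w,
                                       segmentation = segm,
                                       segregating_only = segregating_only)
  }
  fit <- if (method == "bw") baum_welch_fit(encs, model, free_parameters, ...)
         else likelihood_fit(encs, model, free_parameters, ...)
  fit$site_rates <- c(mu_gain = mk[[2]]$mu_gain, mu_loss = mk[[2]]$mu_loss)
  fit$rate_method <- rate_method
  fit$region_used <- use_region
  fit$region_test <- rtest
  fit$segmentations <- segmentations
  fit
}
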