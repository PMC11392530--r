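#' Discretize coalescence time into hidden-state intervals
#'
#' Interval boundaries are the quantiles of the pairwise coalescence-time
#' distribution under a guess demography, so every interval holds equal prior
#' coalescence probability. The representative time of an interval is the
#' conditional mean coalescence time within it.
#'
#' @param n_states number of hidden intervals (>= 2).
#' @param dem guess [demography()] (typically constant at a Watterson-based
#'   size estimate).
#' @return object of class `time_disc`: `boundaries` (length `n_states + 1`,
#'   first 0, last `Inf`) and `rep_time` per interval.
#' @export
discretize_time <- function(n_states, dem) {
  if (n_states < 2) stop("`n_states` must be >= 2")
  stopifnot(inherits(dem, "demography"))
  p <- seq(0, 1, length.out = n_states + 1)[-(n_states + 1)]
  bounds <- c(coal_time_quantile(dem, p), Inf)
  tmax <- coal_time_quantile(dem, 1 - 1e-9)
  rep_time <- numeric(n_states)
  for (k in seq_len(n_states)) {
    a <- bounds[k]
    b <- min(bounds[k + 1], tmax)
    g <- seq(a, b, length.out = 129)
    f <- exp(-coal_cumhaz(dem, g)) / (2 * pop_size_at(dem, g))
    w <- diff(g)
    fm <- (f[-1] + f[-length(f)]) / 2
    tm <- (g[-1] + g[-length(g)]) / 2
    mass <- sum(fm * w)
    rep_time[k] <- sum(tm * fm * w) / mass
  }
  structure(list(n_states = as.integer(n_states), boundaries = bounds,
                 rep_time = rep_time), class = "time_disc")
}

## Prior probability mass of each hidden interval under a demography.
state_prior <- function(disc, dem) {
  b <- disc$boundaries
  surv <- exp(-coal_cumhaz(dem, b[is.finite(b)]))
  p <- c(-diff(surv), surv[length(surv)])
  p / sum(p)
}

## Integration grid for the transition kernel: union of interval boundaries,
## epoch boundaries, representative times and a log-spaced fill up to the
## far tail of the coalescence distribution.
transition_grid <- function(disc, dem, n_fill = 400) {
  tmax <- max(coal_time_quantile(dem, 1 - 1e-12), max(disc$rep_time) * 4)
  g <- c(0, disc$boundaries[is.finite(disc$boundaries)], disc$rep_time,
         dem$boundaries, exp(seq(log(tmax * 1e-6), log(tmax), length.out = n_fill)))
  sort(unique(pmin(g[g >= 0], tmax)))
}

#' Per-site transition matrix of the pairwise SMC hidden Markov model
#'
#' Probability of moving between discretized coalescence-time states from one
#' position to the next. A recombination event occurs on the two branches of
#' length `t_k` with probability `1 - exp(-2 r t_k)` per site; given an
#' event, the detached lineage re-coalesces into the standing pair genealogy
#' (re-coalescence with the remnant of the cut branch is a silent event that
#' keeps the state). The re-coalescence density follows the piecewise-constant
#' demography and is integrated numerically over a fine time grid.
#'
#' @param disc a [discretize_time()] result.
#' @param dem a [demography()].
#' @param r per-site per-generation recombination rate (effective rate if
#'   selfing applies).
#' @return `n_states` x `n_states` stochastic matrix.
#' @export
transition_matrix <- function(disc, dem, r) {
  stopifnot(inherits(disc, "time_disc"), inherits(dem, "demography"))
  if (r < 0) stop("`r` must be >= 0")
  S <- disc$n_states
  if (r == 0) return(diag(S))
  g <- transition_grid(disc, dem)  # contains every representative time
  G <- length(g)
  dg <- diff(g)
  cmid <- 1 / (2 * pop_size_at(dem, (g[-1] + g[-G]) / 2))
  ## cumulative hazard C and I(s) = int_0^s exp(2C) du (exact per segment)
  C <- c(0, cumsum(cmid * dg))
  Iseg <- (exp(2 * C[-1]) - exp(2 * C[-G])) / (2 * cmid)
  I <- c(0, cumsum(Iseg))
  cnode <- 1 / (2 * pop_size_at(dem, g))
  ## f1(s): density of a non-silent re-coalescence below t_k (without the
  ## 1/t_k prefactor, which cancels in the normalization); by symmetry of
  ## the two partner branches below t_k it also equals the silent density.
  ## h(s): shape of the above-t_k re-coalescence density up to the
  ## k-dependent factor J exp(C_k).
  f1 <- exp(-2 * C) * I * cnode
  h <- exp(-C) * cnode
  midt <- (g[-1] + g[-G]) / 2
  dest <- findInterval(midt, disc$boundaries)
  seg1 <- (f1[-1] + f1[-G]) / 2 * dg
  seg2 <- (h[-1] + h[-G]) / 2 * dg
  ## per-destination cumulative masses shared by all source states
  M1 <- matrix(0, G - 1, S); M1[cbind(seq_len(G - 1), dest)] <- seg1
  cum1 <- apply(M1, 2, cumsum)
  M2 <- matrix(0, G - 1, S); M2[cbind(seq_len(G - 1), dest)] <- seg2
  suf2 <- apply(M2[(G - 1):1, , drop = FALSE], 2, cumsum)[(G - 1):1, , drop = FALSE]
  cumtot1 <- cumsum(seg1)
  A <- matrix(0, S, S)
  for (k in seq_len(S)) {
    tk <- disc$rep_time[k]
    ik <- findInterval(tk, g)  # tk is a grid point: g[ik] == tk
    nb <- ik - 1L              # segments fully below tk
    m <- if (nb >= 1L) cum1[nb, ] else numeric(S)
    silent <- if (nb >= 1L) cumtot1[nb] else 0
    Ck <- C[ik]
    J <- exp(-2 * Ck) * I[ik]
    if (ik <= G - 1) m <- m + J * exp(Ck) * suf2[ik, ]
    ## analytic tail beyond the grid goes to the last interval
    m[S] <- m[S] + J * exp(Ck - C[G])
    tot <- silent + sum(m)
    m <- m / tot
    silent <- silent / tot
    ## probability of any recombination event at this site
    p <- 1 - exp(-2 * r * tk)
    A[k, ] <- p * m
    A[k, k] <- A[k, k] + (1 - p) + p * silent
  }
  A / rowSums(A)
}

#' Per-state emission matrix over the global symbol alphabet
#'
#' Evaluates each marker's closed-form pair emission model at every hidden
#' state's representative time. Symbols are grouped per marker; each
#' (state, marker) block sums to 1.
#'
#' @param disc a [discretize_time()] result.
#' @param markers list of [marker_spec()].
#' @param region optional [region_model()]: lifts the asymmetric marker's
#'   symbols to the 9-symbol region-conditioned alphabet.
#' @return matrix `n_states` x `n_symbols` with a `symbols` attribute
#'   (data.frame: marker index and code per column).
#' @export
emission_matrix <- function(disc, markers, region = NULL) {
  S <- disc$n_states
  cols <- list()
  labs <- list()
  for (m in seq_along(markers)) {
    mk <- markers[[m]]
    if (is.null(mk$mu) && is.null(mk$mu_gain)) stop("marker without rates")
    if (mk$model == "symmetric") {
      e <- symmetric_pair_emission(mk, disc$rep_time)
      cols[[length(cols) + 1L]] <- e
      labs[[length(labs) + 1L]] <- data.frame(marker = m, code = c("id", "seg"))
    } else if (is.null(region)) {
      e <- asymmetric_site_emission(mk$mu_gain, mk$mu_loss, disc$rep_time)
      cols[[length(cols) + 1L]] <- e
      labs[[length(labs) + 1L]] <- data.frame(marker = m, code = c("2", "3", "4"))
    } else {
      e <- t(vapply(disc$rep_time, function(t)
        region_conditioned_emission(mk$mu_gain, mk$mu_loss, region, t),
        numeric(9)))
      cols[[length(cols) + 1L]] <- e
      labs[[length(labs) + 1L]] <- data.frame(marker = m,
                                              code = colnames(e))
    }
  }
  E <- do.call(cbind, cols)
  attr(E, "symbols") <- do.call(rbind, labs)
  E
}

## matrix power by repeated squaring (w >= 1 integer)
mat_pow <- function(A, w) {
  w <- as.integer(w)
  R <- diag(nrow(A))
  P <- A
  while (w > 0) {
    if (w %% 2L == 1L) R <- R %*% P
    P <- P %*% P
    w <- w %/% 2L
  }
  R
}

#' SMC model specification
#'
#' Bundles the time discretization, demography, recombination rate, marker
#' set and observation options of the pairwise SMC HMM.
#'
#' @param disc a [discretize_time()] result.
#' @param dem current [demography()].
#' @param r per-site per-generation recombination rate.
#' @param markers list of [marker_spec()] (rates used for emissions).
#' @param selfing selfing rate sigma; the transition matrix uses the
#'   effective rate `r_eff = r (1 - sigma/(2 - sigma))`.
#' @param region optional [region_model()] enabling the 9-symbol alphabet.
#' @param bin_w observation bin width in bp (1 = exact per-site HMM).
#' @return object of class `smc_model`.
#' @export
smc_model <- function(disc, dem, r, markers, selfing = 0, region = NULL,
                      bin_w = 100) {
  structure(list(disc = disc, dem = dem, r = r, markers = markers,
                 selfing = selfing, region = region, bin_w = as.integer(bin_w)),
            class = "smc_model")
}

## Assemble the HMM pieces (transition over one bin, log-emission table,
## initial distribution) for the current model parameters.
model_matrices <- function(model) {
  r_eff <- effective_recombination(model$r, model$selfing)
  A1 <- transition_matrix(model$disc, model$dem, r_eff)
  A <- if (model$bin_w > 1L) mat_pow(A1, model$bin_w) else A1
  E <- emission_matrix(model$disc, model$markers, model$region)
  list(A = A, E = E, logE = log(pmax(E, 1e-320)),
       pi = state_prior(model$disc, model$dem))
}

#' Forward-backward pass of the pairwise SMC HMM
#'
#' Scaled forward-backward over an encoded pair observation sequence. The
#' per-position posteriors are rescaled so each row sums to one.
#'
#' @param obs an encoded pair: either a `pair_obs` (per-site symbols, exact
#'   HMM) or a `pair_bins` (binned symbol counts) from
#'   [bin_pair_observations()].
#' @param model an [smc_model()].
#' @param posterior return the per-position posterior matrix.
#' @param xi return the expected transition-count matrix.
#' @return list: `loglik`, optional `posterior` (positions x states) and
#'   `xi` (states x states), plus the matrices used.
#' @export
forward_backward <- function(obs, model, posterior = TRUE, xi = FALSE) {
  mm <- model_matrices(model)
  logE_pos <- obs_log_emissions(obs, mm$logE)
  A <- if (inherits(obs, "pair_obs")) {
    if (model$bin_w != 1L) {
      r_eff <- effective_recombination(model$r, model$selfing)
      transition_matrix(model$disc, model$dem, r_eff)
    } else mm$A
  } else {
    if (obs$bin_w == model$bin_w) mm$A else {
      r_eff <- effective_recombination(model$r, model$selfing)
      mat_pow(transition_matrix(model$disc, model$dem, r_eff), obs$bin_w)
    }
  }
  out <- .hmm_fb_cpp(A, logE_pos, mm$pi, posterior, xi, FALSE)
  out$A <- A
  out$E <- mm$E
  out$pi <- mm$pi
  out
}

## Per-position (or per-bin) log emission rows for an encoded pair.
obs_log_emissions <- function(obs, logE) {
  if (inherits(obs, "pair_obs")) {
    sym <- obs$symbols
    keep <- !is.na(sym)
    out <- matrix(0, length(sym), nrow(logE))  # missing symbols emit log 1
    out[keep, ] <- t(logE)[sym[keep], , drop = FALSE]
    out
  } else if (inherits(obs, "pair_bins")) {
    obs$counts %*% t(logE)  # T x K times K x S
  } else stop("unsupported observation object")
}

## -------------------------------------------------------------------------
## Pair encoding: binned symbol counts

## number of sites of marker m at positions < b under round-robin placement
pattern_count_before <- function(pat, m, b) {
  res <- which(pat$pattern == m) - 1L
  q <- b %/% pat$period
  rem <- b %% pat$period
  q * length(res) + vapply(rem, function(x) sum(res < x), numeric(1))
}

#' Encode one haplotype pair as binned symbol counts
#'
#' Splits the sequence into fixed-width bins and counts, per bin, the number
#' of sites of each global observation symbol: identical/segregating for
#' symmetric markers, the methylation pair codes 2/3/4 for the asymmetric
#' marker (lifted to the 9-symbol region-conditioned alphabet when a
#' segmentation is supplied). Missing states are dropped (they emit equally
#' in all hidden states).
#'
#' @param dat a `sim_data` (or compatible) object.
#' @param pair integer vector of two haplotype indices.
#' @param bin_w bin width in bp.
#' @param segmentation optional [segment_methylation_regions()] result for
#'   this pair: enables the 9-symbol coding.
#' @param segregating_only restrict methylable sites to those polymorphic in
#'   the full sample.
#' @param markers optional subset of marker indices to include (e.g. `1L` for
#'   a SNP-only encoding).
#' @return object of class `pair_bins`: integer count matrix (bins x symbols)
#'   plus the symbol table.
#' @export
bin_pair_observations <- function(dat, pair, bin_w = 100,
                                  segmentation = NULL,
                                  segregating_only = FALSE,
                                  markers = NULL) {
  stopifnot(length(pair) == 2L)
  use <- if (is.null(markers)) seq_along(dat$markers) else markers
  L <- dat$L
  T_ <- as.integer(ceiling(L / bin_w))
  edges <- (0:T_) * bin_w
  cols <- list()
  labs <- list()
  for (m in use) {
    mk <- dat$markers[[m]]
    md <- dat$marker_data[[m]]
    if (mk$model == "symmetric") {
      tot <- total_sites_per_bin(dat, m, edges)
      seg_pos <- md$positions[md$states[pair[1], ] != md$states[pair[2], ]]
      seg <- tabulate(findInterval(seg_pos, edges), nbins = T_)
      cols[[length(cols) + 1L]] <- cbind(id = tot - seg, seg = seg)
      labs[[length(labs) + 1L]] <- data.frame(marker = m, code = c("id", "seg"))
    } else {
      pos <- md$positions
      s1 <- md$states[pair[1], ]
      s2 <- md$states[pair[2], ]
      if (segregating_only) {
        poly <- matrixStats_colAny(md$states)
        pos <- pos[poly]; s1 <- s1[poly]; s2 <- s2[poly]
      }
      code <- ifelse(s1 == 0 & s2 == 0, 1L, ifelse(s1 == 1 & s2 == 1, 2L, 3L))
      ok <- !is.na(code)
      if (is.null(segmentation)) {
        bins <- findInterval(pos[ok], edges)
        cnt <- matrix(0L, T_, 3)
        for (cc in 1:3) cnt[, cc] <- tabulate(bins[code[ok] == cc], nbins = T_)
        cols[[length(cols) + 1L]] <- cnt
        labs[[length(labs) + 1L]] <- data.frame(marker = m, code = c("2", "3", "4"))
      } else {
        status <- segmentation_status_at(segmentation, pos)
        idx <- (status - 1L) * 3L + code   # 1..9 in UU,UM,MM blocks
        bins <- findInterval(pos[ok], edges)
        cnt <- matrix(0L, T_, 9)
        for (cc in 1:9) cnt[, cc] <- tabulate(bins[idx[ok] == cc], nbins = T_)
        cols[[length(cols) + 1L]] <- cnt
        labs[[length(labs) + 1L]] <-
          data.frame(marker = m,
                     code = paste0(rep(c("UU", "UM", "MM"), each = 3), ":",
                                   rep(c("2", "3", "4"), 3)))
      }
    }
  }
  counts <- do.call(cbind, cols)
  structure(list(counts = counts, symbols = do.call(rbind, labs),
                 bin_w = as.integer(bin_w), L = L, pair = pair),
            class = "pair_bins")
}

## any difference from the first row (polymorphic among the sample);
## missing entries do not count as differences
matrixStats_colAny <- function(st) {
  d <- st != matrix(st[1, ], nrow(st), ncol(st), byrow = TRUE)
  colSums(d, na.rm = TRUE) > 0
}

total_sites_per_bin <- function(dat, m, edges) {
  T_ <- length(edges) - 1L
  if (!is.null(dat$pattern)) {
    cb <- pattern_count_before(dat$pattern, m, pmin(edges, dat$L))
    diff(cb)
  } else {
    ## methylome layout: marker 1 is the complement of the annotated sites
    ann <- tabulate(findInterval(dat$meth$positions, edges), nbins = T_)
    if (m == 1L) pmin(diff(pmin(edges, dat$L)), diff(edges)) - ann else ann
  }
}

## -------------------------------------------------------------------------
## Fitting

## all (or subsampled) haplotype pairs as a 2-column matrix
haplotype_pairs <- function(n, max_haplotypes = NULL) {
  k <- if (is.null(max_haplotypes)) n else min(n, max_haplotypes)
  t(utils::combn(k, 2))
}

default_size_groups <- function(S) {
  rep(seq_len(ceiling(S / 2)), each = 2)[seq_len(S)]
}

## parameter vector <-> model
pack_params <- function(model, free, size_groups) {
  p <- numeric(0)
  if ("sizes" %in% free$what) {
    sz <- pop_size_at(model$dem, model$disc$rep_time)
    grp_sz <- vapply(split(sz, size_groups), mean, numeric(1))
    p <- c(p, log(grp_sz))
  }
  if ("r" %in% free$what) p <- c(p, log(model$r))
  for (m in free$rate_markers) {
    mk <- model$markers[[m]]
    p <- c(p, if (mk$model == "symmetric") log(mk$mu)
           else c(log(mk$mu_gain), log(mk$mu_loss)))
  }
  p
}

unpack_params <- function(p, model, free, size_groups) {
  i <- 0L
  if ("sizes" %in% free$what) {
    G <- length(unique(size_groups))
    sz_grp <- exp(p[i + seq_len(G)]); i <- i + G
    sz <- sz_grp[size_groups]
    b <- model$disc$boundaries
    model$dem <- demography(b[is.finite(b)], sz)
  }
  if ("r" %in% free$what) { model$r <- exp(p[i + 1L]); i <- i + 1L }
  for (m in free$rate_markers) {
    mk <- model$markers[[m]]
    if (mk$model == "symmetric") {
      model$markers[[m]]$mu <- exp(p[i + 1L]); i <- i + 1L
    } else {
      model$markers[[m]]$mu_gain <- exp(p[i + 1L])
      model$markers[[m]]$mu_loss <- exp(p[i + 2L]); i <- i + 2L
    }
  }
  model
}

## box constraints (log scale) matching the pack_params layout
param_bounds <- function(model, free, size_groups) {
  lo <- numeric(0); hi <- numeric(0)
  if ("sizes" %in% free$what) {
    G <- length(unique(size_groups))
    lo <- c(lo, rep(log(10), G)); hi <- c(hi, rep(log(1e8), G))
  }
  if ("r" %in% free$what) { lo <- c(lo, log(1e-13)); hi <- c(hi, log(1e-3)) }
  for (m in free$rate_markers) {
    k <- if (model$markers[[m]]$model == "symmetric") 1L else 2L
    lo <- c(lo, rep(log(1e-12), k)); hi <- c(hi, rep(log(0.4), k))
  }
  list(lower = lo, upper = hi)
}

normalize_free <- function(free_parameters, model) {
  if (is.null(free_parameters)) return(list(what = character(0), rate_markers = integer(0)))
  what <- intersect(free_parameters, c("sizes", "r"))
  rate_markers <- integer(0)
  if ("rates" %in% free_parameters) {
    rate_markers <- seq_along(model$markers)[-1]  # reference marker 1 fixed
  }
  ## explicit per-marker selection, e.g. "rate2"
  rm2 <- as.integer(sub("rate", "", free_parameters[grepl("^rate[0-9]+$",
                                                          free_parameters)]))
  if (length(rm2)) rate_markers <- sort(unique(c(rate_markers, rm2)))
  list(what = what, rate_markers = rate_markers)
}

## expected complete-data log-likelihood of the aggregated sufficient stats
q_function <- function(model, stats) {
  mm <- model_matrices(model)
  qA <- sum(stats$xi * log(pmax(mm$A, 1e-320)))
  qE <- sum(stats$ecounts * log(pmax(mm$E, 1e-320)))
  qP <- sum(stats$gamma1 * log(pmax(mm$pi, 1e-320)))
  qA + qE + qP
}

#' Baum-Welch fit of the multi-marker SMC model
#'
#' Composite-likelihood expectation-maximization over all supplied haplotype
#' pairs: the E-step accumulates expected transition counts, initial-state
#' posteriors and expected symbol counts per hidden state across pairs; the
#' M-step re-estimates the free parameters (tied epoch sizes on the fixed
#' time grid, recombination rate, free marker rates) by numerically
#' maximizing the expected complete-data log-likelihood over log-parameters
#' (a generalized EM step, so the composite likelihood never decreases).
#'
#' @param encs list of encoded pairs from [bin_pair_observations()].
#' @param model starting [smc_model()].
#' @param free_parameters character vector: any of `"sizes"`, `"r"`,
#'   `"rates"` (all non-reference marker rates); `NULL` evaluates the model
#'   without updating.
#' @param size_groups integer vector tying hidden intervals to shared size
#'   parameters (default: adjacent pairs of intervals).
#' @param max_iter,tol maximum EM iterations and relative log-likelihood
#'   convergence tolerance.
#' @return object of class `smc_fit`: final `model`, `demography`, `r`,
#'   `markers`, non-decreasing `loglik_trajectory`, `converged`,
#'   `iterations` and per-pair log-likelihood contributions.
#' @export
baum_welch_fit <- function(encs, model, free_parameters = c("sizes"),
                           size_groups = NULL, max_iter = 30, tol = 1e-5) {
  free <- normalize_free(free_parameters, model)
  if (is.null(size_groups)) size_groups <- default_size_groups(model$disc$n_states)
  traj <- numeric(0)
  n_free <- length(pack_params(model, free, size_groups))
  converged <- FALSE
  iter_done <- 0L
  est <- NULL
  for (iter in seq_len(max_iter)) {
    est <- e_step(encs, model)
    traj <- c(traj, est$loglik)
    iter_done <- iter
    if (n_free == 0L) {
      return(finish_fit(model, traj, TRUE, iter, est$pair_logliks))
    }
    if (iter > 1) {
      rel <- (traj[iter] - traj[iter - 1]) / abs(traj[iter - 1])
      if (abs(rel) < tol) { converged <- TRUE; break }
    }
    p0 <- pack_params(model, free, size_groups)
    bb <- param_bounds(model, free, size_groups)
    obj <- function(p) {
      q <- try(-q_function(unpack_params(p, model, free, size_groups), est),
               silent = TRUE)
      if (inherits(q, "try-error") || !is.finite(q)) 1e15 else q
    }
    ## partial M-step: any Q improvement suffices for the EM guarantee
    opt <- stats::nlminb(p0, obj, lower = bb$lower, upper = bb$upper,
                         control = list(iter.max = 40, eval.max = 150))
    if (is.finite(opt$objective) && opt$objective < -q_function(model, est)) {
      model <- unpack_params(opt$par, model, free, size_groups)
    }
    ## free marker rates move slowly along the EM ridge against the epoch
    ## sizes; interleave a conditional maximization of the actual composite
    ## likelihood over them (still a generalized EM: the optimizer never
    ## returns a worse value than its start). The recombination rate is
    ## deliberately left to the expected-count (Q) update: how Baum-Welch
    ## versus direct likelihood treats r is part of the method contrast.
    fast <- list(what = character(0),
                 rate_markers = free$rate_markers)
    if (length(fast$rate_markers) && iter %% 3 == 0) {
      model2 <- try(profile_rate_refine(encs, model, fast, max_eval = 12),
                    silent = TRUE)
      if (!inherits(model2, "try-error")) model <- model2
    }
  }
  fast <- list(what = character(0),
               rate_markers = free$rate_markers)
  if (length(fast$rate_markers)) {
    model2 <- try(profile_rate_refine(encs, model, fast, max_eval = 40),
                  silent = TRUE)
    if (!inherits(model2, "try-error")) {
      est2 <- e_step(encs, model2)
      if (est2$loglik >= traj[length(traj)]) {
        model <- model2
        est <- est2
        traj <- c(traj, est2$loglik)
      }
    }
    ## beyond the finite-site saturation level the likelihood is flat (or
    ## one-sidedly so) in the rate and any value up to infinity fits; report
    ## the smallest rate within 0.5 log-units of the maximum, which is the
    ## identified value for unsaturated markers and the defensible lower
    ## edge of the flat region for saturated ones
    for (m in fast$rate_markers) {
      model <- shrink_rate_to_profile_edge(encs, model, m)
    }
  }
  finish_fit(model, traj, converged, iter_done, est$pair_logliks)
}

## walk the marker's rate down while the composite likelihood stays within
## `tol` log-units of its value at the fitted rate
shrink_rate_to_profile_edge <- function(encs, model, m, tol = 0.5,
                                        step = 1.3) {
  comp_ll <- function(mod) {
    mm <- model_matrices(mod)
    s <- 0
    for (obs in encs) {
      s <- s + .hmm_fb_cpp(mm$A, obs_log_emissions(obs, mm$logE), mm$pi,
                           FALSE, FALSE, TRUE)$loglik
    }
    s
  }
  base <- comp_ll(model)
  for (i in 1:40) {
    cand <- model
    if (cand$markers[[m]]$model == "symmetric") {
      cand$markers[[m]]$mu <- cand$markers[[m]]$mu / step
      if (cand$markers[[m]]$mu < 1e-12) break
    } else {
      cand$markers[[m]]$mu_gain <- cand$markers[[m]]$mu_gain / step
      cand$markers[[m]]$mu_loss <- cand$markers[[m]]$mu_loss / step
      if (cand$markers[[m]]$mu_gain < 1e-12) break
    }
    if (comp_ll(cand) < base - tol) break
    model <- cand
  }
  model
}

## direct optimization of the composite likelihood over the non-size free
## parameters (recombination rate, marker rates), epoch sizes held fixed
profile_rate_refine <- function(encs, model, free, max_eval = 60) {
  p0 <- pack_params(model, free, size_groups = integer(0))
  bb <- param_bounds(model, free, size_groups = integer(0))
  nll <- function(p) {
    out <- try({
      mod <- unpack_params(p, model, free, size_groups = integer(0))
      mm <- model_matrices(mod)
      ll <- 0
      for (obs in encs) {
        logE_pos <- obs_log_emissions(obs, mm$logE)
        ll <- ll + .hmm_fb_cpp(mm$A, logE_pos, mm$pi, FALSE, FALSE, TRUE)$loglik
      }
      -ll
    }, silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) 1e15 else out
  }
  f0 <- nll(p0)
  opt <- stats::nlminb(p0, nll, lower = bb$lower, upper = bb$upper,
                       control = list(eval.max = max_eval, iter.max = max_eval))
  ## under saturation the likelihood is flat in the rate and the optimizer
  ## can drift to a box bound with no real improvement; only accept moves
  ## that actually raise the likelihood
  if (!is.finite(opt$objective) || f0 - opt$objective < 0.01) return(model)
  unpack_params(opt$par, model, free, size_groups = integer(0))
}

e_step <- function(encs, model) {
  mm <- model_matrices(model)
  S <- model$disc$n_states
  K <- ncol(mm$E)
  xi <- matrix(0, S, S)
  gamma1 <- numeric(S)
  ecounts <- matrix(0, S, K)
  pls <- numeric(length(encs))
  for (i in seq_along(encs)) {
    obs <- encs[[i]]
    logE_pos <- obs_log_emissions(obs, mm$logE)
    A <- if (inherits(obs, "pair_bins") && obs$bin_w != model$bin_w) {
      mat_pow(transition_matrix(model$disc, model$dem,
                                effective_recombination(model$r, model$selfing)),
              obs$bin_w)
    } else mm$A
    fb <- .hmm_fb_cpp(A, logE_pos, mm$pi, TRUE, TRUE, FALSE)
    pls[i] <- fb$loglik
    xi <- xi + fb$xi
    gamma1 <- gamma1 + fb$gamma1
    ecounts <- ecounts + t(fb$posterior) %*% obs$counts
  }
  list(loglik = sum(pls), xi = xi, gamma1 = gamma1, ecounts = ecounts,
       pair_logliks = pls)
}

finish_fit <- function(model, traj, converged, iterations, pls) {
  rates <- lapply(model$markers, function(mk)
    if (mk$model == "symmetric") c(mu = mk$mu)
    else c(mu_gain = mk$mu_gain, mu_loss = mk$mu_loss))
  structure(list(model = model, demography = model$dem, r = model$r,
                 rates = rates, loglik_trajectory = traj,
                 loglik = traj[length(traj)], converged = converged,
                 iterations = iterations, pair_logliks = pls),
            class = "smc_fit")
}

#' @export
print.smc_fit <- function(x, ...) {
  cat(sprintf("<smc_fit> loglik = %.2f after %d iteration(s)%s\n",
              x$loglik, x$iterations,
              if (x$converged) "" else " (not converged)"))
  cat(sprintf("  r = %g\n", x$r))
  print(x$demography)
  invisible(x)
}

#' Direct likelihood optimization of the multi-marker SMC model
#'
#' Maximizes the composite pairwise log-likelihood directly with a
#' quasi-Newton optimizer over the log-transformed free parameters. Slower
#' per step than Baum-Welch but not subject to the EM fixed-point; the
#' experiments run it on a subsample of pairs to limit computation.
#'
#' @inheritParams baum_welch_fit
#' @param max_eval maximum objective evaluations.
#' @return an `smc_fit`; its likelihood is never below the starting model's.
#' @export
likelihood_fit <- function(encs, model, free_parameters = c("sizes", "r"),
                           size_groups = NULL, max_eval = 400) {
  free <- normalize_free(free_parameters, model)
  if (is.null(size_groups)) size_groups <- default_size_groups(model$disc$n_states)
  p0 <- pack_params(model, free, size_groups)
  if (length(p0) == 0L) stop("no free parameters and no evaluation requested")
  bb <- param_bounds(model, free, size_groups)
  nll <- function(p) {
    out <- try({
      mod <- unpack_params(p, model, free, size_groups)
      mm <- model_matrices(mod)
      ll <- 0
      for (obs in encs) {
        logE_pos <- obs_log_emissions(obs, mm$logE)
        ll <- ll + .hmm_fb_cpp(mm$A, logE_pos, mm$pi, FALSE, FALSE, TRUE)$loglik
      }
      -ll
    }, silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) 1e15 else out
  }
  ll0 <- -nll(p0)
  opt <- stats::nlminb(p0, nll, lower = bb$lower, upper = bb$upper,
                       control = list(eval.max = max_eval, iter.max = max_eval))
  best_p <- opt$par
  best_ll <- -opt$objective
  converged <- opt$convergence == 0
  if (!is.finite(best_ll) || best_ll < ll0) {
    best_p <- p0
    best_ll <- ll0
    converged <- FALSE
  }
  model <- unpack_params(best_p, model, free, size_groups)
  est <- e_step(encs, model)
  finish_fit(model, c(ll0, best_ll), converged, 1L, est$pair_logliks)
}

## -------------------------------------------------------------------------
## High-level fit drivers

#' Initial SMC model from the data
#'
#' Builds a starting model: constant population size from the reference
#' marker's Watterson estimate (`N0 = theta_W / (4 mu1)`), equal-mass time
#' discretization under it, and the supplied marker rates.
#'
#' @param dat a `sim_data` (or compatible) object.
#' @param markers marker list with rates (reference marker first).
#' @param n_states number of hidden intervals.
#' @param r starting recombination rate.
#' @param selfing selfing rate.
#' @param region optional [region_model()].
#' @param bin_w observation bin width in bp.
#' @return an [smc_model()].
#' @export
init_model <- function(dat, markers, n_states = 20, r = 1e-8, selfing = 0,
                       region = NULL, bin_w = 100) {
  th <- watterson_theta(length(dat$marker_data[[1]]$positions),
                        dat$marker_data[[1]]$total_sites, dat$n)
  mu1 <- if (markers[[1]]$model == "symmetric") markers[[1]]$mu
         else stop("reference marker must be symmetric")
  N0 <- max(th / (4 * mu1), 10)
  dem0 <- demography(0, N0)
  disc <- discretize_time(n_states, dem0)
  smc_model(disc, dem0, r, markers, selfing = selfing, region = region,
            bin_w = bin_w)
}

#' Fit the SMC using the nucleotide marker only
#'
#' The single-marker PSMC'-style fit: methylation or other marker tracks are
#' ignored and only identical/segregating nucleotide observations enter the
#' likelihood.
#'
#' @param dat a `sim_data` (or compatible) object.
#' @param mu1 known per-site mutation rate of the nucleotide marker.
#' @param method `"bw"` (Baum-Welch) or `"lh"` (direct likelihood).
#' @param free_parameters parameters to estimate.
#' @param n_states,bin_w,r0,selfing,max_haplotypes model and data options;
#'   `max_haplotypes` subsamples haplotypes before forming pairs.
#' @param ... passed to the fitting routine.
#' @return an `smc_fit`.
#' @export
fit_snp_only <- function(dat, mu1, method = c("bw", "lh"),
                         free_parameters = c("sizes", "r"),
                         n_states = 20, bin_w = 100, r0 = 1e-8, selfing = 0,
                         max_haplotypes = NULL, ...) {
  method <- match.arg(method)
  mk <- list(dat$markers[[1]])
  mk[[1]]$mu <- mu1
  model <- init_model(dat, mk, n_states = n_states, r = r0, selfing = selfing,
                      bin_w = bin_w)
  prs <- haplotype_pairs(dat$n, max_haplotypes)
  encs <- lapply(seq_len(nrow(prs)), function(i)
    bin_pair_observations(dat, prs[i, ], bin_w = bin_w, markers = 1L))
  if (method == "bw") baum_welch_fit(encs, model, free_parameters, ...)
  else likelihood_fit(encs, model, free_parameters, ...)
}

#' Fit the SMC jointly on all generic markers
#'
#' The multi-marker fit: identical/segregating observations of every marker
#' class enter the likelihood with their own emission probabilities. Unknown
#' marker rates can be estimated (`free_parameters` including `"rates"`), or
#' pre-estimated from diversity ratios via [estimate_rates_auto()].
#'
#' @inheritParams fit_snp_only
#' @param mu2 rate of the second marker (`NULL` to estimate it as a free
#'   emission parameter).
#' @return an `smc_fit`.
#' @export
fit_multimarker <- function(dat, mu1, mu2 = NULL, method = c("bw", "lh"),
                            free_parameters = c("sizes", "r"),
                            n_states = 20, bin_w = 100, r0 = 1e-8, selfing = 0,
                            max_haplotypes = NULL, ...) {
  method <- match.arg(method)
  mk <- dat$markers
  mk[[1]]$mu <- mu1
  if (!is.null(mu2)) {
    mk[[2]]$mu <- mu2
  } else {
    free_parameters <- union(free_parameters, "rates")
    ## moment start: finite-site-adjusted diversity ratio, refined by the fit
    start <- tryCatch(
      suppressWarnings(watterson_rate_estimate(diversity_summary(dat)[c(1, 2), ],
                                               mu1)),
      error = function(e) mu1 * 10)
    mk[[2]]$mu <- min(max(start, 1e-9), 0.3)
  }
  model <- init_model(dat, mk, n_states = n_states, r = r0, selfing = selfing,
                      bin_w = bin_w)
  prs <- haplotype_pairs(dat$n, max_haplotypes)
  encs <- lapply(seq_len(nrow(prs)), function(i)
    bin_pair_observations(dat, prs[i, ], bin_w = bin_w))
  if (method == "bw") baum_welch_fit(encs, model, free_parameters, ...)
  else likelihood_fit(encs, model, free_parameters, ...)
}
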