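# Monte-Carlo oracles: mechanistic simulation of the marker chains on the
# two-branch pair genealogy, independent of the closed-form emissions.

# symmetric nbs-state chain: jump counts are Poisson, each jump resamples
# uniformly among the other states
mc_jump_chain <- function(start, k, nbs) {
  st <- start
  if (max(k) == 0) return(st)
  for (j in seq_len(max(k))) {
    act <- which(k >= j)
    if (!length(act)) break
    prop <- floor(stats::runif(length(act)) * (nbs - 1))
    cur <- st[act]
    st[act] <- ifelse(prop >= cur, prop + 1L, prop)
  }
  st
}

mc_symmetric_pair <- function(nbs, mu, t, reps) {
  anc <- floor(stats::runif(reps) * nbs)
  k1 <- stats::rpois(reps, mu * t)
  k2 <- stats::rpois(reps, mu * t)
  s1 <- mc_jump_chain(anc, k1, nbs)
  s2 <- mc_jump_chain(anc, k2, nbs)
  mean(s1 == s2)
}

# asymmetric two-state chain by vectorized Gillespie simulation
mc_two_state <- function(start, mu_gain, mu_loss, t, reps) {
  st <- start
  remaining <- rep(t, reps)
  repeat {
    rate <- ifelse(st == 1L, mu_loss, mu_gain)
    act <- rate > 0 & remaining > 0
    if (!any(act)) break
    wait <- stats::rexp(sum(act), rate[act])
    idx <- which(act)
    flip <- wait < remaining[idx]
    remaining[idx] <- remaining[idx] - wait
    remaining[idx][!flip] <- 0
    st[idx[flip]] <- 1L - st[idx[flip]]
  }
  st
}

mc_asymmetric_pair <- function(mu_gain, mu_loss, t, reps, ancestral = NULL) {
  pm <- mu_gain / (mu_gain + mu_loss)
  anc <- if (is.null(ancestral)) as.integer(stats::runif(reps) < pm)
         else rep(as.integer(ancestral == "M"), reps)
  s1 <- mc_two_state(anc, mu_gain, mu_loss, t, reps)
  s2 <- mc_two_state(anc, mu_gain, mu_loss, t, reps)
  c(uu = mean(s1 == 0 & s2 == 0), mm = mean(s1 == 1 & s2 == 1),
    discordant = mean(s1 != s2))
}

# coupled region + site chains on the two-branch tree: region events reset
# the site to the region's new status; the leaf site state therefore evolves
# from the last reset (or from the root state, which equals the root region
# status)
mc_region_site_pair <- function(mu_sm, mu_su, mu_rm, mu_ru, t, reps) {
  pr <- mu_rm / (mu_rm + mu_ru)
  ranc <- as.integer(stats::runif(reps) < pr)
  branch <- function(ranc) {
    st <- ranc
    remaining <- rep(t, length(ranc))
    last_reset <- rep(NA_real_, length(ranc))
    repeat {
      rate <- ifelse(st == 1L, mu_ru, mu_rm)
      act <- rate > 0 & remaining > 0
      if (!any(act)) break
      wait <- stats::rexp(sum(act), rate[act])
      idx <- which(act)
      flip <- wait < remaining[idx]
      remaining[idx] <- remaining[idx] - wait
      remaining[idx][!flip] <- 0
      st[idx[flip]] <- 1L - st[idx[flip]]
      last_reset[idx[flip]] <- remaining[idx[flip]]
    }
    list(status = st, reset_left = last_reset)
  }
  leaf_site <- function(b) {
    start <- ifelse(is.na(b$reset_left), ranc, b$status)
    dur <- ifelse(is.na(b$reset_left), t, b$reset_left)
    ## site chain from the last reset point; resets erase earlier history,
    ## but site events between resets on the path above the last reset do
    ## not matter for the leaf state
    mc_two_state_var(start, mu_sm, mu_su, dur)
  }
  b1 <- branch(ranc)
  b2 <- branch(ranc)
  site1 <- leaf_site(b1)
  site2 <- leaf_site(b2)
  rstat <- ifelse(b1$status == 0 & b2$status == 0, "UU",
                  ifelse(b1$status == 1 & b2$status == 1, "MM", "UM"))
  scode <- ifelse(site1 == 0 & site2 == 0, "2",
                  ifelse(site1 == 1 & site2 == 1, "3", "4"))
  table(factor(paste0(rstat, ":", scode),
               levels = paste0(rep(c("UU", "UM", "MM"), each = 3), ":",
                               rep(c("2", "3", "4"), 3)))) / length(ranc)
}

# two-state Gillespie with per-replicate durations
mc_two_state_var <- function(start, mu_gain, mu_loss, dur) {
  st <- start
  remaining <- dur
  repeat {
    rate <- ifelse(st == 1L, mu_loss, mu_gain)
    act <- rate > 0 & remaining > 0
    if (!any(act)) break
    wait <- stats::rexp(sum(act), rate[act])
    idx <- which(act)
    flip <- wait < remaining[idx]
    remaining[idx] <- remaining[idx] - wait
    remaining[idx][!flip] <- 0
    st[idx[flip]] <- 1L - st[idx[flip]]
  }
  st
}

# brute-force HMM likelihood by path enumeration
enumerate_loglik <- function(A, E, pi0, sym) {
  S <- nrow(A)
  T_ <- length(sym)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  lik <- sum(apply(paths, 1, function(p) {
    v <- pi0[p[1]] * E[p[1], sym[1]]
    for (t in seq_len(T_)[-1]) v <- v * A[p[t - 1], p[t]] * E[p[t], sym[t]]
    v
  }))
  log(lik)
}

# two-marker dataset under a constant population, small scale
small_two_marker_data <- function(seed, n = 6, L = 5e5, mu2 = 1e-4,
                                  N = 1e4, r = 1e-8) {
  set.seed(seed)
  cfg <- sim_config(n, L, r = r, markers = list(
    marker_spec("m1", 4, mu = 1e-8, fraction = 0.98),
    marker_spec("m2", 2, mu = mu2, fraction = 0.02)))
  simulate_dataset(cfg, demography(0, N))
}
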