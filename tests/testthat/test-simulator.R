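one_marker <- list(marker_spec("m1", 4, mu = 1e-8, fraction = 1))

test_that("r = 0 yields a single marginal tree spanning the sequence", {
  set.seed(1)
  cfg <- sim_config(4, 1e5, r = 0, markers = one_marker)
  arg <- simulate_arg(cfg, demography(0, 1e4))
  expect_length(arg$span, 1)
  expect_equal(sum(arg$span), 1e5)
  expect_true(all(arg$time[5:7, 1] > 0))
  expect_error(sim_config(4, 0, r = 0), "zero-length")
})

test_that("pairwise TMRCA matches the coalescent expectation 2N", {
  set.seed(2)
  cfg <- sim_config(2, 100, r = 0, markers = one_marker)
  dem <- demography(0, 5000)
  tm <- replicate(1500, simulate_arg(cfg, dem)$tmrca[1])
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * 5000), 3 * se)
})

test_that("the number of marginal trees grows with rL", {
  set.seed(3)
  dem <- demography(0, 1e4)
  counts <- vapply(c(5e-9, 5e-8), function(r) {
    cfg <- sim_config(4, 5e5, r = r, markers = one_marker)
    mean(replicate(3, length(simulate_arg(cfg, dem)$span)))
  }, numeric(1))
  expect_gt(counts[2], counts[1] * 3)
})

test_that("selfing rescales the effective recombination rate", {
  expect_equal(effective_recombination(1e-8, 0), 1e-8)
  F <- 0.9 / (2 - 0.9)
  expect_equal(effective_recombination(1e-8, 0.9), 1e-8 * (1 - F))
  set.seed(4)
  cfg_out <- sim_config(4, 5e5, r = 1e-7, selfing = 0,  markers = one_marker)
  cfg_self <- sim_config(4, 5e5, r = 1e-7, selfing = 0.9, markers = one_marker)
  dem <- demography(0, 1e4)
  n_out <- mean(replicate(3, length(simulate_arg(cfg_out, dem)$span)))
  n_self <- mean(replicate(3, length(simulate_arg(cfg_self, dem)$span)))
  expect_lt(n_self, n_out * 0.5)
})

test_that("zero mutation rates give zero polymorphic sites", {
  set.seed(5)
  cfg <- sim_config(4, 1e5, r = 1e-8,
                    markers = list(marker_spec("m1", 4, mu = 0, fraction = 1)))
  dat <- simulate_dataset(cfg, demography(0, 1e4))
  expect_length(dat$marker_data[[1]]$positions, 0)
})

test_that("segregating sites match 4 N mu L for a pair", {
  set.seed(6)
  cfg <- sim_config(2, 2e5, r = 1e-8,
                    markers = list(marker_spec("m1", 4, mu = 5e-8, fraction = 1)))
  dem <- demography(0, 1e4)
  S <- replicate(40, length(simulate_dataset(cfg, dem)$marker_data[[1]]$positions))
  expected <- 4 * 1e4 * 5e-8 * 2e5   # = 400
  se <- stats::sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("Watterson's theta of marker 1 is close to 4 N mu", {
  dat <- small_two_marker_data(7, n = 8, L = 1e6)
  ds <- diversity_summary(dat)
  ## theta per site, expectation 4e-4; binomial-ish 3 SE on the seg count
  th <- ds$theta_w[1]
  a_n <- sum(1 / (1:7))
  se <- sqrt(ds$n_segregating[1]) / (a_n * ds$n_sites[1]) * 3
  expect_lt(abs(th - 4e-4), 3 * se)
})

test_that("hyper-mutable marker saturates below 1/2 discordance for a pair", {
  set.seed(8)
  cfg <- sim_config(2, 2e5, r = 1e-8, markers = list(
    marker_spec("m1", 4, mu = 1e-8, fraction = 0.9),
    marker_spec("m2", 2, mu = 1e-2, fraction = 0.1)))
  dat <- simulate_dataset(cfg, demography(0, 1e4))
  frac <- length(dat$marker_data[[2]]$positions) / dat$marker_data[[2]]$total_sites
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.55)
})

test_that("pair symbol frequencies match the closed-form emissions given the TMRCA", {
  ## conservation invariant: counts of segregating marker-2 sites, aggregated
  ## over trees, against the Eq.-style expectation sum(sites_in_span * P(seg|t))
  set.seed(9)
  cfg <- sim_config(2, 1e6, r = 1e-8, markers = list(
    marker_spec("m1", 4, mu = 1e-8, fraction = 0.98),
    marker_spec("m2", 2, mu = 1e-4, fraction = 0.02)))
  dem <- demography(0, 1e4)
  arg <- simulate_arg(cfg, dem)
  dat <- overlay_marker_mutations(arg, cfg$markers)
  m2 <- marker_spec("m2", 2, mu = 1e-4)
  pseg <- symmetric_pair_emission(m2, arg$tmrca)[, "segregating"]
  sites_per_tree <- diff(smcmark:::pattern_count_before(
    dat$pattern, 2, c(0, cumsum(arg$span))))
  expected <- sum(sites_per_tree * pseg)
  variance <- sum(sites_per_tree * pseg * (1 - pseg))
  observed <- length(dat$marker_data[[2]]$positions)
  expect_lt(abs(observed - expected), 4 * sqrt(variance))
})

test_that("fixtures are reproducible and carry their truth demography", {
  d1 <- generate_fixture("constant", seed = 1, n_haplotypes = 4,
                         sequence_length = 1e5)
  d2 <- generate_fixture("constant", seed = 1, n_haplotypes = 4,
                         sequence_length = 1e5)
  expect_identical(d1$marker_data[[1]]$positions, d2$marker_data[[1]]$positions)
  expect_identical(d1$marker_data[[2]]$states, d2$marker_data[[2]]$states)
  expect_error(generate_fixture("no_such", 1), "arg")
  bf <- generate_fixture("bottleneck_fig2A", seed = 2, n_haplotypes = 4,
                         sequence_length = 1e5)
  dem <- bf$truth$demography
  expect_equal(max(dem$sizes) / min(dem$sizes), 10)  # 10-fold bottleneck
  expect_equal(max(dem$sizes), 10000)
})

test_that("methylome simulation: stationarity, region truth, frozen limit", {
  set.seed(10)
  mks <- list(marker_spec("snp", 4, mu = 7e-9, fraction = 0.9),
              marker_spec("meth", 2, mu_gain = 3.5e-4, mu_loss = 1.5e-3,
                          fraction = 0.1))
  cfg <- sim_config(6, 2e5, r = 1e-8, markers = mks,
                    region = NULL, meth_fraction = 0.1)
  dat <- simulate_dataset(cfg, demography(0, 1e4))
  expect_s3_class(dat, "sim_data")
  ## site-only mode: genome-wide methylated fraction near the stationary level
  pm <- 3.5e-4 / (3.5e-4 + 1.5e-3)
  expect_lt(abs(mean(dat$meth$states) - pm), 0.05)
  ## frozen epimutation: every haplotype carries the ancestral pattern
  mks0 <- list(marker_spec("snp", 4, mu = 7e-9, fraction = 0.9),
               marker_spec("meth", 2, mu_gain = 0, mu_loss = 0,
                           fraction = 0.1))
  cfg0 <- sim_config(4, 5e4, r = 1e-8, markers = mks0, meth_fraction = 0.1)
  dat0 <- simulate_dataset(cfg0, demography(0, 1e4))
  expect_true(all(dat0$meth$states == rep(dat0$meth$states[1, ],
                                          each = nrow(dat0$meth$states))))
  ## region length larger than the sequence is rejected
  cfgbad <- sim_config(4, 500, r = 0, markers = mks,
                       region = region_model(2e-4, 1e-3, 1000))
  expect_error(simulate_dataset(cfgbad, demography(0, 1e4)), "region length")
})

test_that("region-only epimutation matches the region-scale emission", {
  set.seed(11)
  mks <- list(marker_spec("snp", 4, mu = 7e-9, fraction = 0.9),
              marker_spec("meth", 2, mu_gain = 0, mu_loss = 0, fraction = 0.1))
  cfg <- sim_config(2, 1e6, r = 1e-8, markers = mks,
                    region = region_model(2e-4, 1e-3, 1000),
                    meth_fraction = 0.1)
  dem <- demography(0, 1e4)
  arg <- simulate_arg(cfg, dem)
  dat <- simulate_methylome(arg, cfg)
  ## per-region pair status against the asymmetric emission at region scale,
  ## evaluated at the true TMRCA of the region midpoint
  reg <- dat$meth$regions
  mid <- (reg[, 1] + reg[, 2]) / 2
  edges <- cumsum(arg$span)
  tmid <- arg$tmrca[findInterval(mid, c(0, edges), rightmost.closed = TRUE)]
  e <- asymmetric_site_emission(2e-4, 1e-3, tmid)
  s1 <- dat$meth$region_leaf[1, ]
  s2 <- dat$meth$region_leaf[2, ]
  disc_obs <- sum(s1 != s2)
  expected <- sum(e[, "discordant"])
  vr <- sum(e[, "discordant"] * (1 - e[, "discordant"]))
  expect_lt(abs(disc_obs - expected), 4 * sqrt(vr) + 3)
})

test_that("methylable fraction is configurable between 2 and 20 percent", {
  for (f in c(0.02, 0.2)) {
    set.seed(12)
    dat <- generate_fixture("methylome_fig5", seed = 12, n_haplotypes = 4,
                            sequence_length = 2e5, meth_fraction = f)
    expect_equal(length(dat$meth$positions) / dat$L, f, tolerance = 0.3)
  }
})
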