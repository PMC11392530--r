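test_that("methylome container validates its inputs", {
  expect_error(methylome(c(5L, 1L), rbind(c(1, 0))), "sorted")
  expect_error(methylome(c(1L, 5L), rbind(c(1, 2))), "alphabet")
  m <- methylome(c(1L, 5L), rbind(c(1L, 0L), c(NA, 1L)))
  expect_s3_class(m, "methylome")
})

test_that("region effect test is calibrated on independent sites and powered on blocks", {
  set.seed(41)
  p_m <- 3.5e-4 / (3.5e-4 + 1.5e-3)
  ## truly independent Bernoulli sites: near-nominal rejection
  rejections <- vapply(1:40, function(i) {
    st <- rbind(stats::rbinom(800, 1, p_m), stats::rbinom(800, 1, p_m))
    rt <- region_effect_test(methylome(seq_len(800) * 10, st),
                             3.5e-4, 1.5e-3)
    rt$p_value < 0.05
  }, logical(1))
  expect_lt(mean(rejections), 0.2)
  ## strong block structure: always rejected
  blocks <- rep(stats::rbinom(40, 1, p_m), each = 20)
  st <- rbind(blocks, blocks)
  rt <- region_effect_test(methylome(seq_len(800) * 10, st), 3.5e-4, 1.5e-3)
  expect_identical(rt$decision, "region effect")
  expect_lt(rt$p_value, 1e-4)
  ## fewer than 2 sites errors
  expect_error(region_effect_test(methylome(1L, rbind(1L)), 3.5e-4, 1.5e-3),
               "fewer than 2")
  ## distance-stratified variant drops close pairs; pairs are disjoint
  pos <- c(0L, 5L, 1000L, 1500L, 2000L)
  st1 <- rbind(c(1L, 1L, 0L, 0L, 1L))
  rt2 <- region_effect_test(methylome(pos, st1), 3.5e-4, 1.5e-3,
                            min_separation = 100)
  ## candidate disjoint pairs are (1,2) and (3,4): only (3,4) is >= 100 bp
  expect_identical(rt2$n_pairs, 1L)
})

test_that("segmentation recovers block structure and degenerate cases", {
  ## all sites methylated in both genomes: a single MM segment
  pos <- seq(0L, 990L, by = 10L)
  st <- rbind(rep(1L, 100), rep(1L, 100))
  seg <- segment_methylation_regions(methylome(pos, st), c(1, 2),
                                     region_length = 500)
  expect_identical(nrow(seg$segments), 1L)
  expect_identical(seg$segments$status, "MM")
  expect_error(segment_methylation_regions(methylome(integer(0),
                                                     matrix(0L, 2, 0)), c(1, 2)),
               "empty")
  ## alternating 1 kb blocks of MM and UU, light noise: lengths within 30%
  set.seed(42)
  pos <- sort(sample(0:9999, 1200))
  truth <- (pos %/% 1000) %% 2
  flip <- stats::runif(length(pos)) < 0.03
  s1 <- as.integer(xor(truth, flip))
  flip2 <- stats::runif(length(pos)) < 0.03
  s2 <- as.integer(xor(truth, flip2))
  seg2 <- segment_methylation_regions(methylome(pos, rbind(s1, s2)), c(1, 2),
                                      region_length = 1000)
  big <- seg2$segments[seg2$segments$status != "UM", ]
  expect_lt(abs(stats::median(big$length) - 1000) / 1000, 0.3)
})

test_that("observation coding round-trips and has the documented symbols", {
  snp_states <- rbind(c(0L, 2L, 1L), c(0L, 3L, 1L))
  snp_pos <- c(10L, 50L, 90L)
  meth <- methylome(c(20L, 40L, 60L), rbind(c(0L, 1L, 1L), c(0L, 1L, 0L)))
  obs <- encode_pair_observations(snp_states, snp_pos, meth, L = 100L)
  expect_s3_class(obs, "pair_obs")
  expect_length(obs$symbols, 100L)
  dec <- decode_pair_observations(obs)
  ## equal nucleotides -> 0-coded (symbol "id"), unequal -> 1
  expect_identical(dec$code[11], "id")
  expect_identical(dec$code[51], "seg")
  ## methylation codes 2 (UU), 3 (MM), 4 (discordant)
  expect_identical(dec$code[21], "2")
  expect_identical(dec$code[41], "3")
  expect_identical(dec$code[61], "4")
  ## default background is identical nucleotides
  expect_identical(dec$code[100], "id")
  ## missing data: dedicated NA symbol
  snp_na <- rbind(c(0L, NA), c(0L, 1L))
  obs2 <- encode_pair_observations(snp_na, c(1L, 2L), NULL, L = 5L)
  expect_true(is.na(obs2$symbols[3]))
  expect_error(encode_pair_observations(rbind(0L, 1L), c(1L, 2L), NULL, 5L),
               "inconsistent")
  ## 9-symbol alphabet with a segmentation
  segm <- list(positions = c(20L, 40L, 60L), status_index = c(1L, 3L, 2L))
  obs9 <- encode_pair_observations(snp_states, snp_pos, meth, L = 100L,
                                   segmentation = segm)
  expect_identical(nrow(obs9$symbols_table), 2L + 9L)
  dec9 <- decode_pair_observations(obs9)
  expect_identical(dec9$code[21], "UU:2")
  expect_identical(dec9$code[41], "MM:3")
  expect_identical(dec9$code[61], "UM:4")
})

test_that("SMCm with zero methylable sites equals the SNP-only fit exactly", {
  set.seed(43)
  dat <- generate_fixture("methylome_fig5", seed = 43, n_haplotypes = 4,
                          sequence_length = 2e5)
  ## empty the methylome layer
  dat$meth$positions <- integer(0)
  dat$meth$states <- matrix(0L, dat$n, 0)
  dat$marker_data[[2]] <- list(positions = integer(0),
                               states = matrix(0L, dat$n, 0), total_sites = 0)
  fm <- fit_smcm(dat, mu1 = 7e-9, site_rates = c(3.5e-4, 1.5e-3),
                 region = "off", method = "bw", free_parameters = NULL,
                 n_states = 6, bin_w = 200, selfing = 0.9)
  fs <- fit_snp_only(dat, mu1 = 7e-9, method = "bw", free_parameters = NULL,
                     n_states = 6, bin_w = 200, selfing = 0.9)
  expect_equal(fm$loglik, fs$loglik, tolerance = 1e-12)
})

test_that("SMCm with symmetric site rates matches the generic two-marker fit", {
  ## with equal gain/loss rates the methylation emission is the symmetric
  ## two-state emission with each identical class carrying probability 1/2;
  ## the likelihoods differ by exactly n_identical * log(2)
  set.seed(44)
  mu <- 2e-4
  mks <- list(marker_spec("snp", 4, mu = 7e-9, fraction = 0.9),
              marker_spec("meth", 2, mu_gain = mu, mu_loss = mu,
                          fraction = 0.1))
  cfg <- sim_config(4, 2e5, r = 1e-8, markers = mks, meth_fraction = 0.1)
  dat <- simulate_methylome(simulate_arg(cfg, demography(0, 1e4)), cfg)
  dat$truth$demography <- demography(0, 1e4)
  fm <- fit_smcm(dat, mu1 = 7e-9, site_rates = c(mu, mu), region = "off",
                 method = "bw", free_parameters = NULL, n_states = 6,
                 bin_w = 200)
  ## generic fit on the same data with marker 2 treated symmetrically
  dat2 <- dat
  dat2$markers[[2]] <- marker_spec("m2", 2, mu = mu, fraction = 0.1)
  fg <- fit_multimarker(dat2, mu1 = 7e-9, mu2 = mu, method = "bw",
                        free_parameters = NULL, n_states = 6, bin_w = 200)
  s1 <- dat$meth$states[1, ]; s2 <- dat$meth$states[2, ]
  ## identical methylation pairs per encoded pair, summed over all pairs
  prs <- smcmark:::haplotype_pairs(dat$n)
  n_id <- sum(apply(prs, 1, function(p)
    sum(dat$meth$states[p[1], ] == dat$meth$states[p[2], ])))
  expect_equal(fm$loglik + n_id * log(2), fg$loglik, tolerance = 1e-6)
})

test_that("fit_smcm auto mode runs the region test and reports diagnostics", {
  set.seed(45)
  mks <- list(marker_spec("snp", 4, mu = 7e-9, fraction = 0.9),
              marker_spec("meth", 2, mu_gain = 3.5e-4, mu_loss = 1.5e-3,
                          fraction = 0.1))
  cfg <- sim_config(4, 2e5, r = 1e-8, markers = mks,
                    region = region_model(2e-4, 1e-3, 500),
                    meth_fraction = 0.1)
  dat <- simulate_methylome(simulate_arg(cfg, demography(0, 1e4)), cfg)
  dat$truth$demography <- demography(0, 1e4)
  fit <- fit_smcm(dat, mu1 = 7e-9, site_rates = c(3.5e-4, 1.5e-3),
                  region = "auto", region_rates = c(2e-4, 1e-3),
                  region_length = 500, method = "bw",
                  free_parameters = NULL, n_states = 6, bin_w = 200)
  expect_true(is.list(fit$region_test))
  if (fit$region_used) {
    expect_length(fit$segmentations, 6)  # 4 choose 2
    expect_s3_class(fit$segmentations[[1]], "methyl_segmentation")
  }
  expect_true(is.finite(fit$loglik))
  ## region model on without rates errors
  expect_error(fit_smcm(dat, mu1 = 7e-9, site_rates = c(3.5e-4, 1.5e-3),
                        region = "on", region_rates = NULL,
                        method = "bw", free_parameters = NULL,
                        n_states = 6, bin_w = 200),
               "region rates")
})

test_that("segregating-SMPs-only mode restricts the methylation sites", {
  set.seed(46)
  dat <- generate_fixture("methylome_fig5", seed = 46, n_haplotypes = 4,
                          sequence_length = 1e5, meth_fraction = 0.1)
  enc_all <- bin_pair_observations(dat, c(1, 2), bin_w = 200)
  enc_seg <- bin_pair_observations(dat, c(1, 2), bin_w = 200,
                                   segregating_only = TRUE)
  meth_cols <- which(enc_all$symbols$marker == 2)
  expect_lt(sum(enc_seg$counts[, meth_cols]), sum(enc_all$counts[, meth_cols]))
})
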