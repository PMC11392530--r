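test_that("marker_spec validates its inputs", {
  expect_error(marker_spec("x", 1, mu = 1e-8), "nbs")
  expect_error(marker_spec("x", 2), "either")
  expect_error(marker_spec("x", 2, mu = 1e-8, mu_gain = 1e-4, mu_loss = 1e-3),
               "mutually exclusive")
  expect_error(marker_spec("x", 4, mu_gain = 1e-4, mu_loss = 1e-3),
               "two-state")
  expect_error(marker_spec("x", 2, mu = -1), ">= 0")
  m <- marker_spec("snp", 4, mu = 1e-8, fraction = 0.98)
  expect_s3_class(m, "marker_spec")
  expect_identical(m$model, "symmetric")
})

test_that("symmetric pair emission has the exact limits", {
  snp <- marker_spec("snp", 4, mu = 1e-8)
  e0 <- symmetric_pair_emission(snp, 0)
  expect_equal(unname(e0[, "identical"]), 1)
  expect_equal(unname(e0[, "segregating"]), 0)
  m2 <- marker_spec("m2", 2, mu = 1e-3)
  einf <- symmetric_pair_emission(m2, 1e12)
  expect_equal(unname(einf[, "identical"]), 0.5, tolerance = 1e-12)
  ## hand-derived value: nbs = 2, mu = 1e-4, t = 1000
  e <- symmetric_pair_emission(marker_spec("x", 2, mu = 1e-4), 1000)
  expect_equal(unname(e[, "identical"]), 0.5 + 0.5 * exp(-0.4), tolerance = 1e-12)
  expect_error(symmetric_pair_emission(snp, -1), ">= 0")
})

test_that("emissions are normalized and monotone in time and rate", {
  snp <- marker_spec("snp", 4, mu = 1e-8)
  tt <- c(10, 1e3, 1e5, 1e7)
  e <- symmetric_pair_emission(snp, tt)
  expect_equal(rowSums(e), rep(1, 4), tolerance = 1e-12)
  expect_true(all(diff(e[, "segregating"]) > 0))
  ## monotone decreasing in mu as well
  pid <- vapply(c(1e-9, 1e-8, 1e-7),
                function(m) symmetric_pair_emission(marker_spec("x", 4, mu = m),
                                                    1e4)[, "identical"],
                numeric(1))
  expect_true(all(diff(pid) < 0))
})

test_that("P(seg) rises with mu then saturates below (nbs-1)/nbs", {
  for (nbs in c(2, 4)) {
    mus <- 10^seq(-8, -1, by = 0.5)
    pseg <- vapply(mus, function(m)
      symmetric_pair_emission(marker_spec("x", nbs, mu = m), 2e4)[, "segregating"],
      numeric(1))
    expect_true(all(diff(pseg) > -1e-12))
    expect_true(all(pseg <= (nbs - 1) / nbs + 1e-12))
    expect_gt(max(pseg), (nbs - 1) / nbs - 1e-3)  # saturation is approached
  }
})

test_that("symmetric emissions match the Monte-Carlo jump-chain oracle", {
  set.seed(42)
  reps <- 2e5
  for (case in list(list(nbs = 2, mu = 1e-4, t = 1000),
                    list(nbs = 4, mu = 5e-5, t = 3000))) {
    pid <- symmetric_pair_emission(marker_spec("x", case$nbs, mu = case$mu),
                                   case$t)[, "identical"]
    phat <- mc_symmetric_pair(case$nbs, case$mu, case$t, reps)
    se <- sqrt(pid * (1 - pid) / reps)
    expect_lt(abs(phat - pid), 3 * se)
  }
})

test_that("asymmetric site emission: limits, symmetry reduction, MC oracle", {
  ## no time, no discordance
  e0 <- asymmetric_site_emission(3.5e-4, 1.5e-3, 0)
  expect_equal(unname(e0[, "discordant"]), 0)
  expect_equal(sum(e0), 1, tolerance = 1e-12)
  ## both rates zero is degenerate
  expect_error(asymmetric_site_emission(0, 0, 100), "degenerate")
  ## equal rates reduce to the symmetric two-state model
  mu <- 2e-4; t <- 1500
  ea <- asymmetric_site_emission(mu, mu, t)
  es <- symmetric_pair_emission(marker_spec("x", 2, mu = mu), t)
  expect_equal(unname(ea[, "uu"] + ea[, "mm"]), unname(es[, "identical"]),
               tolerance = 1e-12)
  ## t -> infinity factorizes into stationary products
  pm <- 3.5e-4 / (3.5e-4 + 1.5e-3)
  einf <- asymmetric_site_emission(3.5e-4, 1.5e-3, 1e9)
  expect_equal(unname(einf[, "mm"]), pm^2, tolerance = 1e-9)
  expect_equal(pm, 0.1892, tolerance = 1e-3)
  ## Monte-Carlo (Gillespie) oracle at field-realistic rates
  set.seed(7)
  reps <- 2e5
  e <- asymmetric_site_emission(3.5e-4, 1.5e-3, 2000)
  phat <- mc_asymmetric_pair(3.5e-4, 1.5e-3, 2000, reps)
  se <- sqrt(e * (1 - e) / reps)
  expect_true(all(abs(phat[colnames(e)] - e) < 3 * se + 1e-9))
})

test_that("region-conditioned 9-symbol emission is a proper distribution", {
  rm_ <- region_model(2e-4, 1e-3, 1000)
  em <- region_conditioned_emission(3.5e-4, 1.5e-3, rm_, t = 5000)
  expect_length(em, 9)
  expect_equal(sum(em), 1, tolerance = 1e-12)
  ## conditional blocks sum to one
  for (s in c("UU", "UM", "MM")) {
    blk <- region_conditioned_emission(3.5e-4, 1.5e-3, rm_, t = 5000,
                                       region_status = s)
    expect_equal(sum(blk), 1, tolerance = 1e-12)
  }
  ## marginal region-pair distribution equals the region-scale emission
  reg_marg <- c(sum(em[1:3]), sum(em[4:6]), sum(em[7:9]))
  ae <- region_pair_status_probs(rm_, 5000)
  expect_equal(unname(reg_marg), unname(ae[1, c("UU", "UM", "MM")]),
               tolerance = 1e-10)
  ## degenerate region process reduces to the plain site emission
  frozen <- region_model(0, 0, 1000)
  expect_error(region_conditioned_emission(3.5e-4, 1.5e-3, frozen, 100), "degenerate")
  blk <- region_conditioned_emission(3.5e-4, 1.5e-3, frozen, 100,
                                     region_status = "MM")
  plain <- asymmetric_site_emission(3.5e-4, 1.5e-3, 100)
  expect_equal(unname(blk), unname(drop(plain)), tolerance = 1e-12)
})

test_that("9-symbol emission matches the coupled region+site chain oracle", {
  set.seed(99)
  rm_ <- region_model(2e-4, 1e-3, 1000)
  em <- region_conditioned_emission(3.5e-4, 1.5e-3, rm_, t = 5000)
  reps <- 1e5
  mc <- as.numeric(mc_region_site_pair(3.5e-4, 1.5e-3, 2e-4, 1e-3, 5000, reps))
  se <- sqrt(em * (1 - em) / reps)
  expect_true(all(abs(mc - em) < 3 * se + 1e-9))
})
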