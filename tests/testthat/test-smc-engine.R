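const_dem <- demography(0, 1e4)

test_that("time discretization has equal prior masses and is deterministic", {
  expect_error(discretize_time(1, const_dem), ">= 2")
  d1 <- discretize_time(8, const_dem)
  d2 <- discretize_time(8, const_dem)
  expect_identical(d1$boundaries, d2$boundaries)
  ## constant N: boundaries are the exact exponential quantiles
  expect_equal(d1$boundaries[-9],
               -2e4 * log(1 - (0:7) / 8), tolerance = 1e-8)
  ## equal prior coalescence mass per interval
  pri <- smcmark:::state_prior(d1, const_dem)
  expect_equal(pri, rep(1 / 8, 8), tolerance = 1e-9)
  ## representative time inside its interval
  expect_true(all(d1$rep_time > d1$boundaries[-9]))
  expect_true(all(d1$rep_time < d1$boundaries[-1]))
})

test_that("transition matrix: identity at rho 0, stochastic rows, oracle match", {
  disc <- discretize_time(5, const_dem)
  expect_equal(transition_matrix(disc, const_dem, 0), diag(5))
  dem_b <- demography(c(0, 1000, 10000), c(10000, 1000, 10000))
  A <- transition_matrix(disc, dem_b, 1e-7)
  expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-12)
  expect_true(all(A >= 0))
  ## off-diagonal mass increases with rho for small rho
  A2 <- transition_matrix(disc, dem_b, 2e-7)
  expect_true(all((1 - diag(A2)) > (1 - diag(A))))

  ## brute-force single-recombination integral oracle (constant N)
  r <- 1e-8; cc <- 1 / (2 * 1e4)
  A <- transition_matrix(disc, const_dem, r)
  for (k in c(1, 3, 5)) {
    tk <- disc$rep_time[k]
    fl <- function(s) (1 - exp(-2 * cc * s)) / (2 * tk)
    J <- (1 - exp(-2 * cc * tk)) / (2 * cc * tk)
    fu <- function(s) J * cc * exp(-cc * (s - tk))
    b <- disc$boundaries
    m <- vapply(1:5, function(l) {
      stats::integrate(function(s) ifelse(s < tk, fl(s), fu(s)),
                       b[l], min(b[l + 1], 2e6),
                       subdivisions = 4000, rel.tol = 1e-10)$value
    }, numeric(1))
    sil <- stats::integrate(fl, 0, tk, rel.tol = 1e-10)$value
    p <- 1 - exp(-2 * r * tk)
    oracle <- p * m / (sil + sum(m))
    oracle[k] <- oracle[k] + (1 - p) + p * sil / (sil + sum(m))
    off <- setdiff(1:5, k)
    expect_lt(max(abs(A[k, off] - oracle[off]) / oracle[off]), 0.01)
  }
})

test_that("emission matrix equals the closed-form evaluation per state", {
  disc <- discretize_time(5, const_dem)
  mks <- list(marker_spec("m1", 4, mu = 1e-8, fraction = 0.98),
              marker_spec("m2", 2, mu = 1e-4, fraction = 0.02))
  E <- emission_matrix(disc, mks)
  expect_equal(ncol(E), 4)
  ## per-marker blocks sum to one
  expect_equal(rowSums(E[, 1:2]), rep(1, 5), tolerance = 1e-12)
  expect_equal(rowSums(E[, 3:4]), rep(1, 5), tolerance = 1e-12)
  direct <- symmetric_pair_emission(mks[[2]], disc$rep_time)
  expect_equal(unname(E[, 3:4]), unname(direct), tolerance = 1e-14)
  ## P(seg) non-decreasing across states ordered by time
  expect_true(all(diff(E[, 2]) >= 0))
  expect_true(all(diff(E[, 4]) >= 0))
  ## deep state of a two-state marker approaches 1/2
  deep <- emission_matrix(discretize_time(30, const_dem), mks)
  expect_equal(unname(deep[30, 4]), 0.5, tolerance = 0.02)
  expect_error(emission_matrix(disc, list(list(model = "symmetric"))), "rates")
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(21)
  S <- 3; T_ <- 8; K <- 2
  A <- matrix(stats::runif(S * S), S); A <- A / rowSums(A)
  E <- matrix(stats::runif(S * K), S); E <- E / rowSums(E)
  pi0 <- stats::runif(S); pi0 <- pi0 / sum(pi0)
  sym <- sample(1:K, T_, replace = TRUE)
  logE <- base::t(log(E)[, sym])
  out <- smcmark:::.hmm_fb_cpp(A, logE, pi0, TRUE, TRUE, FALSE)
  expect_equal(out$loglik, enumerate_loglik(A, E, pi0, sym), tolerance = 1e-10)
  expect_equal(rowSums(out$posterior), rep(1, T_), tolerance = 1e-10)
  expect_equal(sum(out$xi), T_ - 1, tolerance = 1e-10)
  expect_error(smcmark:::.hmm_fb_cpp(A, logE[0, , drop = FALSE], pi0,
                                     FALSE, FALSE, FALSE), "empty")
})

test_that("uniform emissions leave the posterior at the prior", {
  set.seed(22)
  S <- 4; T_ <- 50
  A <- matrix(stats::runif(S * S), S); A <- A / rowSums(A)
  ## stationary of A as prior; uniform emissions must return it unchanged
  ev <- eigen(base::t(A))
  pi0 <- abs(Re(ev$vectors[, 1])); pi0 <- pi0 / sum(pi0)
  logE <- matrix(0, T_, S)
  out <- smcmark:::.hmm_fb_cpp(A, logE, pi0, TRUE, FALSE, FALSE)
  expect_equal(out$posterior[1, ], pi0, tolerance = 1e-10)
  expect_equal(out$posterior[T_, ], pi0, tolerance = 1e-10)
})

test_that("forward-backward runs on encoded pairs and integrates to sane posteriors", {
  dat <- small_two_marker_data(23, n = 4, L = 2e5)
  mks <- dat$markers; mks[[1]]$mu <- 1e-8; mks[[2]]$mu <- 1e-4
  model <- init_model(dat, mks, n_states = 8, r = 1e-8, bin_w = 100)
  enc <- bin_pair_observations(dat, c(1, 2), bin_w = 100)
  fb <- forward_backward(enc, model, posterior = TRUE)
  expect_true(is.finite(fb$loglik))
  expect_equal(rowSums(fb$posterior), rep(1, nrow(fb$posterior)),
               tolerance = 1e-10)
})

test_that("binned and per-site likelihoods agree closely at low density", {
  dat <- small_two_marker_data(29, n = 2, L = 4e4, mu2 = 1e-5)
  mks <- dat$markers; mks[[1]]$mu <- 1e-8; mks[[2]]$mu <- 1e-5
  m_site <- init_model(dat, mks, n_states = 6, r = 1e-8, bin_w = 1)
  enc <- bin_pair_observations(dat, c(1, 2), bin_w = 1)
  fb_site <- forward_backward(enc, m_site, posterior = FALSE)
  m_bin <- init_model(dat, mks, n_states = 6, r = 1e-8, bin_w = 50)
  enc50 <- bin_pair_observations(dat, c(1, 2), bin_w = 50)
  fb_bin <- forward_backward(enc50, m_bin, posterior = FALSE)
  expect_lt(abs(fb_site$loglik - fb_bin$loglik) / abs(fb_site$loglik), 0.01)
})

test_that("Baum-Welch: fixed parameters unchanged, monotone likelihood", {
  dat <- small_two_marker_data(24, n = 4, L = 2e5)
  mks <- dat$markers; mks[[1]]$mu <- 1e-8; mks[[2]]$mu <- 1e-4
  model <- init_model(dat, mks, n_states = 8, r = 1e-8, bin_w = 200)
  encs <- lapply(list(c(1, 2), c(3, 4)), function(p)
    bin_pair_observations(dat, p, bin_w = 200))
  ## all parameters fixed: model returned unchanged after one E-step
  f0 <- baum_welch_fit(encs, model, free_parameters = NULL)
  expect_identical(f0$iterations, 1L)
  expect_identical(f0$model$dem$sizes, model$dem$sizes)
  expect_identical(f0$r, model$r)
  ## free sizes: non-decreasing likelihood trajectory
  f1 <- baum_welch_fit(encs, model, free_parameters = c("sizes"), max_iter = 6)
  tr <- f1$loglik_trajectory
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-1])))
})

test_that("EM monotonicity holds across random small fixtures", {
  set.seed(25)
  for (rep in 1:8) {
    dat <- small_two_marker_data(100 + rep, n = 2, L = 5e4,
                                 mu2 = 10^stats::runif(1, -5, -3.5),
                                 N = round(10^stats::runif(1, 3.5, 4.3)))
    mks <- dat$markers; mks[[1]]$mu <- 1e-8
    mks[[2]]$mu <- 1e-4
    model <- init_model(dat, mks, n_states = 5, r = 1e-8, bin_w = 200)
    enc <- list(bin_pair_observations(dat, c(1, 2), bin_w = 200))
    fit <- baum_welch_fit(enc, model, free_parameters = c("sizes", "r"),
                          max_iter = 4)
    tr <- fit$loglik_trajectory
    expect_true(all(diff(tr) >= -1e-6 * abs(tr[-1])))
  }
})

test_that("composite likelihood is invariant to pair ordering", {
  dat <- small_two_marker_data(26, n = 4, L = 1e5)
  mks <- dat$markers; mks[[1]]$mu <- 1e-8; mks[[2]]$mu <- 1e-4
  model <- init_model(dat, mks, n_states = 6, r = 1e-8, bin_w = 200)
  prs <- list(c(1, 2), c(1, 3), c(2, 4))
  encs <- lapply(prs, function(p) bin_pair_observations(dat, p, bin_w = 200))
  l1 <- smcmark:::e_step(encs, model)$loglik
  l2 <- smcmark:::e_step(rev(encs), model)$loglik
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("constant-N recovery: fitted sizes within 50 percent in interior epochs", {
  dat <- small_two_marker_data(27, n = 6, L = 1e6)
  fit <- fit_multimarker(dat, mu1 = 1e-8, mu2 = 1e-4, method = "bw",
                         free_parameters = c("sizes"), n_states = 12,
                         bin_w = 200, max_iter = 10)
  sizes <- pop_size_at(fit$demography, fit$model$disc$rep_time)
  interior <- sizes[3:10]
  expect_true(all(interior > 1e4 / 1.5 & interior < 1e4 * 1.5))
})

test_that("direct likelihood optimization never returns less than the start", {
  dat <- small_two_marker_data(28, n = 4, L = 2e5)
  mks <- dat$markers; mks[[1]]$mu <- 1e-8; mks[[2]]$mu <- 1e-4
  model <- init_model(dat, mks, n_states = 6, r = 1e-8, bin_w = 200)
  encs <- list(bin_pair_observations(dat, c(1, 2), bin_w = 200))
  expect_error(likelihood_fit(encs, model, free_parameters = NULL),
               "no free parameters")
  fit <- likelihood_fit(encs, model, free_parameters = c("r"), max_eval = 60)
  expect_gte(fit$loglik, fit$loglik_trajectory[1] - 1e-9)
  ## single free parameter recovery: rate of marker 2 on its own data
  fit2 <- likelihood_fit(encs, model, free_parameters = c("rate2"),
                         max_eval = 60)
  expect_gt(fit2$rates[[2]][["mu"]], 1e-4 / 3)
  expect_lt(fit2$rates[[2]][["mu"]], 1e-4 * 3)
})
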