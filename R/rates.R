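#' Watterson's diversity estimator per site
#'
#' @param n_segregating number of segregating sites of the marker class.
#' @param n_sites total number of sites of the class.
#' @param n number of haplotypes sampled.
#' @return theta_W per site: `S / (a_n * L)` with
#'   `a_n = sum(1/i, i = 1..n-1)`.
#' @export
watterson_theta <- function(n_segregating, n_sites, n) {
  if (n_sites <= 0) stop("no sites")
  a_n <- sum(1 / seq_len(n - 1))
  n_segregating / (a_n * n_sites)
}

#' Fraction of polymorphic sites of a marker class
#'
#' Used to decide between the infinite-site (diversity-ratio) and
#' finite-site (Baum-Welch) rate estimation paths.
#'
#' @param dat a `sim_data` (or compatible) object.
#' @param marker marker index.
#' @return fraction of the marker's sites segregating among the sample.
#' @export
polymorphism_fraction <- function(dat, marker) {
  if (marker > length(dat$marker_data)) stop("marker absent from data")
  md <- dat$marker_data[[marker]]
  if (is.null(md) || md$total_sites <= 0) stop("marker absent from data")
  if (ncol(md$states) == 0) return(0)
  poly <- sum(matrixStats_colAny(md$states))
  poly / md$total_sites
}

## finite-site correction: invert the saturating relation between observed
## per-site diversity and the mutation-scale diversity of an nbs-state
## symmetric chain; linearizes to the identity at low diversity.
finite_site_adjust <- function(theta, nbs) {
  cap <- (nbs - 1) / nbs
  if (theta >= cap) {
    warning("diversity at or beyond the finite-site saturation level")
    theta <- cap * (1 - 1e-6)
  }
  -cap * log(1 - theta / cap)
}

#' Diversity summary of a dataset
#'
#' @param dat a `sim_data` (or compatible) object.
#' @return data.frame: per marker the number of sites, segregating sites,
#'   polymorphism fraction and Watterson's theta per site.
#' @export
diversity_summary <- function(dat) {
  out <- lapply(seq_along(dat$markers), function(m) {
    md <- dat$marker_data[[m]]
    seg <- if (ncol(md$states)) sum(matrixStats_colAny(md$states)) else 0L
    data.frame(marker = dat$markers[[m]]$name, nbs = dat$markers[[m]]$nbs,
               n_sites = md$total_sites, n_segregating = seg,
               poly_fraction = seg / md$total_sites,
               theta_w = watterson_theta(seg, md$total_sites, dat$n))
  })
  do.call(rbind, out)
}

#' Transfer a known mutation rate to a second marker via diversity ratios
#'
#' Under the infinite-site regime both markers share the same genealogies, so
#' the ratio of their per-site diversities equals the ratio of their mutation
#' rates. Each marker's Watterson estimate is first adjusted for its number
#' of possible states (finite-site saturation correction, negligible at low
#' diversity): `mu2 = mu1 * adj(theta2, nbs2) / adj(theta1, nbs1)`.
#'
#' @param summary a [diversity_summary()] (or compatible data.frame) with the
#'   reference marker in row 1 and the target marker in row 2.
#' @param mu1 known rate of the reference marker.
#' @return estimated per-site rate of the target marker.
#' @export
watterson_rate_estimate <- function(summary, mu1) {
  if (summary$theta_w[1] <= 0) stop("zero reference diversity")
  t1 <- finite_site_adjust(summary$theta_w[1], summary$nbs[1])
  t2 <- finite_site_adjust(summary$theta_w[2], summary$nbs[2])
  mu1 * t2 / t1
}

#' Estimate unknown marker rates, choosing the estimation path automatically
#'
#' Implements the 1%-polymorphism dispatch rule: markers with at most
#' `threshold` of their sites polymorphic are treated under the infinite-site
#' assumption and their rate is transferred from the reference marker by the
#' diversity ratio ([watterson_rate_estimate()]); markers beyond it violate
#' the infinite-site assumption and their rate is estimated as a free
#' emission parameter by Baum-Welch ([baum_welch_fit()]).
#'
#' @param dat a `sim_data` (or compatible) object.
#' @param mu1 known rate of the reference marker (index 1).
#' @param target index of the marker whose rate is unknown.
#' @param threshold polymorphism dispatch threshold (default 0.01).
#' @param n_states,bin_w,max_haplotypes,... Baum-Welch path options.
#' @return list: `estimate` (named rate vector), `method`
#'   (`"watterson"` or `"baum_welch"`), `poly_fraction`, and the fit when the
#'   Baum-Welch path ran.
#' @export
estimate_rates_auto <- function(dat, mu1, target = 2L, threshold = 0.01,
                                n_states = 18, bin_w = 200,
                                max_haplotypes = 6, ...) {
  if (target > length(dat$markers)) stop("no unknown markers")
  pf <- polymorphism_fraction(dat, target)
  if (pf <= threshold) {
    ds <- diversity_summary(dat)[c(1L, target), ]
    est <- watterson_rate_estimate(ds, mu1)
    if (dat$markers[[target]]$model == "asymmetric") {
      ## split the symmetric-equivalent rate (2 g l / (g + l) at small t) by
      ## the observed methylated fraction pm = g / (g + l)
      pm <- mean(dat$marker_data[[target]]$states, na.rm = TRUE)
      pm <- min(max(pm, 1e-6), 1 - 1e-6)
      est <- c(mu_gain = est / (2 * (1 - pm)), mu_loss = est / (2 * pm))
    } else {
      est <- c(mu = est)
    }
    list(estimate = est, method = "watterson", poly_fraction = pf, fit = NULL)
  } else {
    fit <- fit_multimarker(dat, mu1 = mu1, mu2 = NULL, method = "bw",
                           free_parameters = c("sizes", "rates"),
                           n_states = n_states, bin_w = bin_w,
                           max_haplotypes = max_haplotypes, ...)
    list(estimate = fit$rates[[target]], method = "baum_welch",
         poly_fraction = pf, fit = fit)
  }
}
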