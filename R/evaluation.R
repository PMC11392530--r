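#' Root mean square error between true and estimated demographies
#'
#' Evaluates both step functions at 102 points uniformly spread across the
#' time window on the log10 scale and returns
#' `sqrt(sum((y_i - y_i*)^2) / 102)`.
#'
#' @param true,est [demography()] objects.
#' @param window evaluation window in generations (default `c(100, 1e6)`).
#' @param n_points number of evaluation points (102 by default).
#' @param log_sizes compare log10 population sizes instead of natural sizes.
#' @return the RMSE (same units as the population sizes).
#' @export
rmse_demography <- function(true, est, window = c(100, 1e6), n_points = 102,
                            log_sizes = FALSE) {
  stopifnot(inherits(true, "demography"), inherits(est, "demography"))
  if (window[1] <= 0 || window[2] <= window[1]) stop("invalid window")
  tp <- 10^seq(log10(window[1]), log10(window[2]), length.out = n_points)
  y <- pop_size_at(true, tp)
  ys <- pop_size_at(est, tp)
  if (log_sizes) { y <- log10(y); ys <- log10(ys) }
  sqrt(sum((y - ys)^2) / n_points)
}

#' Posterior expected TMRCA along the genome
#'
#' Runs the forward-backward algorithm on an encoded pair and returns the
#' per-position expected coalescence time: posteriors are rescaled to sum to
#' one at each position and dotted with the hidden states' representative
#' times (`TMRCA_i = sum_j fo_ij ba_ij Tc_j`).
#'
#' @param obs encoded pair observations (`pair_obs` or `pair_bins`).
#' @param model a fitted or known [smc_model()].
#' @return object of class `tmrca_track`: `tmrca` (expected time per
#'   position or bin), `map_state` (maximum-a-posteriori hidden state),
#'   `bin_w`, and `Tc` (the hidden-state time vector).
#' @export
posterior_tmrca <- function(obs, model) {
  if (is.null(model$disc$rep_time)) stop("model without representative times")
  fb <- forward_backward(obs, model, posterior = TRUE)
  tc <- model$disc$rep_time
  structure(list(tmrca = drop(fb$posterior %*% tc),
                 map_state = max.col(fb$posterior, ties.method = "first"),
                 bin_w = if (inherits(obs, "pair_bins")) obs$bin_w else 1L,
                 Tc = tc, loglik = fb$loglik),
            class = "tmrca_track")
}

#' Genomic span distribution of inferred genealogies
#'
#' A genealogy span ends where the inferred hidden state changes along the
#' genome; by default the maximum-a-posteriori state is used (robust to
#' posterior noise), optionally thresholded changes of the expected TMRCA.
#'
#' @param track a [posterior_tmrca()] result.
#' @param use one of `"map"` (state changes) or `"expected"` (relative
#'   changes of the expected TMRCA beyond `threshold`).
#' @param threshold relative change threshold for the `"expected"` mode.
#' @return list: `spans` (bp lengths partitioning the sequence), `mean`,
#'   `median`.
#' @export
genealogy_spans <- function(track, use = c("map", "expected"),
                            threshold = 0.5) {
  stopifnot(inherits(track, "tmrca_track"))
  use <- match.arg(use)
  if (!length(track$tmrca)) stop("empty track")
  if (use == "map") {
    runs <- rle(track$map_state)
  } else {
    x <- track$tmrca
    chg <- abs(diff(x)) / pmax(x[-length(x)], 1e-12) > threshold
    runs <- rle(cumsum(c(0L, as.integer(chg))))
  }
  spans <- runs$lengths * track$bin_w
  list(spans = spans, mean = mean(spans), median = stats::median(spans))
}

#' Linkage disequilibrium decay of a marker class
#'
#' Computes r-squared between pairs of polymorphic sites of one marker class
#' (minor state carried by at least `min_count` haplotypes, LD being
#' undefined for monomorphic sites) and averages it in distance bins.
#'
#' @param dat a `sim_data` (or compatible) object.
#' @param marker marker index.
#' @param breaks distance bin edges in bp.
#' @param min_count minimum minor-state count (default 2).
#' @param max_pairs random cap on the number of site pairs per run.
#' @return data.frame: distance bin, mean r2 and pair count per bin.
#' @export
ld_decay <- function(dat, marker, breaks = c(0, 10^seq(1, 5, by = 0.5)),
                     min_count = 2, max_pairs = 2e5) {
  md <- dat$marker_data[[marker]]
  st <- md$states
  n <- nrow(st)
  ## biallelic 0/1 coding: indicator of the non-majority state
  maj <- apply(st, 2, function(x) {
    tx <- tabulate(x + 1L)
    which.max(tx) - 1L
  })
  x01 <- st != matrix(maj, n, ncol(st), byrow = TRUE)
  cnt <- colSums(x01)
  keep <- cnt >= min_count & cnt <= n - min_count
  pos <- md$positions[keep]
  x01 <- x01[, keep, drop = FALSE]
  S <- length(pos)
  if (S < 2) stop("fewer than 2 polymorphic sites")
  if (S > 3000) {  # keep the all-pairs distance scan affordable
    sel <- sort(sample.int(S, 3000))
    pos <- pos[sel]
    x01 <- x01[, sel, drop = FALSE]
    S <- 3000L
  }
  maxd <- max(breaks)
  ## pairs within the largest distance bin
  idx <- which(outer(pos, pos, function(a, b) {
    d <- b - a
    d > 0 & d <= maxd
  }), arr.ind = TRUE)
  if (nrow(idx) < 1) stop("no site pairs within the distance range")
  if (nrow(idx) > max_pairs) idx <- idx[sample.int(nrow(idx), max_pairs), ]
  d <- pos[idx[, 2]] - pos[idx[, 1]]
  r2 <- vapply(seq_len(nrow(idx)), function(k) {
    suppressWarnings(stats::cor(x01[, idx[k, 1]], x01[, idx[k, 2]]))^2
  }, numeric(1))
  bin <- cut(d, breaks = breaks)
  ok <- !is.na(r2) & !is.na(bin)
  agg <- tapply(r2[ok], bin[ok], mean)
  data.frame(bin = names(agg),
             upper = breaks[-1][seq_along(agg)],
             mean_r2 = as.numeric(agg),
             n_pairs = as.integer(table(bin[ok])))
}

#' Plot true and estimated population size trajectories
#'
#' Step-function display of one or more demographies on log-log axes, the
#' usual way SMC fits are presented.
#'
#' @param fits named list of [demography()] objects (fits and/or truth).
#' @param window time window in generations.
#' @param col line colours, recycled.
#' @param ... further arguments to [graphics::matplot()]-style base plotting.
#' @return invisibly, the matrix of evaluated sizes.
#' @export
plot_demographies <- function(fits, window = c(100, 1e6), col = NULL, ...) {
  tp <- 10^seq(log10(window[1]), log10(window[2]), length.out = 300)
  ys <- vapply(fits, function(d) pop_size_at(d, tp), numeric(length(tp)))
  if (is.null(col)) col <- seq_along(fits)
  graphics::matplot(tp, ys, type = "s", log = "xy", lty = 1, col = col,
                    xlab = "generations ago", ylab = "population size N(t)",
                    ...)
  if (!is.null(names(fits))) {
    graphics::legend("topleft", legend = names(fits), col = col, lty = 1,
                     bty = "n")
  }
  invisible(ys)
}
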