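#' Piecewise-constant population size trajectory
#'
#' @param boundaries increasing epoch start times in generations; the first
#'   must be 0. The last epoch extends to infinity.
#' @param sizes population size per epoch (same length as `boundaries`);
#'   sizes are on the haploid-pair scale: two lineages coalesce at rate
#'   `1/(2N)` per generation, so the expected pairwise TMRCA under a constant
#'   size is `2N` generations.
#' @return an object of class `demography`.
#' @examples
#' demography(c(0, 1000, 10000), c(10000, 1000, 10000))  # 10-fold bottleneck
#' @export
demography <- function(boundaries, sizes) {
  boundaries <- as.numeric(boundaries)
  sizes <- as.numeric(sizes)
  if (length(boundaries) != length(sizes)) stop("lengths differ")
  if (boundaries[1] != 0) stop("first boundary must be 0")
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  if (any(sizes <= 0)) stop("sizes must be > 0")
  structure(list(boundaries = boundaries, sizes = sizes), class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("<demography> piecewise-constant N(t):\n")
  up <- c(x$boundaries[-1], Inf)
  for (i in seq_along(x$sizes)) {
    cat(sprintf("  [%g, %g) N = %g\n", x$boundaries[i], up[i], x$sizes[i]))
  }
  invisible(x)
}

#' Evaluate a demography at given times
#'
#' @param dem a [demography()].
#' @param t times in generations (vectorised).
#' @return population sizes `N(t)`.
#' @export
pop_size_at <- function(dem, t) {
  stopifnot(inherits(dem, "demography"))
  idx <- findInterval(t, dem$boundaries)
  idx[idx < 1L] <- 1L
  dem$sizes[idx]
}

## Cumulative pair-coalescence hazard C(t) = int_0^t 1/(2 N(s)) ds.
## Vectorised over t; exact for the piecewise-constant demography.
coal_cumhaz <- function(dem, t) {
  b <- dem$boundaries
  rate <- 1 / (2 * dem$sizes)
  ## cumulative hazard at each epoch start
  base <- c(0, cumsum(diff(b) * rate[-length(b)]))
  idx <- findInterval(t, b)
  idx[idx < 1L] <- 1L
  base[idx] + (t - b[idx]) * rate[idx]
}

## Inverse of coal_cumhaz: time at which the cumulative hazard reaches h.
coal_cumhaz_inv <- function(dem, h) {
  b <- dem$boundaries
  rate <- 1 / (2 * dem$sizes)
  Hb <- coal_cumhaz(dem, b)
  vapply(h, function(hh) {
    i <- findInterval(hh, Hb)
    i[i < 1L] <- 1L
    i <- min(i, length(b))
    b[i] + (hh - Hb[i]) / rate[i]
  }, numeric(1))
}

## Quantile of the pairwise coalescence time distribution: P(T <= t) = 1-e^-C(t).
coal_time_quantile <- function(dem, p) {
  coal_cumhaz_inv(dem, -log1p(-p))
}

#' Bottleneck demography constructor
#'
#' Standard three-epoch scenario used throughout the simulation experiments:
#' present size `n_anc`, a drop by `fold` between `t_start` and `t_end`
#' generations ago, and ancestral size `n_anc`. `recovery` rescales the
#' present epoch (e.g. `recovery = 0.2` for incomplete recovery).
#'
#' @param n_anc ancestral population size.
#' @param fold bottleneck strength (size divided by `fold` inside it).
#' @param t_start,t_end bottleneck interval, generations ago.
#' @param recovery multiplier for the present-day epoch size (default 1).
#' @return a [demography()].
#' @export
bottleneck_demography <- function(n_anc = 10000, fold = 10,
                                  t_start = 1000, t_end = 10000,
                                  recovery = 1) {
  demography(c(0, t_start, t_end),
             c(n_anc * recovery, n_anc / fold, n_anc))
}
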