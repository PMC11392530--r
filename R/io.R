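#' Read nucleotide states from a VCF
#'
#' Reads haploid (or homozygous-diploid) genotypes for a subset of samples.
#' Multi-allelic records are retained (the finite-site model allows them);
#' missing genotypes become `NA`. Diploid genotypes are collapsed to one
#' haplotype when homozygous; heterozygous calls become missing (mirroring
#' the haploid treatment of highly selfing samples).
#'
#' @param path VCF file (plain text or bgzipped; requires the `vcfR`
#'   package).
#' @param samples character vector of sample names, or `NULL` for all.
#' @return list: `positions` (0-based), `states` (samples x sites allele
#'   indices, 0 = REF), `chrom`, `samples`.
#' @export
read_variants <- function(path, samples = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCFs requires the `vcfR` package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(gt))
    if (length(missing_s)) stop("unknown sample(s): ",
                                paste(missing_s, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  parse1 <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    al <- as.integer(al)
    if (length(al) == 1L) return(al)
    if (length(unique(al)) == 1L) return(al[1])  # homozygous diploid
    NA_integer_  # heterozygous: missing in haploid mode
  }
  states <- apply(gt, c(1, 2), parse1)
  pos <- as.integer(vcfR::getPOS(v)) - 1L  # VCF is 1-based
  ord <- order(pos)
  list(positions = pos[ord], states = t(states[ord, , drop = FALSE]),
       chrom = vcfR::getCHROM(v)[ord], samples = colnames(gt))
}

#' Read a per-site methylation-state table restricted to genic regions
#'
#' The table is a TSV with columns CHROM, POS (1-based), CONTEXT and one
#' status column per sample with values `M`, `U` or `.` (missing). Only
#' CG-context records falling inside the genic BED intervals are kept.
#'
#' @param tsv_path methylation table path.
#' @param bed_path BED file of genic regions (0-based half-open), or `NULL`
#'   to keep all CG records.
#' @return a [methylome()]; sample columns become haplotype rows.
#' @export
read_methylome <- function(tsv_path, bed_path = NULL) {
  tab <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("CHROM", "POS", "CONTEXT")
  if (!all(need %in% names(tab))) stop("methylome table needs columns ",
                                       paste(need, collapse = ", "))
  tab <- tab[tab$CONTEXT == "CG", , drop = FALSE]
  pos <- as.integer(tab$POS) - 1L  # to 0-based
  regions <- NULL
  if (!is.null(bed_path)) {
    bed <- utils::read.table(bed_path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    regions <- cbind(start = as.integer(bed[[2]]), end = as.integer(bed[[3]]))
    inside <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(regions))) {
      inside <- inside | (pos >= regions[i, 1] & pos < regions[i, 2])
    }
    tab <- tab[inside, , drop = FALSE]
    pos <- pos[inside]
  }
  scols <- setdiff(names(tab), need)
  st <- vapply(scols, function(s) {
    x <- tab[[s]]
    if (!all(x %in% c("M", "U", "."))) stop("status outside alphabet in ", s)
    ifelse(x == "M", 1L, ifelse(x == "U", 0L, NA_integer_))
  }, integer(nrow(tab)))
  ord <- order(pos)
  methylome(pos[ord], base::t(st[ord, , drop = FALSE]), regions = regions)
}

#' Write the annotated per-site haplotype table
#'
#' Full per-site export of a simulated dataset (CHROM, POS, MARKER and one
#' state column per haplotype, `M<k>S<state>` coding); intended for short
#' sequences.
#'
#' @param dat a `sim_data` object.
#' @param path output TSV path.
#' @param chrom chromosome label.
#' @return the path, invisibly.
#' @export
write_annotated_tsv <- function(dat, path, chrom = "sim1") {
  L <- as.integer(dat$L)
  marker_of <- integer(L)
  if (!is.null(dat$pattern)) {
    marker_of <- dat$pattern$pattern[(seq_len(L) - 1L) %% dat$pattern$period + 1L]
  } else {
    marker_of <- rep(1L, L)
    marker_of[dat$meth$positions + 1L] <- 2L
  }
  states <- matrix(0L, dat$n, L)
  for (m in seq_along(dat$markers)) {
    md <- dat$marker_data[[m]]
    here <- which(marker_of == m) - 1L
    ## ancestral fill for sites not in the polymorphic/annotated table
    anc <- marker_stationary(dat$markers[[m]])
    fill <- sample.int(length(anc), length(here), replace = TRUE, prob = anc) - 1L
    states[, here + 1L] <- rep(fill, each = dat$n)
    if (length(md$positions)) {
      states[, md$positions + 1L] <- md$states
    }
  }
  tab <- data.frame(CHROM = chrom, POS = seq_len(L) - 1L,
                    MARKER = paste0("M", marker_of))
  for (i in seq_len(dat$n)) {
    tab[[paste0("STATE_", i)]] <- paste0("M", marker_of, "S", states[i, ])
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write truth marginal trees as newick-per-interval
#'
#' @param arg an [simulate_arg()] result.
#' @param path output TSV (`start`, `end`, `newick`).
#' @param max_trees cap on the number of trees written.
#' @return the path, invisibly.
#' @export
write_truth_trees <- function(arg, path, max_trees = 1000L) {
  stopifnot(inherits(arg, "arg_trees"))
  k <- min(length(arg$span), max_trees)
  ends <- cumsum(arg$span)
  starts <- c(0, ends[-length(ends)])
  nw <- vapply(seq_len(k), function(i)
    ape::write.tree(arg_tree_to_phylo(arg, i)), character(1))
  utils::write.table(data.frame(start = starts[seq_len(k)],
                                end = ends[seq_len(k)], newick = nw),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert one marginal tree to an `ape` phylo object
#'
#' @param arg an [simulate_arg()] result.
#' @param i tree index.
#' @return an `ape::phylo` with branch lengths in generations.
#' @export
arg_tree_to_phylo <- function(arg, i) {
  par <- arg$parent[, i]
  tim <- arg$time[, i]
  n <- arg$n
  nn <- length(par)
  kids <- vector("list", nn)
  for (v in seq_len(nn)) {
    p <- par[v] + 1L  # stored 0-based
    if (par[v] >= 0) kids[[p]] <- c(kids[[p]], v)
  }
  root <- which(par < 0)
  nwk <- function(v) {
    if (v <= n) return(paste0("h", v))
    paste0("(", paste(vapply(kids[[v]], function(ch)
      paste0(nwk(ch), ":", format(tim[v] - tim[ch], digits = 12)),
      character(1)), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(nwk(root), ";"))
}

#' Write a demography as a step-function TSV
#'
#' @param dem a [demography()].
#' @param path output path (`time_generations`, `N` columns).
#' @return the path, invisibly.
#' @export
write_demography_tsv <- function(dem, path) {
  utils::write.table(data.frame(time_generations = dem$boundaries,
                                N = dem$sizes),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a step-function demography TSV
#'
#' @param path a file written by [write_demography_tsv()].
#' @return a [demography()].
#' @export
read_demography_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  demography(tab$time_generations, tab$N)
}

#' Serialize a fit result to JSON
#'
#' @param fit an `smc_fit`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(r = fit$r,
              demography = list(boundaries = fit$demography$boundaries,
                                sizes = fit$demography$sizes),
              rates = fit$rates,
              loglik = fit$loglik,
              loglik_trajectory = fit$loglik_trajectory,
              converged = fit$converged,
              iterations = fit$iterations)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
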