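#' Sliding genomic windows
#'
#' Generates sliding windows per chromosome: starts at every multiple of
#' `step` below the chromosome length, each extending `size` bp and
#' truncated at the chromosome end.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp (default 1 Mb).
#' @param step step size in bp (default 500 kb); must satisfy
#'   `size >= step > 0`.
#' @return a [genomic_intervals()] data.frame.
#' @export
make_windows <- function(chrom_lengths, size = 1e6, step = 5e5) {
  if (length(chrom_lengths) == 0L) stop("empty chromosome length table")
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named by chromosome")
  if (!(size >= step && step > 0)) stop("need size >= step > 0")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = step)
    starts <- starts[starts < len]
    genomic_intervals(ch, starts, pmin(starts + size, len))
  })
  do.call(rbind, out)
}

pop_columns <- function(tab, pop) {
  idx <- match(pop, tab$sample_ids)
  if (anyNA(idx))
    stop("samples absent from table: ",
         paste(pop[is.na(idx)], collapse = ", "))
  idx
}

# per-site unbiased pi: n non-missing alleles, c alt alleles
site_pi <- function(geno) {
  n <- 2 * rowSums(!is.na(geno))
  c_alt <- rowSums(geno, na.rm = TRUE)
  pi <- ifelse(n >= 2, 2 * c_alt * (n - c_alt) / (n * (n - 1)), NA_real_)
  pi[n < 2] <- NA_real_
  pi
}

window_accumulate <- function(tab, windows, values) {
  gr_w <- intervals_to_granges(windows)
  gr_s <- sites_to_granges(tab)
  hits <- GenomicRanges::findOverlaps(gr_s, gr_w)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ok <- !is.na(values[qi])
  sum_v <- rep(0, nrow(windows)); n_v <- rep(0L, nrow(windows))
  if (any(ok)) {
    agg <- rowsum(values[qi][ok], si[ok])
    sum_v[as.integer(rownames(agg))] <- agg[, 1L]
    cnt <- table(si[ok])
    n_v[as.integer(names(cnt))] <- as.integer(cnt)
  }
  list(sum = sum_v, n = n_v)
}

#' Windowed nucleotide diversity
#'
#' Nucleotide diversity (theta-pi): the average number of pairwise
#' nucleotide differences per site between two sequences drawn from the
#' population.  Per site with `n` non-missing alleles of which `c` are
#' derived, `pi = 2c(n-c) / (n(n-1))`; the window value is the sum over
#' sites in the window divided by the window length in bp (monomorphic and
#' unobserved positions count zero diversity, the windowed-pi convention of
#' VCFtools).  Truncated terminal windows use their true length.
#'
#' @param tab a [variant_table()].
#' @param pop character vector of sample ids forming the population.
#' @param windows a [genomic_intervals()] data.frame (see
#'   [make_windows()]).
#' @return the windows data.frame with added columns `value` (pi) and
#'   `n_sites` (polymorphic sites contributing).
#' @export
nucleotide_diversity <- function(tab, pop, windows) {
  idx <- pop_columns(tab, pop)
  if (length(idx) < 2L) stop("need at least 2 samples for diversity")
  g <- tab$geno[, idx, drop = FALSE]
  pis <- site_pi(g)
  acc <- window_accumulate(tab, windows, pis)
  out <- as.data.frame(windows)
  out$value <- acc$sum / (windows$end - windows$start)
  out$n_sites <- acc$n
  out
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# Inputs are vectors over sites: diploid sample sizes, alt-allele
# frequencies, observed heterozygote proportions.
wc84_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r -
       hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham Fst
#'
#' Two-population fixation index using the Weir & Cockerham (1984)
#' variance-component estimator with observed heterozygote counts.  Window
#' values are ratio-of-sums (`sum(a) / sum(a+b+c)`, the "weighted" Fst of
#' VCFtools); negative estimates are reported as computed.  Windows whose
#' denominator is zero (or with no usable site) get `NA`.
#'
#' @param tab a [variant_table()].
#' @param pop_a,pop_b disjoint character vectors of sample ids.
#' @param windows a [genomic_intervals()] data.frame.
#' @return the windows data.frame with `value` (Fst), `n_sites`, and
#'   component sums `num` / `den`.
#' @export
fst_weir_cockerham <- function(tab, pop_a, pop_b, windows) {
  if (length(intersect(pop_a, pop_b)))
    stop("populations overlap: ",
         paste(intersect(pop_a, pop_b), collapse = ", "))
  ia <- pop_columns(tab, pop_a); ib <- pop_columns(tab, pop_b)
  ga <- tab$geno[, ia, drop = FALSE]; gb <- tab$geno[, ib, drop = FALSE]
  n1 <- rowSums(!is.na(ga)); n2 <- rowSums(!is.na(gb))
  p1 <- rowSums(ga, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(gb, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(ga == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(gb == 1L, na.rm = TRUE) / n2
  usable <- n1 >= 2 & n2 >= 2
  comp <- wc84_components(n1, p1, h1, n2, p2, h2)
  num <- ifelse(usable, comp$a, NA_real_)
  den <- ifelse(usable, comp$a + comp$b + comp$c, NA_real_)
  acc_n <- window_accumulate(tab, windows, num)
  acc_d <- window_accumulate(tab, windows, den)
  out <- as.data.frame(windows)
  out$num <- acc_n$sum
  out$den <- acc_d$sum
  out$value <- ifelse(acc_d$n > 0 & acc_d$sum != 0,
                      acc_n$sum / acc_d$sum, NA_real_)
  out$n_sites <- acc_d$n
  out
}

#' Pairwise identity-by-state distance matrix
#'
#' IBS distance between two diploids is one minus the mean per-site
#' similarity `1 - |g_i - g_j| / 2` over sites called in both.  Pairs with
#' no co-called site get `NA`.
#'
#' @param tab a [variant_table()] with at least 2 samples.
#' @return a symmetric numeric matrix with zero diagonal, dimnames the
#'   sample ids.
#' @export
ibs_distance_matrix <- function(tab) {
  ns <- n_samples(tab)
  if (ns < 2L) stop("need at least 2 samples")
  g <- tab$geno
  called <- !is.na(g)
  g0 <- g; g0[!called] <- 0L
  # sum |gi - gj| over co-called sites, via the identity
  # |a-b| = a + b - 2*min(a,b); min over {0,1,2} dosages needs indicators
  co <- crossprod(called)                      # co-called site counts
  s  <- crossprod(called, g0)                  # colsum of partner-called g
  sum_ab <- t(s) + s                           # sum (gi + gj) co-called
  ge1 <- (g0 >= 1L) & called
  ge2 <- (g0 >= 2L) & called
  min_ab <- crossprod(ge1) + crossprod(ge2)    # sum min(gi, gj)
  absdiff <- sum_ab - 2 * min_ab
  d <- (absdiff / 2) / co
  d[co == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(tab$sample_ids, tab$sample_ids)
  d
}

#' Subsampled diversity comparison
#'
#' Repeatedly draws `n_sub` samples without replacement from a population
#' and computes the genome-wide mean of windowed pi, the device used to
#' compare diversity between groups of unequal size.
#'
#' @param tab a [variant_table()].
#' @param pop character vector of sample ids (`length(pop) >= n_sub`).
#' @param windows a [genomic_intervals()] data.frame.
#' @param n_sub subsample size (default 19).
#' @param reps number of subsamples (default 100).
#' @param seed RNG seed.
#' @return a list with `mean` (mean over reps) and `per_rep` (numeric
#'   vector of per-rep genome-wide mean pi).
#' @export
subsampled_diversity <- function(tab, pop, windows, n_sub = 19,
                                 reps = 100, seed = 1) {
  if (length(pop) < n_sub)
    stop("population smaller than the subsample size")
  rng <- local_rng(seed)
  per_rep <- vapply(seq_len(reps), function(i) {
    sub <- sample(pop, n_sub)
    w <- nucleotide_diversity(tab, sub, windows)
    mean(w$value, na.rm = TRUE)
  }, numeric(1))
  list(mean = mean(per_rep), per_rep = per_rep)
}

# Seed the global RNG for the calling frame and restore it on exit.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  withr::defer({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, envir = envir)
  invisible(seed)
}
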