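#' Linkage-disequilibrium decay profile
#'
#' Computes the mean squared genotype correlation (r^2) between all
#' same-chromosome SNP pairs within `max_dist` bp, binned by physical
#' distance (PopLDdecay-style genotype r^2 on diploid dosages, not phased
#' haplotypes).  Pairs with fewer than `min_pairs_called` samples called at
#' both sites, or with zero dosage variance at either site, are skipped.
#'
#' @param tab a [variant_table()].
#' @param pop character vector of sample ids.
#' @param max_dist maximum pair distance in bp (default 1 Mb).
#' @param bin distance bin width in bp (default 500).
#' @param min_pairs_called minimum co-called samples per pair (default 4).
#' @return a data.frame with `distance_low`, `distance_high` (bp, bins
#'   `(low, high]` tiling `(0, max_dist]`), `mean_r2` and `n_pairs`;
#'   empty-bin rows carry `NA` mean.  A warning is raised if every pair was
#'   skipped.
#' @export
ld_decay <- function(tab, pop, max_dist = 1e6, bin = 500,
                     min_pairs_called = 4) {
  idx <- pop_columns(tab, pop)
  g <- tab$geno[, idx, drop = FALSE]
  # sites monomorphic within the population can never contribute a pair
  v <- site_pi(g)
  seg <- !is.na(v) & v > 0
  n_bins <- ceiling(max_dist / bin)
  sum_r2 <- rep(0, n_bins); n_pairs <- rep(0L, n_bins)
  chunk <- 512L       # sites per block; bounds the pairwise work set
  for (ch in unique(tab$chrom)) {
    rows <- which(tab$chrom == ch & seg)
    if (length(rows) < 2L) next
    gm <- t(g[rows, , drop = FALSE])        # samples x sites
    pos <- tab$pos[rows]
    p <- length(rows)
    for (i1 in seq(1L, p, by = chunk)) {
      i2 <- min(i1 + chunk - 1L, p)
      hi <- findInterval(pos[i2] + max_dist, pos)
      if (hi <= i1) next
      ji <- i1:hi
      r2 <- suppressWarnings(
        stats::cor(gm[, i1:i2, drop = FALSE], gm[, ji, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      co <- crossprod(!is.na(gm[, i1:i2, drop = FALSE]),
                      !is.na(gm[, ji, drop = FALSE]))
      dist <- outer(pos[i1:i2], pos[ji], function(a, b) b - a)
      keep <- which(dist > 0 & dist <= max_dist &
                      co >= min_pairs_called & !is.na(r2))
      # dist > 0 plus i1:hi >= i1 guarantees each pair is seen once
      if (!length(keep)) next
      b <- ceiling(dist[keep] / bin)
      add <- rowsum(r2[keep], b)
      bi <- as.integer(rownames(add))
      sum_r2[bi] <- sum_r2[bi] + add[, 1L]
      cnt <- table(b)
      n_pairs[as.integer(names(cnt))] <-
        n_pairs[as.integer(names(cnt))] + as.integer(cnt)
    }
  }
  if (sum(n_pairs) == 0L)
    warning("no usable SNP pair within max_dist; empty LD profile")
  data.frame(distance_low = (seq_len(n_bins) - 1L) * bin,
             distance_high = seq_len(n_bins) * bin,
             mean_r2 = ifelse(n_pairs > 0, sum_r2 / pmax(n_pairs, 1L),
                              NA_real_),
             n_pairs = n_pairs)
}
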