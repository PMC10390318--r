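#' Group samples by candidate-region genotype haplotype
#'
#' Partitions samples by exact identity of their genotype vector over the
#' SNPs in a candidate region (typically a gene span plus its 2-kb
#' strand-aware upstream flank).  Samples with any missing genotype in the
#' region are excluded (their count is reported); groups smaller than
#' `min_group` are dropped.  Groups are ordered by decreasing size and
#' labelled `Hap.1`, `Hap.2`, ...
#'
#' @param tab a [variant_table()].
#' @param region a single-row [genomic_intervals()] data.frame (0-based
#'   half-open).
#' @param samples sample ids to consider (default all).
#' @param min_group minimum group size retained (default 3).
#' @return a list with `groups` (named list of member sample-id vectors),
#'   `defining` (matrix of defining genotype vectors, one column per
#'   group), `n_sites`, and `n_excluded_missing`.  A warning is raised when
#'   no group reaches `min_group`.
#' @export
group_haplotypes <- function(tab, region, samples = tab$sample_ids,
                             min_group = 3) {
  stopifnot(nrow(region) == 1L)
  rows <- which(tab$chrom == region$chrom &
                  tab$pos > region$start & tab$pos <= region$end)
  if (!length(rows)) stop("no SNP in the candidate region")
  idx <- pop_columns(tab, samples)
  g <- tab$geno[rows, idx, drop = FALSE]
  complete <- colSums(is.na(g)) == 0L
  n_excluded <- sum(!complete)
  g <- g[, complete, drop = FALSE]
  kept <- samples[complete]
  if (!length(kept)) {
    warning("every sample has a missing call in the region")
    return(list(groups = list(), defining = NULL,
                n_sites = length(rows), n_excluded_missing = n_excluded))
  }
  key <- apply(g, 2L, paste, collapse = ",")
  tab_sizes <- sort(table(key), decreasing = TRUE)
  keys <- names(tab_sizes)[tab_sizes >= min_group]
  if (!length(keys)) {
    warning("no haplotype group reaches min_group = ", min_group)
    return(list(groups = list(), defining = NULL,
                n_sites = length(rows), n_excluded_missing = n_excluded))
  }
  groups <- lapply(keys, function(k) kept[key == k])
  names(groups) <- paste0("Hap.", seq_along(groups))
  defining <- vapply(keys, function(k) g[, which(key == k)[1L]],
                     integer(length(rows)))
  defining <- matrix(defining, nrow = length(rows),
                     dimnames = list(NULL, names(groups)))
  list(groups = groups, defining = defining,
       n_sites = length(rows), n_excluded_missing = n_excluded)
}

#' Phenotype contrast between haplotype groups
#'
#' Two-sample t-test of a quantitative trait between every pair of
#' haplotype groups (Welch's unequal-variance test by default; set
#' `pooled = TRUE` for the classical equal-variance form).  Pairs where
#' either group has fewer than 2 phenotyped members are skipped and noted.
#'
#' @param groups named list of member sample-id vectors (see
#'   [group_haplotypes()]).
#' @param phenotypes data.frame with columns `sample_id` and `value` (one
#'   trait), e.g. from [read_phenotypes()] subset to a trait.
#' @param alpha significance level for the `significant` flag
#'   (default 0.01).
#' @param pooled use the pooled-variance Student test instead of Welch.
#' @return a data.frame with one row per tested pair: `group_a`, `group_b`,
#'   `n_a`, `n_b`, `mean_a`, `mean_b`, `t`, `p_value`, `significant`.
#'   Skipped pairs appear with `NA` statistics.
#' @export
compare_haplotype_phenotypes <- function(groups, phenotypes, alpha = 0.01,
                                         pooled = FALSE) {
  if (length(groups) < 2L) stop("need at least 2 groups to contrast")
  vals <- lapply(groups, function(m) {
    v <- phenotypes$value[match(m, phenotypes$sample_id)]
    v[!is.na(v)]
  })
  pairs <- utils::combn(names(groups), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    va <- vals[[a]]; vb <- vals[[b]]
    base <- data.frame(group_a = a, group_b = b,
                       n_a = length(va), n_b = length(vb),
                       mean_a = mean(va), mean_b = mean(vb),
                       t = NA_real_, p_value = NA_real_,
                       significant = NA)
    if (length(va) < 2L || length(vb) < 2L) return(base)
    if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
      # degenerate: both groups constant; equal means -> no evidence,
      # unequal means -> complete separation
      equal <- mean(va) == mean(vb)
      base$t <- if (equal) 0 else sign(mean(va) - mean(vb)) * Inf
      base$p_value <- if (equal) 1 else 0
      base$significant <- !equal
      return(base)
    }
    tt <- stats::t.test(va, vb, var.equal = pooled)
    base$t <- unname(tt$statistic)
    base$p_value <- tt$p.value
    base$significant <- tt$p.value < alpha
    base
  })
  do.call(rbind, rows)
}
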