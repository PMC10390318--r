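# Independent reference implementations: direct transcriptions of the
# definitions, written for clarity not speed, used to cross-check the
# package's vectorized code.

# per-site boolean re-evaluation of the hard site filter
oracle_filter_pass <- function(tab, qual_min = 30, fs_max = 60,
                               mq_min = 40, pass_frac_min = 0.8,
                               maf_min = 0.05, missing_max = 0.20,
                               gq_min = 10) {
  ns <- length(tab$sample_ids)
  vapply(seq_along(tab$pos), function(i) {
    g <- tab$geno[i, ]
    called <- sum(!is.na(g))
    if (called == 0) return(FALSE)
    af <- sum(g, na.rm = TRUE) / (2 * called)
    maf <- min(af, 1 - af)
    missing <- 1 - called / ns
    gqi <- if (is.null(tab$gq)) rep(Inf, ns) else tab$gq[i, ]
    passf <- sum(!is.na(g) & gqi >= gq_min) / ns
    (is.na(tab$qual[i]) || tab$qual[i] >= qual_min) &&
      (is.na(tab$fs[i]) || tab$fs[i] <= fs_max) &&
      (is.na(tab$mq[i]) || tab$mq[i] >= mq_min) &&
      passf >= pass_frac_min && maf >= maf_min && missing <= missing_max
  }, logical(1))
}

# mean pairwise Hamming distance per bp over all haplotype pairs
oracle_pi_hamming <- function(hap, span) {
  n <- ncol(hap)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(hap[, i] != hap[, j])
    np <- np + 1
  }
  tot / np / span
}

# Weir & Cockerham (1984) single-site theta from genotype vectors,
# spelled out with scalars
oracle_wc84_site <- function(ga, gb) {
  ga <- ga[!is.na(ga)]; gb <- gb[!is.na(gb)]
  n1 <- length(ga); n2 <- length(gb); r <- 2
  p1 <- sum(ga) / (2 * n1); p2 <- sum(gb) / (2 * n2)
  h1 <- mean(ga == 1); h2 <- mean(gb == 1)
  nbar <- mean(c(n1, n2))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# PLINK-style ROH rules transcribed directly, all loops
oracle_roh <- function(g, pos, ws = 50, wmiss = 2, whet = 0,
                       min_snp = 50, min_kb = 500, density_kb = 50,
                       hit_threshold = 0.05, max_gap_kb = 1000) {
  p <- length(g)
  if (p < ws) return(NULL)
  nw <- p - ws + 1
  perm <- logical(nw)
  for (w in seq_len(nw)) {
    win <- g[w:(w + ws - 1)]
    perm[w] <- sum(win == 1, na.rm = TRUE) <= whet &&
      sum(is.na(win)) <= wmiss
  }
  eligible <- logical(p)
  for (j in seq_len(p)) {
    covering <- max(1, j - ws + 1):min(j, nw)
    rate <- mean(perm[covering])
    eligible[j] <- rate >= hit_threshold && !(!is.na(g[j]) && g[j] == 1)
  }
  segs <- NULL
  run <- integer(0)
  flush <- function(run, segs) {
    if (length(run) >= min_snp) {
      kb <- (pos[max(run)] - pos[min(run)] + 1) / 1000
      if (kb >= min_kb && kb / length(run) <= density_kb)
        segs <- rbind(segs, data.frame(
          start = pos[min(run)] - 1, end = pos[max(run)],
          n_snps = length(run), kb_length = kb,
          snp_density = kb / length(run)))
    }
    segs
  }
  for (j in seq_len(p)) {
    if (eligible[j]) {
      if (length(run) && (pos[j] - pos[max(run)]) > max_gap_kb * 1000) {
        segs <- flush(run, segs)
        run <- integer(0)
      }
      run <- c(run, j)
    } else {
      segs <- flush(run, segs)
      run <- integer(0)
    }
  }
  flush(run, segs)
}

# exhaustive segment x window overlap count for nibd
oracle_nibd_counts <- function(ibd, target, ref_pop, windows) {
  counts <- integer(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    for (s in seq_len(nrow(ibd))) {
      pair_ok <- (ibd$sample_a[s] %in% target &
                    ibd$sample_b[s] %in% ref_pop) ||
        (ibd$sample_a[s] %in% ref_pop & ibd$sample_b[s] %in% target)
      same_chr <- ibd$chrom[s] == windows$chrom[w]
      overlap <- min(ibd$end[s], windows$end[w]) -
        max(ibd$start[s], windows$start[w])
      if (pair_ok && same_chr && overlap > 0)
        counts[w] <- counts[w] + 1L
    }
  }
  counts
}

# all-pairs same-founder interval intersection for true IBD
oracle_true_ibd <- function(tracts, min_length) {
  haps <- unique(tracts[, c("sample_id", "hap")])
  out <- NULL
  for (i in seq_len(nrow(haps) - 1)) for (j in (i + 1):nrow(haps)) {
    ta <- tracts[tracts$sample_id == haps$sample_id[i] &
                   tracts$hap == haps$hap[i], ]
    tb <- tracts[tracts$sample_id == haps$sample_id[j] &
                   tracts$hap == haps$hap[j], ]
    for (a in seq_len(nrow(ta))) for (b in seq_len(nrow(tb))) {
      if (ta$founder_id[a] != tb$founder_id[b]) next
      lo <- max(ta$start[a], tb$start[b])
      hi <- min(ta$end[a], tb$end[b])
      if (hi - lo >= min_length)
        out <- rbind(out, data.frame(
          sample_a = haps$sample_id[i], hap_a = haps$hap[i],
          sample_b = haps$sample_id[j], hap_b = haps$hap[j],
          start = lo, end = hi))
    }
  }
  out
}

# random genotype vector with long homozygous stretches, for ROH tests
random_roh_genotypes <- function(p, seed) {
  set.seed(seed)
  g <- integer(0)
  state_hom <- TRUE
  while (length(g) < p) {
    len <- stats::rgeom(1, if (state_hom) 1 / 150 else 1 / 30) + 1
    block <- if (state_hom) {
      sample(c(0L, 2L), len, replace = TRUE, prob = c(0.6, 0.4))
    } else {
      sample(c(0L, 1L, 2L), len, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    }
    g <- c(g, block)
    state_hom <- !state_hom
  }
  g <- g[seq_len(p)]
  g[stats::runif(p) < 0.01] <- NA
  pos <- cumsum(sample(200:2000, p, replace = TRUE))
  list(g = g, pos = pos)
}

# canonical sortable key for an IBD segment set (endpoint order-free)
ibd_key <- function(d) {
  a <- sprintf("%s %d", d$sample_a, d$hap_a)
  b <- sprintf("%s %d", d$sample_b, d$hap_b)
  lo <- pmin(a, b); hi <- pmax(a, b)
  sort(sprintf("%s | %s | %.0f %.0f", lo, hi, d$start, d$end))
}
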