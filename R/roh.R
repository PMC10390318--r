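#' Runs of homozygosity (scanning-window heuristic)
#'
#' Reimplements the PLINK `--homozyg` scanning-window heuristic.  Per
#' sample and chromosome, a window of `window_snp` consecutive SNPs slides
#' one SNP at a time; a window is permissible if it contains at most
#' `window_het` heterozygous and at most `window_missing` missing calls.
#' Each SNP's hit rate is the fraction of permissible windows among those
#' covering it; SNPs with hit rate at least `hit_threshold` and a
#' non-heterozygous call are run-eligible.  Maximal runs of consecutive
#' eligible SNPs are split where the gap between adjacent SNPs exceeds
#' `max_gap_kb`, and a run is reported iff it has at least `min_snp` SNPs,
#' spans at least `min_kb` kb, and its kb-per-SNP density is at most
#' `density_kb`.
#'
#' Default parameters are the published scan settings
#' (`window_snp 50, window_missing 2, window_het 0, min_snp 50, min_kb 500,
#' density_kb 50`) with PLINK defaults for the unprinted knobs
#' (`hit_threshold 0.05`, `max_gap_kb 1000`).
#'
#' @param tab a [variant_table()].
#' @param samples sample ids to scan (default all).
#' @param window_snp,window_missing,window_het scanning-window size and
#'   tolerance.
#' @param min_snp,min_kb,density_kb segment acceptance thresholds.
#' @param hit_threshold minimum permissible-window hit rate per SNP.
#' @param max_gap_kb maximum gap (kb) between adjacent SNPs inside a run.
#' @return a data.frame with one row per segment: `sample_id`, `chrom`,
#'   `start` (0-based), `end` (exclusive), `n_snps`, `kb_length`
#'   (`(last - first + 1)/1000` on 1-based positions), `snp_density`
#'   (kb per SNP).
#' @export
roh_scan <- function(tab, samples = tab$sample_ids,
                     window_snp = 50, window_missing = 2, window_het = 0,
                     min_snp = 50, min_kb = 500, density_kb = 50,
                     hit_threshold = 0.05, max_gap_kb = 1000) {
  res <- list()
  for (ch in unique(tab$chrom)) {
    rows <- which(tab$chrom == ch)
    if (length(rows) < window_snp) {
      warning("chromosome ", ch, " has fewer than ", window_snp,
              " SNPs; skipped")
      next
    }
    pos <- tab$pos[rows]
    for (s in samples) {
      g <- tab$geno[rows, match(s, tab$sample_ids)]
      seg <- roh_one(g, pos, window_snp, window_missing, window_het,
                     min_snp, min_kb, density_kb, hit_threshold,
                     max_gap_kb)
      if (nrow(seg)) {
        seg$sample_id <- s
        seg$chrom <- ch
        res[[length(res) + 1L]] <- seg
      }
    }
  }
  if (!length(res))
    return(data.frame(sample_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), kb_length = numeric(),
                      snp_density = numeric()))
  out <- do.call(rbind, res)
  out[, c("sample_id", "chrom", "start", "end",
          "n_snps", "kb_length", "snp_density")]
}

roh_one <- function(g, pos, ws, wmiss, whet, min_snp, min_kb,
                    density_kb, hit_threshold, max_gap_kb) {
  p <- length(g)
  het <- !is.na(g) & g == 1L
  miss <- is.na(g)
  roll <- function(x) {
    cs <- cumsum(x)
    cs[ws:p] - c(0, cs[seq_len(p - ws)])
  }
  perm <- roll(het) <= whet & roll(miss) <= wmiss   # one per window start
  nw <- length(perm)
  # windows covering SNP j start at max(1, j-ws+1) .. min(j, nw)
  cp <- c(0, cumsum(perm))
  lo <- pmax(1L, seq_len(p) - ws + 1L)
  hi <- pmin(seq_len(p), nw)
  hits <- cp[hi + 1L] - cp[lo]
  cover <- hi - lo + 1L
  rate <- hits / cover
  eligible <- rate >= hit_threshold & !het
  # split runs at ineligible SNPs and at large physical gaps
  gap_break <- c(FALSE, diff(pos) > max_gap_kb * 1000)
  run_id <- cumsum(!eligible | gap_break)
  out <- list()
  for (id in unique(run_id[eligible])) {
    j <- which(run_id == id & eligible)
    if (length(j) < min_snp) next
    kb <- (pos[max(j)] - pos[min(j)] + 1) / 1000
    if (kb < min_kb) next
    dens <- kb / length(j)
    if (dens > density_kb) next
    out[[length(out) + 1L]] <- data.frame(
      start = pos[min(j)] - 1, end = pos[max(j)],
      n_snps = length(j), kb_length = kb, snp_density = dens)
  }
  if (!length(out))
    return(data.frame(start = numeric(), end = numeric(),
                      n_snps = integer(), kb_length = numeric(),
                      snp_density = numeric()))
  do.call(rbind, out)
}
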