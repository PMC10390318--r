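#' SNP table container
#'
#' A `variant_table` holds biallelic SNP sites by samples: positions, site
#' annotations (QUAL, FS, MQ), diploid genotype dosages, per-call genotype
#' qualities and, when available, phased haplotypes.  It is the substrate of
#' every scan in the package.
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions, strictly increasing
#'   within each chromosome.
#' @param ref,alt single reference/alternate bases per site.
#' @param geno integer matrix, sites x samples, with entries 0/1/2 counting
#'   copies of the alternate allele, or `NA` for missing calls.
#' @param sample_ids character vector naming the columns of `geno`.
#' @param qual numeric site quality (VCF QUAL); `NA` if absent.
#' @param fs,mq numeric INFO/FS (Fisher strand) and INFO/MQ (RMS mapping
#'   quality) annotations; `NA` where the VCF carried none.
#' @param gq optional numeric matrix of per-call genotype qualities,
#'   same shape as `geno`.
#' @param hap optional integer matrix of phased haploid alleles (0/1),
#'   sites x (2 * samples); columns `2i-1`, `2i` are the two haplotypes of
#'   sample `i`.  Row sums per sample must equal the diploid dosage.
#'
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, geno, sample_ids,
                          qual = NULL, fs = NULL, mq = NULL,
                          gq = NULL, hap = NULL) {
  n <- length(pos)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != n)
    stop("geno must have one row per site")
  if (ncol(geno) != length(sample_ids))
    stop("geno must have one column per sample id")
  fill <- function(x) if (is.null(x)) rep(NA_real_, n) else as.numeric(x)
  obj <- structure(list(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    qual = fill(qual),
    fs = fill(fs),
    mq = fill(mq),
    geno = geno,
    gq = gq,
    hap = hap,
    sample_ids = as.character(sample_ids)
  ), class = "variant_table")
  colnames(obj$geno) <- obj$sample_ids
  validate_variant_table(obj)
  obj
}

validate_variant_table <- function(x) {
  n <- length(x$pos)
  stopifnot(length(x$chrom) == n, length(x$ref) == n, length(x$alt) == n)
  if (n > 1) {
    ord <- order(match(x$chrom, unique(x$chrom)), x$pos)
    if (!all(ord == seq_len(n)))
      stop("sites must be sorted by chromosome with strictly increasing pos")
    same <- x$chrom[-1] == x$chrom[-n]
    if (any(same & diff(x$pos) <= 0))
      stop("positions must be strictly increasing within a chromosome")
  }
  bad <- x$geno[!is.na(x$geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  if (!is.null(x$gq)) {
    if (!identical(dim(x$gq), dim(x$geno)))
      stop("gq must have the same shape as geno")
  }
  if (!is.null(x$hap)) {
    if (nrow(x$hap) != n || ncol(x$hap) != 2L * ncol(x$geno))
      stop("hap must be sites x (2 * samples)")
    ds <- x$hap[, seq(1L, ncol(x$hap), by = 2L), drop = FALSE] +
      x$hap[, seq(2L, ncol(x$hap), by = 2L), drop = FALSE]
    ok <- is.na(x$geno) | is.na(ds) | ds == x$geno
    if (!all(ok))
      stop("phased haplotypes are inconsistent with diploid dosages")
  }
  invisible(x)
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d biallelic SNPs x %d samples (%s)\n",
              n_sites(x), n_samples(x),
              paste(unique(x$chrom), collapse = ", ")))
  cat(sprintf("  gq: %s  phased: %s\n",
              if (is.null(x$gq)) "absent" else "present",
              if (is.null(x$hap)) "absent" else "present"))
  invisible(x)
}

#' @rdname variant_table
#' @param x a `variant_table`.
#' @export
n_sites <- function(x) length(x$pos)

#' @rdname variant_table
#' @export
n_samples <- function(x) ncol(x$geno)

#' Subset a variant table by site index and/or samples
#'
#' @param x a `variant_table`.
#' @param sites integer or logical index over sites.
#' @param samples character vector of sample ids (or index) to keep.
#' @return the subset `variant_table`.
#' @export
subset_variants <- function(x, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(x))
  if (is.logical(sites)) sites <- which(sites)
  scol <- seq_len(n_samples(x))
  if (!is.null(samples)) {
    if (is.character(samples)) {
      scol <- match(samples, x$sample_ids)
      if (anyNA(scol))
        stop("unknown sample ids: ",
             paste(samples[is.na(scol)], collapse = ", "))
    } else scol <- samples
  }
  hcol <- as.vector(rbind(2L * scol - 1L, 2L * scol))
  variant_table(
    chrom = x$chrom[sites], pos = x$pos[sites],
    ref = x$ref[sites], alt = x$alt[sites],
    geno = x$geno[sites, scol, drop = FALSE],
    sample_ids = x$sample_ids[scol],
    qual = x$qual[sites], fs = x$fs[sites], mq = x$mq[sites],
    gq = if (is.null(x$gq)) NULL else x$gq[sites, scol, drop = FALSE],
    hap = if (is.null(x$hap)) NULL else x$hap[sites, hcol, drop = FALSE]
  )
}

#' Genomic windows and intervals
#'
#' Intervals are handled as plain data frames with columns `chrom`,
#' `start` (0-based inclusive) and `end` (0-based exclusive); VCF positions
#' stay 1-based at the boundary and BED output is 0-based, so a site at VCF
#' position `p` falls in the interval iff `start < p <= end`.
#'
#' @param chrom,start,end vectors of equal length.
#' @return a data.frame with class `genomic_intervals` prepended.
#' @export
genomic_intervals <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("intervals require start < end")
  if (any(start < 0)) stop("negative interval start")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

sites_to_granges <- function(tab) {
  GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$pos, tab$pos))
}
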