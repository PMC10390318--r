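#' Mask low-quality genotype calls
#'
#' Sets every genotype call with genotype quality (GQ) strictly below
#' `gq_min` to missing, the masking step applied before site filtering so
#' that allele frequencies and missingness are computed on trusted calls
#' only.
#'
#' @param tab a [variant_table()].
#' @param gq_min minimum GQ retained (default 10); calls with `gq < gq_min`
#'   become missing, calls at exactly `gq_min` are kept.
#' @return the masked `variant_table`.  Tables without GQ are returned
#'   unchanged with a warning.
#' @export
mask_low_gq <- function(tab, gq_min = 10) {
  if (gq_min < 0) stop("gq_min must be non-negative")
  if (is.null(tab$gq)) {
    warning("table carries no GQ; mask_low_gq is a no-op")
    return(tab)
  }
  drop <- !is.na(tab$gq) & tab$gq < gq_min
  tab$geno[drop] <- NA_integer_
  if (!is.null(tab$hap)) {
    idx <- which(drop, arr.ind = TRUE)
    if (nrow(idx)) {
      tab$hap[cbind(idx[, 1L], 2L * idx[, 2L] - 1L)] <- NA_integer_
      tab$hap[cbind(idx[, 1L], 2L * idx[, 2L])] <- NA_integer_
    }
  }
  tab
}

#' Per-site summary statistics
#'
#' Computes, for every site, the minor allele frequency, missing-call rate,
#' the fraction of samples with a non-missing genotype of quality at least
#' `gq_min` (the `F_PASS` quantity of the hard filter), and a
#' transition flag.  Rates are computed on the genotypes as given, i.e.
#' after any masking already applied.
#'
#' @param tab a [variant_table()].
#' @param gq_min GQ threshold entering the pass fraction (default 10).
#' @return a data.frame with columns `chrom`, `pos`, `maf`, `missing_rate`,
#'   `pass_fraction`, `is_transition`.
#' @export
site_stats <- function(tab, gq_min = 10) {
  ns <- n_samples(tab)
  called <- !is.na(tab$geno)
  n_called <- rowSums(called)
  alt_count <- rowSums(tab$geno, na.rm = TRUE)
  af <- ifelse(n_called > 0, alt_count / (2 * n_called), NA_real_)
  maf <- pmin(af, 1 - af)
  if (is.null(tab$gq)) {
    pass <- n_called / ns
  } else {
    pass <- rowSums(called & !is.na(tab$gq) & tab$gq >= gq_min) / ns
  }
  data.frame(chrom = tab$chrom, pos = tab$pos,
             maf = maf,
             missing_rate = 1 - n_called / ns,
             pass_fraction = pass,
             is_transition = is_transition(tab$ref, tab$alt),
             stringsAsFactors = FALSE)
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Hard site filter
#'
#' Applies the combined site filter: a site survives iff
#' `QUAL >= qual_min`, `FS <= fs_max`, `MQ >= mq_min`, the fraction of
#' samples with a called genotype of `GQ >= 10` is at least
#' `pass_frac_min`, the minor allele frequency is at least `maf_min`, and
#' the missing-call rate is at most `missing_max`.  All removals use strict
#' inequalities, so boundary values (e.g. MAF exactly 0.05, missingness
#' exactly 0.20) survive.  Sites lacking an FS or MQ annotation pass those
#' clauses (absence of an annotation is not evidence of failure).
#'
#' Genotype masking ([mask_low_gq()]) is a documented precondition and is
#' not re-applied here; MAF and missingness are computed on the genotypes
#' as given.
#'
#' @param tab a [variant_table()] (after [mask_low_gq()]).
#' @param qual_min,fs_max,mq_min site-annotation thresholds
#'   (defaults 30, 60, 40).
#' @param pass_frac_min minimum fraction of samples with a good call
#'   (default 0.8).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param missing_max maximum missing rate (default 0.20).
#' @param gq_min GQ threshold used inside the pass fraction (default 10).
#' @return a list with elements `table` (the surviving `variant_table`) and
#'   `stats` (per-site statistics for **all** input sites, with a logical
#'   `pass` column).
#' @export
filter_sites <- function(tab, qual_min = 30, fs_max = 60, mq_min = 40,
                         pass_frac_min = 0.8, maf_min = 0.05,
                         missing_max = 0.20, gq_min = 10) {
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must lie in [0, 0.5]")
  if (missing_max < 0 || missing_max > 1)
    stop("missing_max must lie in [0, 1]")
  if (pass_frac_min < 0 || pass_frac_min > 1)
    stop("pass_frac_min must lie in [0, 1]")
  st <- site_stats(tab, gq_min = gq_min)
  keep <- (is.na(tab$qual) | tab$qual >= qual_min) &
    (is.na(tab$fs) | tab$fs <= fs_max) &
    (is.na(tab$mq) | tab$mq >= mq_min) &
    st$pass_fraction >= pass_frac_min &
    !is.na(st$maf) & st$maf >= maf_min &
    st$missing_rate <= missing_max
  st$pass <- keep
  list(table = subset_variants(tab, sites = keep), stats = st)
}

#' Transition/transversion ratio
#'
#' Ratio of transition SNPs (A<->G, C<->T) to transversion SNPs over all
#' sites in the table; a well-behaved SNP set is expected near 2.
#'
#' @param tab a non-empty [variant_table()].
#' @return the Ts/Tv ratio; `Inf` if the table holds no transversion.
#' @export
ts_tv_ratio <- function(tab) {
  if (n_sites(tab) == 0L) stop("Ts/Tv undefined on an empty table")
  ts <- sum(is_transition(tab$ref, tab$alt))
  tv <- n_sites(tab) - ts
  if (tv == 0L) Inf else ts / tv
}
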