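#' Strict genotype filter for clock sites
#'
#' High-confidence filter applied before divergence estimation: a variant
#' site is retained iff its QUAL is at least `qual_min` and every chosen
#' accession carries a non-missing call with GQ at least `gq_min`
#' (removal uses strict `<`, so boundary values survive).  Invariant
#' clock sites, being absent from the variant table, are unaffected and
#' enter the divergence denominator downstream.
#'
#' @param tab a [variant_table()].
#' @param samples the accessions entering the estimate (typically three:
#'   one from each focal population and the calibration outgroup).
#' @param qual_min,gq_min thresholds (defaults 60 and 30).
#' @return the retained [variant_table()], restricted to `samples`.
#' @export
strict_site_filter <- function(tab, samples = tab$sample_ids,
                               qual_min = 60, gq_min = 30) {
  sub <- subset_variants(tab, samples = samples)
  called <- rowSums(is.na(sub$geno)) == 0L
  qual_ok <- !is.na(sub$qual) & sub$qual >= qual_min
  gq_ok <- if (is.null(sub$gq)) rep(TRUE, n_sites(sub))
  else rowSums(is.na(sub$gq) | sub$gq < gq_min) == 0L
  subset_variants(sub, sites = called & qual_ok & gq_ok)
}

#' Mean per-site divergence between two diploid accessions
#'
#' The expected per-site difference between two diploids is the mean of
#' the four haploid allele comparisons, `(gx (2 - gy) + gy (2 - gx)) / 4`
#' in dosage form.  Sites absent from the table (invariant clock sites)
#' count as zero difference, with `n_total_sites` as the denominator, so
#' the result is a per-site distance over the full clock-site set.
#'
#' @param tab a [variant_table()] of retained variant sites.
#' @param sample_x,sample_y sample ids.
#' @param n_total_sites total number of clock sites (variant + invariant);
#'   defaults to the variant count in `tab`.
#' @return a list: `d` (mean per-site difference), `n_variant_used`,
#'   `n_total_sites`.
#' @export
pairwise_divergence <- function(tab, sample_x, sample_y,
                                n_total_sites = NULL) {
  if (is.null(n_total_sites)) n_total_sites <- n_sites(tab)
  if (n_total_sites < 1) stop("no sites to compare")
  gx <- tab$geno[, match(sample_x, tab$sample_ids)]
  gy <- tab$geno[, match(sample_y, tab$sample_ids)]
  ok <- !is.na(gx) & !is.na(gy)
  per_site <- (gx[ok] * (2 - gy[ok]) + gy[ok] * (2 - gx[ok])) / 4
  list(d = sum(per_site) / n_total_sites,
       n_variant_used = sum(ok),
       n_total_sites = n_total_sites)
}

#' Calibration-ratio divergence time
#'
#' Strict-clock ratio estimator: with a per-site distance `d_target`
#' between the two focal accessions and `d_calib` between the focal
#' ingroup and a calibration outgroup of known divergence `t_calib`,
#' `t_estimate = t_calib * d_target / d_calib`.  This deliberately simple
#' estimator replaces Bayesian relaxed-clock dating; it is exact under a
#' strict molecular clock and scale-invariant in the distances.
#'
#' @param d_target,d_calib per-site distances in `[0, 1]`.
#' @param t_calib calibration divergence in years (default 780,000, a
#'   wild-oat/cultivated-oat calibration).
#' @param n_sites optional retained-site count, carried through.
#' @return a list of class `divergence_estimate`: `d_target`, `d_calib`,
#'   `t_calib`, `t_estimate`, `n_sites`.
#' @export
calibrated_split_time <- function(d_target, d_calib, t_calib = 780000,
                                  n_sites = NA_integer_) {
  if (d_calib <= 0) stop("d_calib must be positive")
  structure(list(d_target = d_target, d_calib = d_calib,
                 t_calib = t_calib,
                 t_estimate = t_calib * d_target / d_calib,
                 n_sites = n_sites),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("calibrated split time: %.0f years\n", x$t_estimate))
  cat(sprintf("  d_target %.3e  d_calib %.3e  t_calib %.0f  sites %s\n",
              x$d_target, x$d_calib, x$t_calib,
              ifelse(is.na(x$n_sites), "?", x$n_sites)))
  invisible(x)
}

#' One-call divergence-time pipeline
#'
#' Applies [strict_site_filter()] to the three chosen accessions, computes
#' the focal-pair distance and the mean ingroup-outgroup distance over the
#' clock-site set, and returns the calibration-ratio estimate.
#'
#' @param tab a [variant_table()] restricted to (or containing) the three
#'   accessions.
#' @param sample_x,sample_y the two focal accessions (e.g. one naked and
#'   one hulled oat).
#' @param sample_out the calibration outgroup accession.
#' @param n_total_sites total clock-site count (variant + invariant).
#' @param t_calib calibration time in years.
#' @param qual_min,gq_min strict-filter thresholds.
#' @return a `divergence_estimate` (see [calibrated_split_time()]).
#' @export
estimate_divergence_time <- function(tab, sample_x, sample_y, sample_out,
                                     n_total_sites = NULL,
                                     t_calib = 780000,
                                     qual_min = 60, gq_min = 30) {
  keep <- strict_site_filter(tab, c(sample_x, sample_y, sample_out),
                             qual_min = qual_min, gq_min = gq_min)
  if (is.null(n_total_sites)) n_total_sites <- n_sites(keep)
  d_xy <- pairwise_divergence(keep, sample_x, sample_y, n_total_sites)$d
  d_xo <- pairwise_divergence(keep, sample_x, sample_out, n_total_sites)$d
  d_yo <- pairwise_divergence(keep, sample_y, sample_out, n_total_sites)$d
  calibrated_split_time(d_xy, (d_xo + d_yo) / 2, t_calib,
                        n_sites = n_sites(keep))
}
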