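#' Simulation configuration
#'
#' Parameters of the founder-mosaic cohort simulator.  Two ingroup
#' populations (hulled `OH` and naked-landrace `ONL`) diverged `t_split`
#' generations ago, an outgroup `OG` diverged `t_og` generations ago, and
#' a cultivar group `ONC` descends from `ONL` with an admixture pulse of
#' fraction `f` from `OH`.  Each population carries `founders_per_pop`
#' founder haplotypes coalescing `t_within` generations back; every sample
#' haplotype is a recombinant mosaic of its population's founders with a
#' Poisson(`recomb_rate * seq_length * admix_age`) crossover count, so
#' donor tracts have roughly exponential lengths with mean
#' `1 / (recomb_rate * admix_age)`.
#'
#' With `admix_mode = "shared"` (default) the pulse enters the cultivar
#' group's common ancestor: one donor-ancestry template is drawn (tract
#' donors i.i.d. `OH` with probability `f`) and every `ONC` haplotype
#' inherits it, choosing its own founders within each pool — this yields
#' the *common* introgressed segments a breeding pedigree produces.
#' `"independent"` redraws donors i.i.d. for every haplotype.
#'
#' @param seq_length simulated genome length in bp (one chromosome).
#' @param chrom chromosome name.
#' @param n_oh,n_onl,n_onc,n_og diploid sample counts per population.
#' @param founders_per_pop founder haplotypes per population.
#' @param mu per-site per-generation mutation rate (default 6.5e-9).
#' @param recomb_rate per-bp per-generation recombination rate.
#' @param t_split,t_og generations since the OH/ONL split and since the
#'   outgroup split (`t_og > t_split`).
#' @param t_within founder coalescence depth within a population,
#'   generations (`< t_split`); a single number or a named vector with
#'   entries `OH`, `ONL`, `OG` to give populations unequal diversity.
#' @param admix_fraction admixture pulse fraction `f` in `[0, 1]`.
#' @param admix_age generations since the pulse (also the mosaic age).
#' @param admix_mode `"shared"` or `"independent"` (see above).
#' @param anc_poly_factor amount of ancestral standing variation shared
#'   across the split (incomplete lineage sorting): the expected count of
#'   such sites is `anc_poly_factor * mu * t_split * seq_length`, each
#'   segregating at a Uniform(0.1, 0.9) frequency independently in both
#'   ingroup founder pools and absent from the outgroup.  These sites make
#'   the four-taxon test informative under the null; they also add a known
#'   upward bias to naive clock distances, so the default is kept modest.
#' @param transition_bias odds of a transition over any transversion; the
#'   expected Ts/Tv ratio of emitted SNPs equals this value (default 2).
#' @param error_rate per-call genotype miscall probability.
#' @param gq_correct_lambda,gq_error_lambda Poisson rates of the genotype
#'   quality model: correct calls get `GQ = 30 + Pois(gq_correct_lambda)`,
#'   miscalls `GQ = Pois(gq_error_lambda)` (both capped at 99), so GQ<10
#'   masking removes most miscalls and GQ<30 removes essentially all.
#' @param bad_site_frac fraction of sites given failing QUAL/FS/MQ
#'   annotations, to exercise the hard site filter.
#' @param causal_region_bp length of the planted causal region.
#' @param causal_effect trait-unit effect per causal haplotype copy.
#' @param min_ibd_length minimum true-IBD segment length recorded (bp).
#' @param seed RNG seed; fixed seed gives a bit-identical cohort.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seq_length = 20e6, chrom = "chr1",
                       n_oh = 10, n_onl = 10, n_onc = 8, n_og = 4,
                       founders_per_pop = 6,
                       mu = 6.5e-9, recomb_rate = 5e-8,
                       t_split = 50000, t_og = 780000, t_within = 5000,
                       admix_fraction = 0.1, admix_age = 10,
                       admix_mode = c("shared", "independent"),
                       anc_poly_factor = 0.3,
                       transition_bias = 2,
                       error_rate = 0.002,
                       gq_correct_lambda = 45, gq_error_lambda = 6,
                       bad_site_frac = 0.02,
                       causal_region_bp = 1e4, causal_effect = 1,
                       min_ibd_length = 1e5,
                       seed = 1) {
  admix_mode <- match.arg(admix_mode)
  tw <- t_within
  if (is.null(names(tw))) tw <- c(OH = tw[[1]], ONL = tw[[1]], OG = tw[[1]])
  for (p in c("OH", "ONL", "OG"))
    if (is.na(tw[p])) tw[p] <- mean(t_within)
  cfg <- list(seq_length = seq_length, chrom = chrom,
              n_oh = n_oh, n_onl = n_onl, n_onc = n_onc, n_og = n_og,
              founders_per_pop = founders_per_pop,
              mu = mu, recomb_rate = recomb_rate,
              t_split = t_split, t_og = t_og, t_within = tw,
              admix_fraction = admix_fraction, admix_age = admix_age,
              admix_mode = admix_mode,
              anc_poly_factor = anc_poly_factor,
              transition_bias = transition_bias,
              error_rate = error_rate,
              gq_correct_lambda = gq_correct_lambda,
              gq_error_lambda = gq_error_lambda,
              bad_site_frac = bad_site_frac,
              causal_region_bp = causal_region_bp,
              causal_effect = causal_effect,
              min_ibd_length = min_ibd_length,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (admix_fraction < 0 || admix_fraction > 1)
      stop("admix_fraction must lie in [0, 1]")
    if (!(t_og > t_split))
      stop("need t_og > t_split")
    if (!(t_split > admix_age) || admix_age < 1)
      stop("need t_split > admix_age >= 1")
    if (any(t_within >= t_split))
      stop("t_within must be smaller than t_split")
    if (min(n_oh, n_onl, n_onc, n_og, founders_per_pop) < 1)
      stop("all sample and founder counts must be >= 1")
    if (min(mu, recomb_rate, error_rate, transition_bias) < 0)
      stop("rates must be non-negative")
    if (seq_length < 1e4) stop("seq_length unreasonably small")
  })
  invisible(cfg)
}
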