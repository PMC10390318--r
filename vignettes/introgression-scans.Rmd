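---
title: "Detecting donor introgression in resequenced crop cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting donor introgression in resequenced crop cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The analysis this package implements

`introscan` packages the population-genomic workflow used to study how a
donor population's chromatin ends up inside a recipient crop gene pool —
the motivating system being hexaploid oat, where hulled oat (*Avena
sativa*, "OH") has been crossed into naked oat cultivars ("ONC") whose
base ancestry comes from naked oat landraces ("ONL"), with wild hexaploid
relatives ("OG") as the outgroup.  The same functions apply to any diploid
biallelic SNP panel with analogous group structure.

The stages, each an exported function:

* **Genotype masking and hard site filtering** (`mask_low_gq`,
  `filter_sites`).  Calls with genotype quality below 10 become missing;
  a site then survives iff `QUAL >= 30`, `FS <= 60`, `MQ >= 40`, at least
  80% of samples carry a called genotype of quality 10 or more, minor
  allele frequency is at least 0.05 and missingness at most 20%.  All
  removals are strict inequalities, so boundary values survive.  MAF and
  missingness are computed *after* masking, matching the
  mask-then-filter order of a BCFtools-style pipeline.
* **Windowed diversity and differentiation** (`nucleotide_diversity`,
  `fst_weir_cockerham`, `ibs_distance_matrix`, `subsampled_diversity`),
  defaulting to 1-Mb windows at 500-kb steps.  Per site with `n`
  non-missing alleles and `c` derived copies, pi is `2c(n-c)/(n(n-1))`;
  the window value divides the sum by the full window length in bp, the
  VCFtools windowed-pi convention (truncated terminal windows use their
  true length).  Fst is Weir & Cockerham (1984) with observed
  heterozygote counts and ratio-of-sums window averaging; negative
  windows are reported as computed.
* **Runs of homozygosity** (`roh_scan`): the PLINK `--homozyg` scanning
  heuristic with the published parameter set (50-SNP windows, at most 2
  missing and 0 heterozygous calls, minimum 50 SNPs / 500 kb / 50 kb-per-
  SNP density) and PLINK defaults for the unprinted knobs (hit threshold
  0.05, maximum gap 1000 kb).
* **LD decay** (`ld_decay`): mean squared dosage correlation of all SNP
  pairs within 1 Mb, in 500-bp distance bins — genotype r², the
  PopLDdecay default, not phased-haplotype r².
* **Four-taxon introgression test** (`patterson_d`): frequency-weighted
  ABBA-BABA `D` with alleles polarized on the outgroup (sites whose
  outgroup minor-allele frequency exceeds 0.1 are dropped as
  unpolarizable) and a weighted delete-one block jackknife over
  contiguous physical blocks (5 Mb by default) for the standard error.
  Under `patterson_d(tab, p1 = ONL, p2 = ONC, p3 = OH, outgroup = OG)`
  positive `D` means excess ONC–OH sharing.
* **rIBD scan** (`nibd_scan`, `ribd_scan`,
  `call_introgressed_segments`): per 100-kb window (50-kb step), the
  count of IBD segments joining a target cultivar haplotype to each
  candidate donor population, normalized by that population's size;
  `rIBD = nIBD_OH - nIBD_ONL`, z-standardized over all genome windows.
  Windows with `z > 2` (strict) are merged by interval union into
  introgressed segments, then annotated with overlapping genes
  (1-bp overlap rule) and per-subgenome length totals.
* **Fourfold-degenerate clock** (`fourfold_sites`,
  `strict_site_filter`, `estimate_divergence_time`): third positions of
  the eight fourfold codon families, extracted strand-aware from GFF3 +
  FASTA; genotypes pass a stricter `QUAL >= 60` / all-accession
  `GQ >= 30` filter; divergence time is the calibration ratio
  `t = t_calib * d_target / d_calib` with `t_calib = 780,000` years
  (wild-oat/cultivated-oat calibration).  This is a strict-clock
  simplification of Bayesian relaxed-clock dating: it is exact when
  rates are homogeneous, scale-invariant in the distances, and the only
  dating regime that can be validated at desk scale.  Invariant fourfold
  sites count as zero-difference sites in the denominator, so distances
  are per fourfold site, not per variant.
* **Candidate-gene haplotypes** (`group_haplotypes`,
  `compare_haplotype_phenotypes`): samples grouped by exact genotype
  identity over a gene span plus 2-kb strand-aware upstream flank
  (samples with missing calls in the region are excluded), and Welch
  two-sample t-tests between groups at alpha 0.01.  Welch is the default
  even where a classical Student test was historically used; `pooled =
  TRUE` restores the pooled-variance form.

## The synthetic cohort generator

Because the real resequencing cohorts these methods target are hundreds
of gigabytes, every scan is validated against `simulate_cohort()`, a
founder-mosaic simulator that produces a `variant_table` plus exact
ground truth.

**Genealogy.**  Each population carries `founders_per_pop` (default 6)
founder haplotypes.  Mutations (infinite-sites, integer positions,
transition:transversion odds `transition_bias = 2`, so the expected
Ts/Tv of emitted SNPs is 2) are placed on a fixed genealogy: an outgroup
branch (`t_og = 780,000` generations), an ingroup stem, population
branches splitting `t_split = 50,000` generations ago, and per-founder
private branches of depth `t_within = 5,000` generations.  Expected
pairwise divergence is therefore `2 mu t_split` between OH and ONL,
`2 mu t_og` to the outgroup, and `2 mu t_within (1 - 1/K)` within a
population, with `mu = 6.5e-9` per site per generation and a 1-year
generation.  These are deliberately desk-scale conditions: within-
population diversity (~1.6e-4 with the standing-variation term below) is
lower, and Fst correspondingly higher, than in real oat panels; the
closed forms, not realism, are what the tests exploit.

**Standing variation.**  A star genealogy alone leaves no site
polymorphic in both ingroup pools, which would starve the four-taxon test
of informative sites under the null.  A configurable class of ancestral
polymorphisms (`anc_poly_factor = 0.3`, giving an expected
`0.3 mu t_split L` sites) segregates at a Uniform(0.1, 0.9) frequency
independently in both ingroup founder pools and is absent from the
outgroup — incomplete lineage sorting in miniature.  Because `p1` and
`p2` are exchangeable at these sites, they contribute ABBA and BABA
symmetrically and `D` stays centred at zero without gene flow.  The
factor is kept modest because naive clock distances inflate by the
standing diversity; at 0.3 the divergence-time ratio estimator stays
within a few percent of truth.

**Mosaics and the pulse.**  Every sample haplotype is a recombinant
mosaic of its pool's founders with Poisson(`recomb_rate * L *
admix_age`) crossovers (defaults `5e-8`/bp and 10 generations, i.e.
2-Mb mean tracts).  The admixture pulse of fraction `f` enters the
cultivar group's *common ancestor*: one donor-ancestry template is drawn
for ONC and every ONC haplotype inherits it, choosing its own founders
within each pool.  This is what a breeding pedigree produces — *common*
introgressed segments across cultivars — and it is what a windowed
rIBD scan can detect.  Template tracts are marked as donor in random
order until the donor share reaches `f` exactly (the last tract is split
at the boundary): at a 20-Mb genome, leaving the realized fraction to
i.i.d. tract sampling would make it swing between 0 and 2–3 times `f`
from seed to seed, so the fraction is a planted condition, not a random
outcome.  `admix_mode = "independent"` restores fully independent
per-haplotype donor draws for users who want the classic
hybrid-swarm geometry.

**Noise and truth.**  Genotypes are miscalled with probability
`error_rate = 0.002`; correct calls draw `GQ = 30 + Pois(45)`, miscalls
`GQ = Pois(6)` (capped at 99), so GQ<10 masking removes ~92% of errors
and the strict GQ<30 clock filter essentially all of them.  Two percent
of sites receive failing QUAL/FS/MQ annotations to exercise the hard
filter.  The truth set records ancestry tracts per haplotype, true IBD
segments (maximal same-founder overlaps of at least `min_ibd_length =`
100 kb, a stand-in for phased-IBD detector output with perfect
sensitivity), and a causal region — a 10-kb interval centred in the
largest planted donor tract — whose donor-haplotype copies shift a
simulated phenotype by `causal_effect` trait units per copy.

**What passing tests do and do not show.**  The simulator validates the
*estimators*: that pi equals exhaustive pairwise Hamming counting, that
the ROH scan reproduces a direct transcription of the PLINK rules, that
the rIBD scan recovers planted tracts, that the clock recovers a known
split time.  It does not model hexaploid homoeology, reference bias,
variable recombination or mutation rate, phasing errors in IBD
detection, or ancestral population structure — conclusions about real
oat data inherit those caveats from the upstream tools, not from these
tests.

## Numerical and design choices

* Internal coordinates are 0-based half-open; VCF stays 1-based at the
  boundary, BED output is 0-based.  A site at VCF position `p` is in
  window `[s, e)` iff `s < p <= e`.
* Sites lacking FS or MQ annotations pass those filter clauses —
  absence of an annotation is not evidence of failure.
* `ribd_scan` z-standardizes genome-wide (not per chromosome), includes
  zero-IBD windows in the normalization, and refuses degenerate input
  (constant rIBD).  The nIBD denominator is the reference-population
  size only; constants involving the target size cancel under the
  z-normalization.
* `patterson_d` jackknife blocks are physical 5-Mb blocks (no genetic
  map is assumed); desk-scale analyses on 10–20-Mb simulated genomes use
  1–2-Mb blocks so that ~10 blocks support the variance estimate.
* Overlapping-transcript conflicts in fourfold-site extraction resolve
  by exclusion, not majority vote; codons with ambiguity codes in their
  first two bases are skipped.
* Welch's t-test is the haplotype-contrast default; groups that are both
  constant are handled explicitly (equal means: `t = 0, p = 1`).
* Whether group-level pi should be a mean over windows or a genome-wide
  ratio is ambiguous in common usage; `subsampled_diversity` and the
  examples use the mean over windows.
* Test problem sizes (5–20-Mb genomes, 32–64 haplotypes, 10–40
  simulation replicates) were chosen as the smallest instances at which
  the closed-form expectations above have small enough sampling error to
  assert tight tolerances.

## Known limitations

The founder-mosaic model has no coalescent variance within branches, no
selection, and no gene conversion; `derive_true_ibd` is truth-based and
therefore optimistic relative to RefinedIBD output on real data; the
calibration-ratio clock is biased upward when ancestral diversity is
large relative to `2 mu t_split` (documented above); and the CLI's
`simulate` subcommand exposes only the most commonly varied parameters —
use `sim_config()` directly for the rest.
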