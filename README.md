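# introscan

Windowed population-genomic scans for detecting donor introgression in
resequenced crop cohorts.

## The problem

Breeding programmes routinely cross a donor gene pool into an elite
recipient pool — the motivating case is hulled oat (*Avena sativa*, "OH")
crossed into naked oat cultivars ("ONC"), whose base ancestry comes from
naked oat landraces ("ONL"), with wild hexaploid relatives ("OG") as
outgroup.  Given a biallelic SNP panel for such a cohort, the questions
are: *is* there gene flow, *where* in the genome did the donor segments
land, *which genes* do they carry, and how do the groups compare in
diversity, differentiation, inbreeding, LD, divergence time and
candidate-gene phenotypes?

`introscan` implements that workflow end to end for people analysing
diploid resequencing panels:

* genotype-quality masking (GQ < 10 → missing) and the combined hard
  site filter `QUAL ≥ 30 ∧ FS ≤ 60 ∧ MQ ≥ 40 ∧ F_PASS(GQ≥10) ≥ 0.8 ∧
  MAF ≥ 0.05 ∧ missing ≤ 0.20`, plus Ts/Tv accounting;
* sliding-window nucleotide diversity
  π<sub>site</sub> = 2c(n−c)/(n(n−1)) summed over a window and divided
  by its length (1 Mb / 500 kb defaults), Weir–Cockerham (1984) Fst with
  ratio-of-sums window averaging, pairwise IBS distances, and repeated
  subsampling (n = 19 × 100 draws) for size-matched diversity
  comparisons;
* PLINK-style runs of homozygosity (50-SNP windows, ≤2 missing, 0 het,
  ≥50 SNPs, ≥500 kb, ≤50 kb/SNP) and LD-decay profiles (genotype r²
  within 1 Mb, 500-bp bins);
* Patterson's D (ABBA–BABA) with outgroup polarization and a weighted
  block-jackknife z-score: D = Σ(ABBA−BABA)/Σ(ABBA+BABA) with
  ABBA = (1−p̂₁)p̂₂p̂₃(1−p̂₄), BABA = p̂₁(1−p̂₂)p̂₃(1−p̂₄);
* the rIBD introgression scan: per 100-kb window (50-kb step),
  nIBD = (IBD segments shared with a reference population)/|population|,
  rIBD = nIBD_OH − nIBD_ONL, z-standardized genome-wide; windows with
  z > 2 merged into introgressed segments, with gene overlap and
  per-subgenome length totals;
* fourfold-degenerate site extraction from GFF3 + FASTA, a strict
  QUAL ≥ 60 / GQ ≥ 30 genotype filter, and a calibration-ratio
  divergence clock t = t_calib · d_target/d_calib (t_calib = 0.78 My);
* candidate-gene haplotype grouping (exact genotype identity over the
  gene ± 2-kb upstream flank) with Welch t-test phenotype contrasts.

Because the real cohorts are terabyte-scale, the package ships a
founder-mosaic cohort simulator (`simulate_cohort`) that plants an
admixture pulse with exact ancestry-tract ground truth, true IBD
segments, genotype-call noise with a correctness-dependent GQ model, and
a causal phenotype region — every scan is validated against it.  See the
vignette (`vignettes/introgression-scans.Rmd`) for the model and its
assumptions.

## Worked example

```r
library(introscan)

cfg <- sim_config(seq_length = 20e6, admix_fraction = 0.1, seed = 42)
cohort <- simulate_cohort(cfg)

tab <- mask_low_gq(cohort$table, gq_min = 10)
filt <- filter_sites(tab)
cat(sprintf("%d of %d sites pass the hard filter; Ts/Tv = %.2f\n",
            n_sites(filt$table), n_sites(tab), ts_tv_ratio(filt$table)))

pops <- cohort$populations
grp <- function(p) names(pops)[pops == p]

w <- make_windows(c(chr1 = cfg$seq_length), size = 1e6, step = 5e5)
pi_onl <- nucleotide_diversity(tab, grp("ONL"), w)
cat(sprintf("mean windowed pi (ONL) = %.3e\n", mean(pi_onl$value)))

d <- patterson_d(tab, p1 = grp("ONL"), p2 = grp("ONC"),
                 p3 = grp("OH"), outgroup = grp("OG"), block_size = 2e6)
print(d)

wk <- make_windows(c(chr1 = cfg$seq_length), size = 1e5, step = 5e4)
rw <- ribd_scan(cohort$truth$true_ibd, target = grp("ONC"),
                pop_oh = grp("OH"), pop_onl = grp("ONL"), wk)
calls <- call_introgressed_segments(rw, z_threshold = 2,
                                    chrom_lengths = c(chr1 = cfg$seq_length))
cat(sprintf("%d introgressed segment(s), %.2f Mb (%.1f%% of genome)\n",
            nrow(calls$segments), calls$total_bp / 1e6,
            100 * calls$genome_fraction))

est <- estimate_divergence_time(tab, grp("OH")[1], grp("ONL")[1],
                                grp("OG")[1],
                                n_total_sites = cfg$seq_length,
                                t_calib = cfg$t_og)
print(est)
```

which prints:

```
210560 of 220291 sites pass the hard filter; Ts/Tv = 2.00
mean windowed pi (ONL) = 9.052e-05
Patterson's D = 0.6022  (SE 0.1485, z = 4.05)
  ABBA 773.8  BABA 192.1  informative sites 3084  blocks 10
1 introgressed segment(s), 1.95 Mb (9.8% of genome)
calibrated split time: 52283 years
  d_target 6.751e-04  d_calib 1.007e-02  t_calib 780000  sites 217522
```

Reading the output: the site filter removes the ~2% of sites given
failing annotations plus rare/over-missing sites; Ts/Tv sits at the
configured transition odds of 2.  The positive D with z > 3 says ONC
shares significantly more derived alleles with OH than the landraces do
— the planted pulse.  The rIBD scan localizes it: the called segment
total (1.95 Mb, 9.8% of this toy genome) matches the planted donor
fraction f = 0.1, and the clock recovers the configured 50,000-generation
split (1-year generations) within ~5%.

A thin CLI wraps the same functions
(`inst/exec/introscan simulate|filter|pi|fst|ribd|dstat|fourfold|divtime`);
run it with `help` for usage.

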