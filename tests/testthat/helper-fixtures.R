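# Hand-constructable variant tables and shared simulated cohorts.

make_table <- function(geno, pos = NULL, chrom = "chr1", ref = NULL,
                       alt = NULL, qual = NULL, fs = NULL, mq = NULL,
                       gq = NULL, hap = NULL, ids = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("C", n)
  if (is.null(ids)) ids <- paste0("S", seq_len(ncol(geno)))
  variant_table(chrom = rep(chrom, n), pos = pos, ref = ref, alt = alt,
                geno = geno, sample_ids = ids, qual = qual, fs = fs,
                mq = mq, gq = gq, hap = hap)
}

# random table with phased haplotypes and no missing data
random_hap_table <- function(n_hap, n_sites, span, seed) {
  set.seed(seed)
  pos <- sort(sample.int(span, n_sites))
  hap <- matrix(0L, n_sites, n_hap)
  # each site gets a random derived count in 1..n_hap-1 so it segregates
  for (i in seq_len(n_sites))
    hap[i, sample.int(n_hap, sample(n_hap - 1L, 1L))] <- 1L
  geno <- hap[, seq(1L, n_hap, 2L), drop = FALSE] +
    hap[, seq(2L, n_hap, 2L), drop = FALSE]
  make_table(geno, pos = pos, hap = hap)
}

# cached mid-size cohort shared across test files (same seed everywhere)
.cohorts <- new.env(parent = emptyenv())
shared_cohort <- function(seq_length = 5e6, seed = 101, ...) {
  key <- paste(seq_length, seed, ...)
  if (is.null(.cohorts[[key]]))
    .cohorts[[key]] <- simulate_cohort(
      sim_config(seq_length = seq_length, seed = seed, ...))
  .cohorts[[key]]
}

pop_ids <- function(cohort, pop) {
  names(cohort$populations)[cohort$populations == pop]
}

# toy genome/annotation pair used across the fourfold tests:
#   fwd gene (3..8, 12..17, +): transcript ATG GCT ACC TAG
#   rev gene (19..27, -):       transcript CCG GAA ATT
toy_genome_files <- function() {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "AAATGGCTGGAACCTAGAAATTTCCGGA"), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t3\t17\t.\t+\t.\tID=gf",
    "chr1\tt\tmRNA\t3\t17\t.\t+\t.\tID=fwd;Parent=gf",
    "chr1\tt\tCDS\t3\t8\t.\t+\t0\tParent=fwd",
    "chr1\tt\tCDS\t12\t17\t.\t+\t0\tParent=fwd",
    "chr1\tt\tgene\t19\t27\t.\t-\t.\tID=gr",
    "chr1\tt\tmRNA\t19\t27\t.\t-\t.\tID=rev;Parent=gr",
    "chr1\tt\tCDS\t19\t27\t.\t-\t0\tParent=rev"), gff)
  list(fa = fa, gff = gff)
}

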