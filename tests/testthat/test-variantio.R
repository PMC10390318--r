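vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FS\">",
  "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
  "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2")

write_toy_vcf <- function(body, path = tempfile(fileext = ".vcf")) {
  writeLines(c(vcf_header, body), path)
  path
}

test_that("read_vcf keeps biallelic SNPs, decodes GT/GQ and phase", {
  path <- write_toy_vcf(c(
    "chr1\t100\t.\tA\tG\t50\tPASS\tFS=1.0;MQ=55\tGT:GQ\t0/0:40\t0/1:35",
    "chr1\t200\t.\tC\tT,G\t50\tPASS\tFS=1.0;MQ=55\tGT:GQ\t0/1:40\t1/2:35",
    "chr1\t300\t.\tG\tA\t50\tPASS\tFS=2.5;MQ=50\tGT:GQ\t./.:.\t1/1:60",
    "chr1\t400\t.\tT\tTA\t50\tPASS\tFS=1.0;MQ=55\tGT:GQ\t0/0:40\t0/1:35",
    "chr1\t500\t.\tT\tA\t50\tPASS\tFS=1.0;MQ=55\tGT:GQ\t0/0:20\t1/1:99"))
  expect_message(tab <- read_vcf(path), "excluded")
  expect_equal(n_sites(tab), 3L)          # triallelic and indel dropped
  expect_equal(tab$pos, c(100L, 300L, 500L))
  expect_equal(unname(tab$geno[, "S1"]), c(0L, NA, 0L))
  expect_equal(unname(tab$geno[, "S2"]), c(1L, 2L, 2L))
  expect_equal(unname(tab$gq[, "S2"]), c(35, 60, 99))
  expect_equal(tab$fs, c(1.0, 2.5, 1.0))
  expect_equal(tab$mq, c(55, 50, 55))
  expect_null(tab$hap)                    # unphased input
})

test_that("fully phased records populate haplotypes consistently", {
  path <- write_toy_vcf(
    "chr1\t100\t.\tA\tG\t50\tPASS\tFS=1.0;MQ=55\tGT\t0|1\t1|1")
  tab <- read_vcf(path)
  expect_equal(unname(tab$hap[1, ]), c(0L, 1L, 1L, 1L))
  expect_equal(unname(tab$geno[1, ]), c(1L, 2L))
})

test_that("a VCF without biallelic SNPs yields an empty table, missing file errors", {
  path <- write_toy_vcf(
    "chr1\t400\t.\tT\tTA\t50\tPASS\tFS=1.0;MQ=55\tGT\t0/0\t0/1")
  expect_warning(suppressMessages(tab <- read_vcf(path)),
                 "no biallelic")
  expect_equal(n_sites(tab), 0L)
  expect_error(read_vcf(tempfile()), "not found")
})

test_that("mask_low_gq masks strictly below the threshold only", {
  tab <- make_table(rbind(c(1L, 2L), c(0L, 1L)),
                    gq = rbind(c(9, 10), c(30, 5)))
  m <- mask_low_gq(tab, 10)
  expect_equal(unname(m$geno), rbind(c(NA, 2L), c(0L, NA)))
  expect_error(mask_low_gq(tab, -1), "non-negative")
  tab_nogq <- make_table(rbind(c(1L, 2L)))
  expect_warning(m2 <- mask_low_gq(tab_nogq), "no-op")
  expect_identical(m2$geno, tab_nogq$geno)
})

test_that("filter_sites keeps exactly the sites passing every clause", {
  # seven sites: one violating each clause, one passing all
  geno <- rbind(
    c(0L, 1L, 1L, 0L, 1L),    # passes everything
    c(0L, 1L, 1L, 0L, 1L),    # qual too low
    c(0L, 1L, 1L, 0L, 1L),    # FS too high
    c(0L, 1L, 1L, 0L, 1L),    # MQ too low
    c(0L, 1L, 1L, 0L, 1L),    # pass fraction too low (called but GQ < 10)
    c(0L, 0L, 0L, 0L, 0L),    # monomorphic: maf 0 < 0.05
    c(0L, 1L, NA, NA, NA))    # missing 0.6 (> 0.2; also sinks pass frac)
  gq <- matrix(50, nrow(geno), ncol(geno))
  gq[5, 1:2] <- 5            # two poor calls: pass fraction 0.6 < 0.8
  tab <- make_table(geno,
                    qual = c(40, 29.9, 40, 40, 40, 40, 40),
                    fs = c(10, 10, 60.1, 10, 10, 10, 10),
                    mq = c(50, 50, 50, 39.9, 50, 50, 50),
                    gq = gq)
  res <- filter_sites(tab)
  expect_equal(which(res$stats$pass), 1L)
  expect_equal(n_sites(res$table), 1L)
  expect_equal(res$table$pos, tab$pos[1])
})

test_that("boundary values survive the filter and the filter is idempotent", {
  # maf exactly 0.05 (1 alt allele in 10), missing exactly 0.20 (1 of 5)
  geno <- rbind(c(1L, 0L, 0L, 0L, 0L),
                c(1L, 1L, 0L, 0L, NA))
  tab <- make_table(geno, qual = c(30, 30), fs = c(60, 60),
                    mq = c(40, 40))
  res <- filter_sites(tab)
  expect_true(all(res$stats$pass))
  twice <- filter_sites(res$table)
  expect_identical(twice$table$pos, res$table$pos)
  expect_identical(twice$table$geno, res$table$geno)
})

test_that("filter_sites survivors satisfy every clause on independent re-check", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200; ns <- 10
    geno <- matrix(sample(c(0L, 1L, 2L, NA), n * ns, replace = TRUE,
                          prob = c(0.5, 0.2, 0.2, 0.1)), n)
    tab <- make_table(geno,
                      pos = sort(sample.int(1e6, n)),
                      qual = runif(n, 0, 100),
                      fs = rexp(n, 1 / 30),
                      mq = runif(n, 20, 60),
                      gq = matrix(sample(0:60, n * ns, TRUE), n))
    tab <- suppressWarnings(mask_low_gq(tab))
    res <- filter_sites(tab)
    expect_identical(res$stats$pass, oracle_filter_pass(tab))
    # and empty-table input passes through
    expect_equal(n_sites(filter_sites(subset_variants(tab, 0))$table), 0L)
  }
})

test_that("ts_tv_ratio counts transition pairs and flags edge cases", {
  tab <- make_table(matrix(1L, 3, 2), ref = c("A", "C", "A"),
                    alt = c("G", "T", "C"))
  expect_equal(ts_tv_ratio(tab), 2)
  all_ts <- make_table(matrix(1L, 2, 2), ref = c("A", "C"),
                       alt = c("G", "T"))
  expect_equal(ts_tv_ratio(all_ts), Inf)
  expect_error(ts_tv_ratio(subset_variants(tab, 0)), "empty")
})

test_that("simulated SNPs realize the configured Ts/Tv odds", {
  co <- shared_cohort()
  expect_equal(ts_tv_ratio(co$table), co$config$transition_bias,
               tolerance = 0.05)
})

test_that("IBD TSV round-trips with 1-based to half-open conversion", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("S1\t1\tS2\t2\tchr1\t1001\t2000\t9.3",
               "S1\t2\tS3\t1\tchr1\t5001\t9000\t4.0",
               "S2\t1\tS3\t2\tchr2\t1\t500\t3.1",
               "S4\t1\tS5\t1\tchr1\t900\t100\t2.0"), path)  # end < start
  expect_warning(seg <- read_ibd_segments(path), "1 malformed")
  expect_equal(nrow(seg), 3L)
  expect_equal(seg$start[1], 1000)
  expect_equal(seg$end[1], 2000)
  out <- tempfile(fileext = ".tsv")
  write_ibd_segments(seg, out)
  again <- read_ibd_segments(out)
  expect_equal(again, seg)
  empty <- tempfile(); writeLines("x\ty", empty)
  expect_error(suppressWarnings(read_ibd_segments(empty)))
})

test_that("write_bed orders records and round-trips; empty input gives empty file", {
  iv <- genomic_intervals(c("chr2", "chr1", "chr1"),
                          c(500, 0, 100), c(600, 100, 300))
  path <- tempfile(fileext = ".bed")
  write_bed(iv, path)
  lines <- readLines(path)
  expect_equal(lines[1], "chr2\t500\t600")  # input chrom order preserved
  back <- read_bed(path)
  expect_equal(back$start, c(500, 0, 100))
  empty_path <- tempfile()
  write_bed(iv[0, ], empty_path)
  expect_equal(length(readLines(empty_path)), 0L)
})

test_that("gene models order CDS by transcript, flag malformed lengths", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", paste(rep("ACGT", 30), collapse = "")), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tmRNA\t3\t20\t.\t+\t.\tID=fwd",
    "chr1\tt\tCDS\t3\t8\t.\t+\t0\tParent=fwd",
    "chr1\tt\tCDS\t12\t17\t.\t+\t0\tParent=fwd",
    "chr1\tt\tmRNA\t30\t50\t.\t-\t.\tID=rev",
    "chr1\tt\tCDS\t30\t38\t.\t-\t0\tParent=rev",
    "chr1\tt\tCDS\t45\t50\t.\t-\t0\tParent=rev",
    "chr1\tt\tmRNA\t60\t70\t.\t+\t.\tID=bad",
    "chr1\tt\tCDS\t60\t69\t.\t+\t0\tParent=bad"), gff)
  expect_warning(gm <- read_gene_models(gff, fa), "malformed")
  expect_named(gm$models, c("fwd", "rev"))
  expect_equal(gm$models$fwd$cds$start, c(2, 11))
  # reverse strand: transcript order is descending genomic coordinate
  expect_equal(gm$models$rev$cds$start, c(44, 29))
  expect_equal(gm$n_malformed, 1L)
})

test_that("gene models on a missing contig raise a named error", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrX", "ACGTACGTACGT"), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr9\tt\tmRNA\t1\t6\t.\t+\t.\tID=m",
               "chr9\tt\tCDS\t1\t6\t.\t+\t0\tParent=m"), gff)
  expect_error(read_gene_models(gff, fa), "chr9")
})

test_that("sample sheets and phenotype tables parse", {
  ss <- tempfile(); writeLines(c("sample_id\tpopulation",
                                 "a1\tOH", "a2\tONL"), ss)
  m <- read_sample_sheet(ss)
  expect_equal(m[["a1"]], "OH")
  dup <- tempfile(); writeLines(c("a1\tOH", "a1\tONL"), dup)
  expect_error(read_sample_sheet(dup), "duplicated")
  ph <- tempfile()
  writeLines(c("sample_id\ttrait\tvalue", "a1\tyield\t3.5"), ph)
  expect_equal(read_phenotypes(ph)$value, 3.5)
})

test_that("VCF coordinates survive a write/read/write cycle", {
  co <- shared_cohort()
  sub <- subset_variants(co$table, sites = 1:200)
  p1 <- tempfile(fileext = ".vcf"); write_vcf(sub, p1)
  r1 <- read_vcf(p1)
  expect_identical(r1$pos, sub$pos)
  expect_identical(unname(r1$geno), unname(sub$geno))
  expect_identical(unname(r1$hap), unname(sub$hap))
  p2 <- tempfile(fileext = ".vcf"); write_vcf(r1, p2)
  expect_identical(readLines(p1), readLines(p2))
})
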