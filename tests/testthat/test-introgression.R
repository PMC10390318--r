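dstat_table <- function(p1g, p2g, p3g, p4g, pos = NULL) {
  g <- cbind(p1g, p2g, p3g, p4g)
  n <- nrow(g)
  make_table(g, pos = if (is.null(pos)) seq_len(n) * 1e6 else pos,
             ids = paste0("S", seq_len(ncol(g))))
}

test_that("pure ABBA sites give D = 1 and label exchange negates D", {
  # p2 = p3 fixed derived, p1 = outgroup fixed ancestral, two blocks
  tab <- dstat_table(rep(0L, 4), rep(2L, 4), rep(2L, 4), rep(0L, 4),
                     pos = c(1e6, 2e6, 7e6, 8e6))
  d <- patterson_d(tab, "S1", "S2", "S3", "S4")
  expect_equal(d$d, 1)
  expect_equal(d$n_baba, 0)
  flip <- patterson_d(tab, "S2", "S1", "S3", "S4")
  expect_equal(flip$d, -1)
  expect_equal(abs(flip$z), abs(d$z))
})

test_that("D is exactly zero when p1 and p2 have identical frequencies", {
  set.seed(31)
  g1 <- matrix(sample(0:2, 40, TRUE), 20)
  g3 <- matrix(sample(0:2, 40, TRUE), 20)
  g4 <- matrix(0L, 20, 2)
  tab <- make_table(cbind(g1, g1, g3, g4), pos = seq_len(20) * 5e5,
                    ids = paste0("S", 1:8))
  d <- patterson_d(tab, c("S1", "S2"), c("S3", "S4"),
                   c("S5", "S6"), c("S7", "S8"), block_size = 5e6)
  expect_equal(d$d, 0)
})

test_that("population sets must be disjoint and blocks sufficient", {
  tab <- dstat_table(rep(0L, 4), rep(2L, 4), rep(2L, 4), rep(0L, 4))
  expect_error(patterson_d(tab, "S1", "S1", "S3", "S4"), "disjoint")
  one_block <- dstat_table(rep(0L, 2), rep(2L, 2), rep(2L, 2),
                           rep(0L, 2), pos = c(100, 200))
  expect_error(patterson_d(one_block, "S1", "S2", "S3", "S4"),
               "blocks")
})

test_that("sites with a polymorphic outgroup are dropped as unpolarizable", {
  # outgroup heterozygous (freq 0.5) at the middle site -> dropped
  tab <- dstat_table(c(0L, 0L, 0L), c(2L, 2L, 2L), c(2L, 2L, 2L),
                     c(0L, 1L, 0L), pos = c(1e6, 2e6, 7e6))
  d <- patterson_d(tab, "S1", "S2", "S3", "S4", block_size = 5e6)
  expect_equal(d$n_informative_sites, 2L)
  expect_equal(d$d, 1)
})

test_that("nIBD counts match the exhaustive segment-window enumeration", {
  w <- make_windows(c(chr1 = 1e6), size = 1e5, step = 5e4)
  seg <- data.frame(
    sample_a = c("T1", "T1", "R1", "T2", "X1"),
    hap_a = 1L,
    sample_b = c("R1", "R2", "R2", "R1", "R1"),
    hap_b = 2L,
    chrom = "chr1",
    start = c(1.5e5, 0, 4e5, 9.9e5, 2e5),
    end = c(3.6e5, 5e4, 8e5, 1e6, 9e5),
    lod = 5, stringsAsFactors = FALSE)
  got <- nibd_scan(seg, target = c("T1", "T2"),
                   ref_pop = c("R1", "R2"), w)
  want <- oracle_nibd_counts(seg, c("T1", "T2"), c("R1", "R2"), w)
  expect_equal(got$c_ibd, want)
  expect_equal(got$n_ibd, want / 2)
  # a single target-ref segment covering several windows counts once each
  seg1 <- seg[1, ]
  got1 <- nibd_scan(seg1, "T1", c("R1", "R2"), w)
  covered <- which(got1$c_ibd == 1)
  expect_equal(got1$start[covered[1]], 1e5)      # window [100k,200k)
  expect_equal(got1$start[covered[length(covered)]], 3.5e5)
  expect_true(all(got1$c_ibd[-covered] == 0))
  # ref-ref segments contribute nowhere
  got2 <- nibd_scan(seg[3, ], c("T1", "T2"), c("R1", "R2"), w)
  expect_true(all(got2$c_ibd == 0))
  expect_error(nibd_scan(seg, character(0), "R1", w), "non-empty")
})

test_that("random IBD fixtures agree with the double-loop oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 30
    st <- runif(n, 0, 9e5)
    seg <- data.frame(
      sample_a = sample(c("T1", "T2", "R1", "R2", "Z1"), n, TRUE),
      hap_a = sample(1:2, n, TRUE),
      sample_b = sample(c("T1", "T2", "R1", "R2", "Z1"), n, TRUE),
      hap_b = sample(1:2, n, TRUE),
      chrom = sample(c("chr1", "chr2"), n, TRUE),
      start = st, end = st + runif(n, 1e3, 4e5), lod = 3,
      stringsAsFactors = FALSE)
    w <- make_windows(c(chr1 = 1e6, chr2 = 8e5), 1e5, 5e4)
    got <- nibd_scan(seg, c("T1", "T2"), c("R1", "R2"), w)
    expect_equal(got$c_ibd,
                 oracle_nibd_counts(seg, c("T1", "T2"), c("R1", "R2"), w))
  }
})

test_that("rIBD z-scores are standardized and degenerate input errors", {
  co <- shared_cohort()
  onc <- pop_ids(co, "ONC"); oh <- pop_ids(co, "OH")
  onl <- pop_ids(co, "ONL")
  w <- make_windows(c(chr1 = co$config$seq_length), 1e5, 5e4)
  rw <- ribd_scan(co$truth$true_ibd, onc, oh, onl, w)
  expect_equal(mean(rw$z), 0, tolerance = 1e-9)
  expect_equal(sd(rw$z), 1, tolerance = 1e-9)
  expect_equal(rw$ribd, rw$n_ibd_oh - rw$n_ibd_onl)
  empty <- co$truth$true_ibd[0, ]
  expect_error(ribd_scan(empty, onc, oh, onl, w), "degenerate")
})

test_that("windows inside planted donor tracts score higher rIBD z", {
  co <- shared_cohort()
  onc <- pop_ids(co, "ONC")
  w <- make_windows(c(chr1 = co$config$seq_length), 1e5, 5e4)
  rw <- ribd_scan(co$truth$true_ibd, onc, pop_ids(co, "OH"),
                  pop_ids(co, "ONL"), w)
  tr <- co$truth$tracts
  tr <- tr[tr$sample_id %in% onc & tr$donor_pop == "OH", ]
  donor <- IRanges::reduce(IRanges::IRanges(tr$start + 1, tr$end))
  inside <- IRanges::overlapsAny(IRanges::IRanges(w$start + 1, w$end),
                                 donor)
  expect_gt(mean(rw$z[inside]), mean(rw$z[!inside]))
})

test_that("segment calling merges overlapping windows and is strict at z", {
  rw <- data.frame(chrom = "chr1",
                   start = c(0, 5e4, 2e5, 4e5),
                   end = c(1e5, 1.5e5, 3e5, 5e5),
                   z = c(3, 2.5, 2, 4))
  calls <- call_introgressed_segments(rw, z_threshold = 2,
                                      chrom_lengths = c(chr1 = 1e6))
  expect_equal(nrow(calls$segments), 2L)
  expect_equal(calls$segments$start, c(0, 4e5))
  expect_equal(calls$segments$end, c(1.5e5, 5e5))
  expect_equal(calls$total_bp, 2.5e5)          # union, not the sum of 3
  expect_equal(calls$genome_fraction, 0.25)
  expect_equal(calls$segments$peak_z, c(3, 4))
  # z exactly at the threshold is excluded; nothing selected -> empty
  none <- call_introgressed_segments(rw[3, ], 2)
  expect_equal(nrow(none$segments), 0L)
  expect_equal(none$total_bp, 0)
})

test_that("called length equals the union of selected windows on real scans", {
  co <- shared_cohort()
  w <- make_windows(c(chr1 = co$config$seq_length), 1e5, 5e4)
  rw <- ribd_scan(co$truth$true_ibd, pop_ids(co, "ONC"),
                  pop_ids(co, "OH"), pop_ids(co, "ONL"), w)
  calls <- call_introgressed_segments(
    rw, 2, chrom_lengths = c(chr1 = co$config$seq_length))
  sel <- rw[rw$z > 2, ]
  union_bp <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(sel$start + 1, sel$end))))
  expect_equal(calls$total_bp, union_bp)
})

test_that("gene overlap counting honors the 1-bp rule", {
  models <- list(
    structure(list(gene_id = "gA", chrom = "chr1", strand = "+",
                   cds = data.frame(start = 1e5, end = 1.2e5, phase = 0)),
              class = "gene_model"),
    structure(list(gene_id = "gB", chrom = "chr1", strand = "+",
                   cds = data.frame(start = 2e5 - 1, end = 2.1e5,
                                    phase = 0)),
              class = "gene_model"),
    structure(list(gene_id = "gC", chrom = "chr1", strand = "-",
                   cds = data.frame(start = 5e5, end = 6e5, phase = 0)),
              class = "gene_model"))
  segs <- data.frame(chrom = "chr1", start = c(0, 1.9e5),
                     end = c(1.5e5, 2e5))
  res <- genes_in_segments(segs, models)
  expect_equal(res$per_segment[[1]], "gA")     # wholly inside
  expect_equal(res$per_segment[[2]], "gB")     # 1-bp overlap counts
  expect_equal(res$n_unique_genes, 2L)
  # exhaustive check over random fixtures
  set.seed(12)
  for (rep in 1:5) {
    st <- sort(runif(2, 0, 8e5))
    segs2 <- data.frame(chrom = "chr1", start = st, end = st + 1e5)
    counts <- genes_in_segments(segs2, models)
    for (i in 1:2) {
      manual <- vapply(models, function(m) {
        sp <- gene_span(m)
        sp$start < segs2$end[i] && sp$end > segs2$start[i]
      }, logical(1))
      expect_setequal(counts$per_segment[[i]],
                      vapply(models[manual], `[[`, "", "gene_id"))
    }
  }
})

test_that("subgenome totals sum to the called total and form ratios", {
  segs <- data.frame(chrom = c("1A", "2C", "3C"),
                     start = c(0, 0, 1e5), end = c(1e5, 2e5, 3e5))
  mapping <- c(`1A` = "A", `2C` = "C", `3C` = "C", `4D` = "D")
  res <- subgenome_totals(segs, mapping)
  expect_equal(res$totals, c(A = 1e5, C = 4e5, D = 0))
  expect_equal(res$ratios["C", "A"], 4)
  expect_equal(sum(res$totals), sum(segs$end - segs$start))
  expect_error(subgenome_totals(
    data.frame(chrom = "9Z", start = 0, end = 1), mapping), "9Z")
})
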