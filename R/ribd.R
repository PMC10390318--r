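#' Windowed IBD-sharing counts against a reference population
#'
#' Counts, per sliding window, the IBD segments whose two haplotype
#' endpoints belong one to a `target` accession and one to a `ref_pop`
#' accession and whose interval overlaps the window by at least 1 bp;
#' the normalized count is `nIBD = count / |ref_pop|`.
#'
#' @param ibd an `ibd_segments` data.frame (see [read_ibd_segments()] or
#'   [derive_true_ibd()]).
#' @param target,ref_pop character vectors of sample ids (non-empty,
#'   disjoint).
#' @param windows a [genomic_intervals()] data.frame, conventionally
#'   100-kb windows at 50-kb step.
#' @return the windows data.frame with `c_ibd` (raw count) and `n_ibd`
#'   (normalized) columns.
#' @export
nibd_scan <- function(ibd, target, ref_pop, windows) {
  if (!length(target) || !length(ref_pop))
    stop("target and ref_pop must be non-empty")
  a_t <- ibd$sample_a %in% target; b_t <- ibd$sample_b %in% target
  a_r <- ibd$sample_a %in% ref_pop; b_r <- ibd$sample_b %in% ref_pop
  keep <- (a_t & b_r) | (a_r & b_t)
  out <- as.data.frame(windows)
  out$c_ibd <- 0L
  if (any(keep)) {
    seg <- ibd[keep, , drop = FALSE]
    gr_s <- GenomicRanges::GRanges(
      seg$chrom, IRanges::IRanges(start = seg$start + 1, end = seg$end))
    hits <- GenomicRanges::findOverlaps(gr_s, intervals_to_granges(windows))
    cnt <- table(S4Vectors::subjectHits(hits))
    out$c_ibd[as.integer(names(cnt))] <- as.integer(cnt)
  }
  out$n_ibd <- out$c_ibd / length(ref_pop)
  out
}

#' rIBD introgression scan
#'
#' Relative IBD sharing of a target group against two candidate donor
#' populations: per window, `rIBD = nIBD_OH - nIBD_ONL` (sharing with the
#' putative donor minus sharing with the recipient's own kin), then
#' z-standardized over all genome windows (windows with no IBD in either
#' term included).
#'
#' @param ibd an `ibd_segments` data.frame.
#' @param target sample ids of the admixture-candidate group (e.g. naked
#'   oat cultivars).
#' @param pop_oh sample ids of the putative donor population (e.g. hulled
#'   oat).
#' @param pop_onl sample ids of the reference kin population (e.g. naked
#'   oat landraces).
#' @param windows a [genomic_intervals()] data.frame.
#' @return the windows data.frame with columns `c_ibd_oh`, `c_ibd_onl`,
#'   `n_ibd_oh`, `n_ibd_onl`, `ribd` and `z`.
#' @export
ribd_scan <- function(ibd, target, pop_oh, pop_onl, windows) {
  oh <- nibd_scan(ibd, target, pop_oh, windows)
  onl <- nibd_scan(ibd, target, pop_onl, windows)
  out <- as.data.frame(windows)
  out$c_ibd_oh <- oh$c_ibd
  out$c_ibd_onl <- onl$c_ibd
  out$n_ibd_oh <- oh$n_ibd
  out$n_ibd_onl <- onl$n_ibd
  out$ribd <- out$n_ibd_oh - out$n_ibd_onl
  s <- stats::sd(out$ribd)
  if (is.na(s) || s == 0)
    stop("rIBD is constant across windows; degenerate input")
  out$z <- (out$ribd - mean(out$ribd)) / s
  out
}

#' Call introgressed segments from rIBD z-scores
#'
#' Selects windows with `z > z_threshold` (strict) and merges overlapping
#' or book-ended selected windows into maximal segments by interval union,
#' so the 50% window overlap is not double counted.
#'
#' @param ribd_windows output of [ribd_scan()].
#' @param z_threshold z cutoff (default 2, strict inequality).
#' @param chrom_lengths optional named vector; when given, the genome
#'   fraction uses `sum(chrom_lengths)`, otherwise the span covered by the
#'   window set.
#' @return a list with `segments` (data.frame `chrom`, `start`, `end`,
#'   `peak_z`, `n_windows`), `total_bp` and `genome_fraction`.
#' @export
call_introgressed_segments <- function(ribd_windows, z_threshold = 2,
                                       chrom_lengths = NULL) {
  genome_bp <- if (is.null(chrom_lengths)) {
    sum(vapply(split(ribd_windows$end, ribd_windows$chrom), max,
               numeric(1)))
  } else sum(chrom_lengths)
  sel <- ribd_windows[ribd_windows$z > z_threshold, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(list(segments = data.frame(chrom = character(),
                                      start = numeric(), end = numeric(),
                                      peak_z = numeric(),
                                      n_windows = integer()),
                total_bp = 0, genome_fraction = 0))
  gr <- intervals_to_granges(sel)
  merged <- IRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  peak <- vapply(split(sel$z[S4Vectors::queryHits(hits)],
                       S4Vectors::subjectHits(hits)), max, numeric(1))
  nw <- vapply(split(S4Vectors::queryHits(hits),
                     S4Vectors::subjectHits(hits)), length, integer(1))
  segments <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1,
    end = GenomicRanges::end(merged),
    peak_z = unname(peak), n_windows = unname(nw))
  total <- sum(segments$end - segments$start)
  list(segments = segments, total_bp = total,
       genome_fraction = total / genome_bp)
}

#' Genes overlapping introgressed segments
#'
#' A gene counts for a segment iff its full genomic span overlaps the
#' segment by at least 1 bp.
#'
#' @param segments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [call_introgressed_segments()].
#' @param gene_models list of `gene_model` objects (see
#'   [read_gene_models()]).
#' @return a list with `per_segment` (list of gene-id vectors, one per
#'   segment row) and `n_unique_genes`.
#' @export
genes_in_segments <- function(segments, gene_models) {
  spans <- do.call(rbind, lapply(gene_models, gene_span))
  ids <- vapply(gene_models, `[[`, character(1), "gene_id")
  if (nrow(segments) == 0L)
    return(list(per_segment = list(), n_unique_genes = 0L))
  unmatched <- setdiff(unique(spans$chrom), unique(segments$chrom))
  if (length(unmatched))
    warning("gene chromosome(s) absent from segments: ",
            paste(unmatched, collapse = ", "))
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(spans),
                                      intervals_to_granges(segments))
  per_segment <- lapply(seq_len(nrow(segments)), function(i)
    unname(ids[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]]))
  list(per_segment = per_segment,
       n_unique_genes = length(unique(unlist(per_segment))))
}

#' Per-subgenome totals of introgressed length
#'
#' @param segments data.frame with `chrom`, `start`, `end`.
#' @param chrom_to_subgenome named character vector mapping every segment
#'   chromosome to a subgenome label (e.g. `A`, `C`, `D`).
#' @return a list with `totals` (named numeric, bp per subgenome) and
#'   `ratios` (matrix of pairwise total ratios).
#' @export
subgenome_totals <- function(segments, chrom_to_subgenome) {
  unmapped <- setdiff(unique(segments$chrom), names(chrom_to_subgenome))
  if (length(unmapped))
    stop("unmapped chromosome(s): ", paste(unmapped, collapse = ", "))
  labels <- unique(unname(chrom_to_subgenome))
  len <- segments$end - segments$start
  sg <- chrom_to_subgenome[segments$chrom]
  totals <- vapply(labels, function(l) sum(len[sg == l]), numeric(1))
  ratios <- outer(totals, totals, function(a, b) ifelse(b > 0, a / b, NA))
  list(totals = totals, ratios = ratios)
}
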