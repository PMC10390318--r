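# 2-base codon prefixes whose third position is fourfold degenerate,
# derived from the standard genetic code at load time.
fourfold_prefixes <- local({
  gc <- Biostrings::GENETIC_CODE
  pre <- unique(substr(names(gc), 1, 2))
  keep <- vapply(pre, function(p) {
    aa <- gc[paste0(p, c("A", "C", "G", "T"))]
    length(unique(aa)) == 1L
  }, logical(1))
  pre[keep]
})

#' Fourfold-degenerate sites from gene models
#'
#' Walks every CDS in transcript orientation and emits the genomic
#' coordinate of each codon third position whose amino acid is determined
#' by the first two bases alone (the eight fourfold families CTN, GTN,
#' TCN, CCN, ACN, GCN, CGN, GGN of the standard code).  Codons with
#' ambiguity codes in the first two bases are skipped.  Genomic positions
#' covered by several transcripts are kept only if every covering
#' transcript classifies them as a fourfold third position (conflicting
#' degeneracy excludes the site); duplicates are collapsed.
#'
#' @param gene_models list of `gene_model` objects
#'   (see [read_gene_models()]).
#' @param genome a `Biostrings::DNAStringSet` (or the `genome` element of
#'   [read_gene_models()]).
#' @return a data.frame with one row per site: `chrom`, `pos` (0-based),
#'   `gene_id`, `codon` (transcript orientation), `strand`.
#' @export
fourfold_sites <- function(gene_models, genome) {
  per_tx <- lapply(gene_models, function(m) {
    if (!m$chrom %in% names(genome))
      stop("gene ", m$gene_id, " references contig absent from FASTA: ",
           m$chrom)
    minus <- identical(m$strand, "-")
    coords <- unlist(lapply(seq_len(nrow(m$cds)), function(i) {
      if (minus) seq(m$cds$end[i], m$cds$start[i] + 1L)
      else seq(m$cds$start[i] + 1L, m$cds$end[i])
    }))
    chrseq <- genome[[m$chrom]]
    span <- as.character(Biostrings::subseq(chrseq, min(coords),
                                            max(coords)))
    bases <- strsplit(span, "")[[1L]]
    tx <- bases[coords - min(coords) + 1L]
    if (minus) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")[tx]
      comp[is.na(comp)] <- "N"
      tx <- comp
    }
    phase <- m$cds$phase[1L]
    if (phase > 0L) {
      tx <- tx[-seq_len(phase)]
      coords <- coords[-seq_len(phase)]
    }
    nc <- 3L * (length(tx) %/% 3L)
    if (nc == 0L) return(NULL)
    tx <- tx[seq_len(nc)]; coords <- coords[seq_len(nc)]
    codon_of <- rep(seq_len(nc %/% 3L), each = 3L)
    third <- seq(3L, nc, by = 3L)
    codon <- paste0(tx[third - 2L], tx[third - 1L], tx[third])
    clean <- !grepl("[^ACGT]", substr(codon, 1L, 2L))
    is_ff_codon <- clean & substr(codon, 1L, 2L) %in% fourfold_prefixes
    # classify every CDS base so conflicts with non-third positions of
    # other transcripts are detectable
    flag <- rep(FALSE, nc)
    flag[third] <- is_ff_codon
    data.frame(chrom = m$chrom, pos = coords - 1L,   # 0-based
               gene_id = m$gene_id, strand = m$strand,
               codon = codon[codon_of],
               fourfold = flag,
               stringsAsFactors = FALSE)
  })
  allb <- do.call(rbind, per_tx)
  empty <- data.frame(chrom = character(), pos = integer(),
                      gene_id = character(), codon = character(),
                      strand = character())
  if (is.null(allb) || nrow(allb) == 0L) return(empty)
  key <- paste(allb$chrom, allb$pos)
  agree <- tapply(allb$fourfold, key, all)
  ok_key <- names(agree)[agree]
  out <- allb[allb$fourfold & key %in% ok_key, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
  out <- out[order(match(out$chrom, unique(out$chrom)), out$pos), ]
  rownames(out) <- NULL
  out[, c("chrom", "pos", "gene_id", "codon", "strand")]
}
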