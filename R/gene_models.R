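#' Read gene models from GFF3 plus genome FASTA
#'
#' Builds one strand-aware CDS model per mRNA from a GFF3 annotation, with
#' the genome loaded as a `Biostrings::DNAStringSet` for sequence access.
#' CDS parts are ordered 5'->3' in transcript orientation (descending
#' genomic coordinate on the minus strand) and carry their GFF phase.
#' Models whose phase-adjusted CDS length is not a multiple of 3 are
#' flagged malformed and excluded with a warning.
#'
#' @param gff_path GFF3 file with gene/mRNA/CDS features.
#' @param fasta_path genome FASTA whose names match the GFF seqids.
#' @return a list with `models` (list of `gene_model` objects, each with
#'   `gene_id`, `chrom`, `strand`, `cds` data.frame of `start` (0-based),
#'   `end`, `phase`), `genome` (a `DNAStringSet`), and `n_malformed`.
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  gff <- rtracklayer::import(gff_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  cds <- gff[gff$type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features in ", gff_path)
  missing_contig <- setdiff(unique(as.character(GenomicRanges::seqnames(cds))),
                            names(genome))
  if (length(missing_contig))
    stop("CDS references contig(s) absent from FASTA: ",
         paste(missing_contig, collapse = ", "))
  parent <- as.character(sapply(cds$Parent, `[`, 1L))
  models <- list()
  n_bad <- 0L
  for (tx in unique(parent)) {
    part <- cds[parent == tx]
    strand <- as.character(BiocGenerics::strand(part))[1L]
    ord <- order(GenomicRanges::start(part),
                 decreasing = identical(strand, "-"))
    part <- part[ord]
    phase <- as.integer(part$phase)
    phase[is.na(phase)] <- 0L
    d <- data.frame(start = GenomicRanges::start(part) - 1L,
                    end = GenomicRanges::end(part),
                    phase = phase)
    len <- sum(d$end - d$start) - d$phase[1L]
    if (len %% 3L != 0L) {
      n_bad <- n_bad + 1L
      next
    }
    models[[tx]] <- structure(list(
      gene_id = tx,
      chrom = as.character(GenomicRanges::seqnames(part))[1L],
      strand = strand,
      cds = d
    ), class = "gene_model")
  }
  if (n_bad > 0L)
    warning(n_bad, " malformed gene model(s) excluded ",
            "(CDS length not a multiple of 3)")
  list(models = models, genome = genome, n_malformed = n_bad)
}

#' Genomic span of a gene model
#'
#' @param model a `gene_model`.
#' @param upstream bases of strand-aware upstream flank to include.
#' @return a [genomic_intervals()] row covering the CDS span plus flank.
#' @export
gene_span <- function(model, upstream = 0) {
  lo <- min(model$cds$start)
  hi <- max(model$cds$end)
  if (identical(model$strand, "-")) hi <- hi + upstream
  else lo <- max(0, lo - upstream)
  genomic_intervals(model$chrom, lo, hi)
}
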