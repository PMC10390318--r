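#' Read biallelic SNPs from a VCF file
#'
#' Parses a VCF 4.x file through [vcfR::read.vcfR()] and returns a
#' [variant_table()] restricted to biallelic SNPs.  Multiallelic records and
#' indels are excluded with a message reporting the count.  Diploid GT
#' fields are decoded to alternate-allele dosages (0/1/2, `NA` for `./.`);
#' fully phased records additionally populate the haplotype matrix.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param sample_subset optional character vector of sample ids to keep.
#' @return a [variant_table()].  If the file holds no biallelic SNP a
#'   zero-site table is returned with a warning.
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (n_drop > 0)
    message(n_drop, " multiallelic/indel record(s) excluded")
  if (!any(snp)) {
    warning("no biallelic SNPs in ", path)
    return(variant_table(character(), integer(), character(), character(),
                         matrix(integer(), 0, 0), character()))
  }

  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  samples <- colnames(gt)
  if (!is.null(sample_subset)) {
    miss <- setdiff(sample_subset, samples)
    if (length(miss))
      stop("samples absent from VCF: ", paste(miss, collapse = ", "))
    gt <- gt[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }

  allele <- function(s) ifelse(s %in% c("0", "1"), as.integer(s), NA_integer_)
  a1 <- allele(substr(gt, 1L, 1L))
  sep <- substr(gt, 2L, 2L)
  a2 <- allele(substr(gt, 3L, 3L))
  geno <- matrix(a1 + a2, nrow = nrow(gt), dimnames = dimnames(gt))

  hap <- NULL
  if (all(sep == "|", na.rm = TRUE) && any(sep == "|", na.rm = TRUE)) {
    hap <- matrix(NA_integer_, nrow(gt), 2L * length(samples))
    hap[, seq(1L, ncol(hap), 2L)] <- a1
    hap[, seq(2L, ncol(hap), 2L)] <- a2
  }

  gq <- NULL
  if ("GQ" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
    gq <- gq[snp, , drop = FALSE]
    if (!is.null(sample_subset)) gq <- gq[, sample_subset, drop = FALSE]
  }

  info_num <- function(tag) {
    x <- vcfR::extract.info(v, element = tag, as.numeric = TRUE)
    if (is.null(x)) rep(NA_real_, sum(snp)) else x[snp]
  }
  qual <- suppressWarnings(as.numeric(fix[snp, "QUAL"]))

  variant_table(chrom = fix[snp, "CHROM"],
                pos = as.integer(fix[snp, "POS"]),
                ref = ref[snp], alt = alt[snp],
                geno = geno, sample_ids = samples,
                qual = qual, fs = info_num("FS"), mq = info_num("MQ"),
                gq = gq, hap = hap)
}

#' Write a variant table as VCF
#'
#' Emits a minimal, valid VCF 4.2 text file carrying QUAL, INFO/FS, INFO/MQ,
#' and per-sample GT (phased `0|1` style when haplotypes are present,
#' `0/1` otherwise) plus GQ when available.  Round-trips through
#' [read_vcf()].
#'
#' @param tab a [variant_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", tab$sample_ids), collapse = "\t")), con)
  n <- n_sites(tab)
  if (n == 0L) return(invisible(path))
  num <- function(x) ifelse(is.na(x), ".", formatC(x, format = "g", digits = 6))
  info <- paste0("FS=", num(tab$fs), ";MQ=", num(tab$mq))
  has_gq <- !is.null(tab$gq)
  fmt <- if (has_gq) "GT:GQ" else "GT"
  if (!is.null(tab$hap)) {
    h1 <- tab$hap[, seq(1L, ncol(tab$hap), 2L), drop = FALSE]
    h2 <- tab$hap[, seq(2L, ncol(tab$hap), 2L), drop = FALSE]
    gts <- matrix(paste0(h1, "|", h2), n)
    gts[is.na(h1) | is.na(h2)] <- ".|."
    gts[is.na(tab$geno)] <- ".|."
  } else {
    gtcode <- c("0/0", "0/1", "1/1")
    gts <- matrix(gtcode[tab$geno + 1L], n)
    gts[is.na(tab$geno)] <- "./."
  }
  if (has_gq) {
    gqs <- matrix(ifelse(is.na(tab$gq), ".", as.character(tab$gq)), n)
    gts <- matrix(paste0(gts, ":", gqs), n)
  }
  lines <- paste(tab$chrom, tab$pos, ".", tab$ref, tab$alt, num(tab$qual),
                 "PASS", info, fmt, sep = "\t")
  lines <- paste(lines, apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
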