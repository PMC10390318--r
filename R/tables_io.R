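#' Read pairwise IBD segments
#'
#' Reads identity-by-descent segments from a RefinedIBD-style 8-column TSV:
#' `sample_a, hap_a, sample_b, hap_b, chrom, start, end, lod`, with 1-based
#' inclusive coordinates in the file; internally segments use the package's
#' 0-based half-open convention.  Malformed lines (wrong column count,
#' non-numeric coordinates, `end < start`, identical haplotype endpoints)
#' are skipped with a warning giving the count.
#'
#' @param path TSV file path.
#' @param columns integer vector of length 8 mapping the expected fields to
#'   file columns, for other dialects; default `1:8`.
#' @return a data.frame of class `ibd_segments` with columns `sample_a`,
#'   `hap_a`, `sample_b`, `hap_b`, `chrom`, `start` (0-based), `end`
#'   (exclusive), `lod`.
#' @export
read_ibd_segments <- function(path, columns = 1:8) {
  if (!file.exists(path)) stop("IBD file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE,
                           colClasses = "character")
  if (nrow(raw) == 0L) stop("no parseable IBD lines in ", path)
  if (max(columns) > ncol(raw))
    stop("file has fewer columns than the mapping requires")
  d <- raw[, columns, drop = FALSE]
  names(d) <- c("sample_a", "hap_a", "sample_b", "hap_b",
                "chrom", "start", "end", "lod")
  num <- function(x) suppressWarnings(as.numeric(x))
  d$hap_a <- num(d$hap_a); d$hap_b <- num(d$hap_b)
  d$start <- num(d$start); d$end <- num(d$end); d$lod <- num(d$lod)
  ok <- !is.na(d$start) & !is.na(d$end) & d$end >= d$start &
    d$hap_a %in% c(1, 2) & d$hap_b %in% c(1, 2) &
    !(d$sample_a == d$sample_b & d$hap_a == d$hap_b)
  if (any(!ok))
    warning(sum(!ok), " malformed IBD line(s) skipped")
  d <- d[ok, , drop = FALSE]
  if (nrow(d) == 0L) stop("no valid IBD segments in ", path)
  d$start <- d$start - 1            # 1-based inclusive -> 0-based half-open
  d$hap_a <- as.integer(d$hap_a); d$hap_b <- as.integer(d$hap_b)
  rownames(d) <- NULL
  class(d) <- c("ibd_segments", "data.frame")
  d
}

#' @rdname read_ibd_segments
#' @param segments an `ibd_segments` data.frame (internal coordinates).
#' @export
write_ibd_segments <- function(segments, path) {
  out <- segments
  out$start <- format(out$start + 1, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write intervals (optionally with values) as BED
#'
#' Emits 0-based half-open BED, ordered by chromosome then start; any
#' columns beyond `chrom`/`start`/`end` are appended as value columns.
#' No header is written.
#'
#' @param intervals a data.frame with `chrom`, `start`, `end` and optional
#'   value columns (e.g. windowed statistics).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  d <- as.data.frame(intervals)
  if (nrow(d) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  d <- d[order(match(d$chrom, unique(d$chrom)), d$start), , drop = FALSE]
  d$start <- format(d$start, scientific = FALSE, trim = TRUE)
  d$end <- format(d$end, scientific = FALSE, trim = TRUE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED file (no header).
#' @return a [genomic_intervals()] data.frame; extra columns preserved.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  out <- genomic_intervals(d[[1]], d[[2]], d[[3]])
  if (ncol(d) > 3) out <- cbind(out, d[, -(1:3), drop = FALSE])
  out
}

#' Read a sample sheet mapping accessions to populations
#'
#' @param path TSV with columns `sample_id` and `population` (header
#'   optional; detected).
#' @return a named character vector, population keyed by sample id.
#' @export
read_sample_sheet <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  if (identical(tolower(d[1, 1]), "sample_id")) d <- d[-1, , drop = FALSE]
  if (any(duplicated(d[[1]])))
    stop("duplicated sample ids in sample sheet")
  if (any(!nzchar(d[[2]]))) stop("empty population labels in sample sheet")
  stats::setNames(d[[2]], d[[1]])
}

#' Read a phenotype table
#'
#' @param path TSV with columns `sample_id`, `trait`, `value`.
#' @return a data.frame with those columns, `value` numeric.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  names(d)[1:3] <- c("sample_id", "trait", "value")
  d$value <- as.numeric(d$value)
  d
}
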