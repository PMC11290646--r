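#' Readers and writers for the standard genomic text formats
#'
#' Thin, validating wrappers around rtracklayer / Biostrings importers.
#' BED and bedGraph are 0-based half-open on disk; GFF3 is 1-based
#' inclusive; all are converted to `GRanges` (1-based closed) on read, so a
#' BED line `chrI 100 124 . 0 +` and a GFF feature `101..124` describe the
#' same interval. `write_bed()` followed by `read_bed()` is the identity for
#' canonical records.
#'
#' @param path file path.
#' @param genome optional [genome_build()]; when given, intervals are
#'   validated against it and carry its seqinfo.
#' @param mapq_from_score if `TRUE`, copy the BED score column into a
#'   `mapq` metadata column (XR-seq convention used by this package).
#'
#' @return `read_bed()`, `read_bedgraph()`, `read_gff_subset()` return
#'   [GenomicRanges::GRanges]; `read_chrom_sizes()` returns a named integer
#'   vector; `read_fasta()` returns a [Biostrings::DNAStringSet].
#' @name genomic-io
NULL

#' @rdname genomic-io
#' @export
read_bed <- function(path, genome = NULL, mapq_from_score = FALSE) {
  gr <- rtracklayer::import(path, format = "BED")
  if (mapq_from_score && !is.null(S4Vectors::mcols(gr)$score))
    S4Vectors::mcols(gr)$mapq <- as.integer(S4Vectors::mcols(gr)$score)
  attach_build(gr, genome)
}

#' @rdname genomic-io
#' @param x intervals to write.
#' @export
write_bed <- function(x, path) {
  x <- as_reads_granges(x)
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}

#' @rdname genomic-io
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (nrow(df) == 0L) stop("empty chrom.sizes file: ", path)
  structure(as.integer(df$length), names = df$chrom)
}

#' @rdname genomic-io
#' @export
read_bedgraph <- function(path, genome = NULL) {
  attach_build(rtracklayer::import(path, format = "bedGraph"), genome)
}

#' @rdname genomic-io
#' @param types GFF3 feature types to keep (e.g. `c("gene", "ncRNA")`);
#'   `NULL` keeps everything.
#' @export
read_gff_subset <- function(path, types = NULL, genome = NULL) {
  gr <- rtracklayer::import(path, format = "GFF3")
  if (!is.null(types))
    gr <- gr[as.character(S4Vectors::mcols(gr)$type) %in% types]
  attach_build(gr, genome)
}

#' @rdname genomic-io
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname genomic-io
#' @param seq a [Biostrings::DNAStringSet].
#' @export
write_fasta <- function(seq, path) {
  Biostrings::writeXStringSet(seq, path)
  invisible(path)
}

attach_build <- function(gr, genome) {
  if (is.null(genome)) return(gr)
  stopifnot(inherits(genome, "GenomeBuild"))
  bad <- !(as.character(GenomicRanges::seqnames(gr)) %in%
             names(genome$chrom_lengths))
  if (any(bad))
    stop("unknown chromosome(s) for build '", genome$name, "': ",
         paste(unique(as.character(GenomicRanges::seqnames(gr))[bad]),
               collapse = ", "))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome$seqinfo)
  GenomeInfoDb::seqinfo(gr) <- genome$seqinfo
  gr
}
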