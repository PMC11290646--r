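#' Genome build: named chromosomes with lengths
#'
#' A `GenomeBuild` is the coordinate authority for every interval in the
#' package: a named, ordered set of chromosome lengths (optionally backed by
#' sequence held separately as a [Biostrings::DNAStringSet]). All intervals
#' are BED-style 0-based half-open externally; internally they are stored as
#' [GenomicRanges::GRanges] (1-based closed), with conversion confined to the
#' format readers/writers.
#'
#' @param name single string identifying the build (e.g. `"ce11"`, `"sim1"`).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   names are chromosome names, order is preserved.
#'
#' @return An object of class `"GenomeBuild"`: a list with elements `name`,
#'   `chrom_lengths` (named integer) and `seqinfo`
#'   ([GenomeInfoDb::Seqinfo]).
#'
#' @examples
#' gb <- genome_build("toy", c(chrI = 10000, chrII = 5000))
#' chrom_lengths(gb)
#' @export
genome_build <- function(name, chrom_lengths) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(chrom_lengths) == 0L)
    stop("empty genome: no chromosomes given")
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chromosome names must be present and unique")
  if (any(chrom_lengths <= 0) || any(!is.finite(chrom_lengths)))
    stop("chromosome lengths must be positive and finite")
  lens <- structure(as.integer(round(chrom_lengths)), names = names(chrom_lengths))
  structure(
    list(
      name = name,
      chrom_lengths = lens,
      seqinfo = GenomeInfoDb::Seqinfo(
        seqnames = names(lens), seqlengths = lens, genome = name
      )
    ),
    class = "GenomeBuild"
  )
}

#' @rdname genome_build
#' @param x a `GenomeBuild`.
#' @export
chrom_lengths <- function(x) {
  stopifnot(inherits(x, "GenomeBuild"))
  x$chrom_lengths
}

#' @export
print.GenomeBuild <- function(x, ...) {
  cat(sprintf("GenomeBuild '%s': %d chromosome(s), %s bp total\n",
              x$name, length(x$chrom_lengths),
              format(sum(as.numeric(x$chrom_lengths)), big.mark = ",")))
  print(x$chrom_lengths)
  invisible(x)
}

#' Tile a genome into consecutive non-overlapping fixed-width bins
#'
#' Partitions every chromosome into consecutive, non-overlapping bins of
#' `width` bp. The terminal bin of each chromosome is retained even when
#' shorter than `width`, so a chromosome of length L yields `ceiling(L /
#' width)` bins and the bins cover the chromosome exactly once.
#'
#' @param genome a [genome_build()].
#' @param width bin width in bp (>= 1).
#'
#' @return Unstranded [GenomicRanges::GRanges] of bins, ordered by chromosome
#'   then coordinate, with the build's seqinfo attached.
#'
#' @examples
#' gb <- genome_build("toy", c(chr1 = 1000))
#' length(tile_genome(gb, 200))  # 5
#' @export
tile_genome <- function(genome, width) {
  stopifnot(inherits(genome, "GenomeBuild"))
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("width must be >= 1")
  bins <- GenomicRanges::tileGenome(
    genome$seqinfo, tilewidth = width, cut.last.tile.in.chrom = TRUE
  )
  S4Vectors::metadata(bins) <- list(bin_width = width, genome = genome$name)
  bins
}

#' Construct a GRanges validated against a genome build
#'
#' Convenience constructor used throughout the package: takes 0-based
#' half-open coordinates (BED convention) and returns a 1-based
#' [GenomicRanges::GRanges] carrying the build's seqinfo. Out-of-bounds
#' coordinates or unknown chromosomes are errors.
#'
#' @param chrom chromosome names.
#' @param start 0-based inclusive starts.
#' @param end exclusive ends.
#' @param strand `"+"`, `"-"` or `"*"` (recycled).
#' @param genome a [genome_build()], or `NULL` to skip validation.
#' @param ... further vectors stored as metadata columns.
#'
#' @return A [GenomicRanges::GRanges].
#' @export
stranded_intervals <- function(chrom, start, end, strand = "*", genome = NULL, ...) {
  if (any(start < 0) || any(end <= start))
    stop("need 0 <= start < end for every interval")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand,
    ...
  )
  if (!is.null(genome)) {
    stopifnot(inherits(genome, "GenomeBuild"))
    bad <- !(as.character(GenomicRanges::seqnames(gr)) %in%
               names(genome$chrom_lengths))
    if (any(bad))
      stop("unknown chromosome(s): ",
           paste(unique(as.character(GenomicRanges::seqnames(gr))[bad]),
                 collapse = ", "))
    if (any(GenomicRanges::end(gr) >
              genome$chrom_lengths[as.character(GenomicRanges::seqnames(gr))]))
      stop("interval end beyond chromosome length")
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome$seqinfo)
    GenomeInfoDb::seqinfo(gr) <- genome$seqinfo
  }
  gr
}
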