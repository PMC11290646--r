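#' A set of mapped reads from one sequencing sample
#'
#' Thin container coupling a [GenomicRanges::GRanges] of mapped-read
#' intervals with sample metadata (genotype, assay, timepoint, replicate).
#' The library size used for normalisation is the number of reads held.
#' Optional per-read mapping quality lives in `mcols(reads)$mapq`.
#'
#' @param reads [GenomicRanges::GRanges] of read intervals (stranded for
#'   XR-seq / capped RNA-seq).
#' @param sample_id single string.
#' @param genotype `"WT"`, `"csb-1"` or `"xpc-1"` (free-form allowed for
#'   non-XR assays).
#' @param assay one of `"XR"`, `"RNA"`, `"shortcap"`, `"longcap"`.
#' @param timepoint label such as `"1h"`, or `NA` for untimed assays.
#' @param replicate integer replicate index.
#'
#' @return An object of class `"ReadSet"`.
#' @export
read_set <- function(reads, sample_id, genotype = NA_character_,
                     assay = c("XR", "RNA", "shortcap", "longcap"),
                     timepoint = NA_character_, replicate = 1L) {
  assay <- match.arg(assay)
  stopifnot(methods::is(reads, "GRanges"))
  structure(
    list(
      reads = reads,
      sample_id = as.character(sample_id),
      genotype = as.character(genotype),
      assay = assay,
      timepoint = as.character(timepoint),
      replicate = as.integer(replicate)
    ),
    class = "ReadSet"
  )
}

#' @rdname read_set
#' @param x a `ReadSet` (or GRanges, passed through).
#' @export
library_size <- function(x) length(as_reads_granges(x))

# Accept either a ReadSet or a bare GRanges wherever reads are consumed.
as_reads_granges <- function(x) {
  if (inherits(x, "ReadSet")) x$reads
  else if (methods::is(x, "GRanges")) x
  else stop("expected a ReadSet or GRanges of reads")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet '%s': %s %s%s rep%d, %s reads\n",
              x$sample_id, x$genotype, x$assay,
              if (is.na(x$timepoint)) "" else paste0(" @", x$timepoint),
              x$replicate, format(length(x$reads), big.mark = ",")))
  invisible(x)
}

#' @export
length.ReadSet <- function(x) length(x$reads)

# Replace the reads of a ReadSet, keeping metadata.
replace_reads <- function(rs, reads) {
  if (inherits(rs, "ReadSet")) { rs$reads <- reads; rs } else reads
}

#' Canonical XR-seq timepoint labels
#'
#' The ordered post-UV collection times used throughout the time-course
#' analyses.
#' @return Character vector `c("5min","1h","8h","16h","24h","48h")`.
#' @export
xr_timepoints <- function() c("5min", "1h", "8h", "16h", "24h", "48h")
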