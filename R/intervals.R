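#' Count reads per feature with bedtools-style overlap and strand semantics
#'
#' Reproduces `bedtools intersect -c -wa [-F frac] [-s|-S]` with features as
#' the A file and reads as the B file: a read contributes to a feature iff
#' the overlap covers at least `min_read_overlap_frac` of the *read* length
#' (ties at the threshold count) and the strand rule holds. A read may count
#' toward several features; there is no unique assignment.
#'
#' The strand rules are stated relative to the feature strand:
#' `"same"` requires read strand == feature strand (non-transcribed strand
#' counting for genes annotated on their coding strand, bedtools `-s`),
#' `"opposite"` requires the complementary strand (transcribed-strand /
#' template counting, bedtools `-S`), and `"ignore"` disregards strand.
#' Unstranded (`*`) reads or features never satisfy `"same"`/`"opposite"`.
#'
#' @param features [GenomicRanges::GRanges] of features (A file).
#' @param reads [GenomicRanges::GRanges] of reads, or a [read_set()].
#' @param min_read_overlap_frac minimum overlap as a fraction of read length,
#'   in (0, 1]. Default 0.5 (`-F 0.5`).
#' @param strand_rule `"same"`, `"opposite"` or `"ignore"`.
#'
#' @return Integer vector of counts, one per feature.
#'
#' @examples
#' f <- stranded_intervals("chr1", 0, 1000, "+")
#' r <- stranded_intervals("chr1", c(100, 300), c(124, 324), c("+", "-"))
#' intersect_count(f, r, 0.5, "same")      # 1
#' intersect_count(f, r, 0.5, "opposite")  # 1
#' @export
intersect_count <- function(features, reads, min_read_overlap_frac = 0.5,
                            strand_rule = c("same", "opposite", "ignore")) {
  strand_rule <- match.arg(strand_rule)
  reads <- as_reads_granges(reads)
  if (min_read_overlap_frac <= 0 || min_read_overlap_frac > 1)
    stop("min_read_overlap_frac must be in (0, 1]")
  known <- as.character(GenomicRanges::seqnames(reads)) %in%
    GenomeInfoDb::seqlevels(features)
  if (!all(known)) {
    warning(sum(!known), " read(s) on chromosomes absent from the feature set",
            " contribute no counts")
    reads <- reads[known]
  }
  hits <- GenomicRanges::findOverlaps(features, reads, ignore.strand = TRUE)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(features)[q], GenomicRanges::ranges(reads)[s]
    ))
    keep <- ov / IRanges::width(reads)[s] >= min_read_overlap_frac
    if (strand_rule != "ignore") {
      fs <- as.character(GenomicRanges::strand(features))[q]
      rs <- as.character(GenomicRanges::strand(reads))[s]
      stranded <- fs != "*" & rs != "*"
      keep <- keep & stranded &
        (if (strand_rule == "same") fs == rs else fs != rs)
    }
    q <- q[keep]
  } else {
    q <- integer(0)
  }
  tabulate(q, nbins = length(features))
}

#' Interval algebra: subtract, merge, upstream extension
#'
#' `subtract_overlapping()` drops every interval of `a` that overlaps any
#' interval of `b` by at least one bp (strand-blind), the operation used to
#' remove genic/blacklisted bins. `merge_intervals()` collapses overlapping
#' or bookended intervals into their union (strand-blind, sorted).
#' `extend_upstream()` grows each feature at its 5' side by `d` bp in the
#' feature's transcription orientation (leftward for `+`, rightward for `-`),
#' clipped at the chromosome bounds; unstranded features are extended
#' leftward.
#'
#' @param a,b,features [GenomicRanges::GRanges].
#' @param d upstream extension in bp.
#'
#' @return A [GenomicRanges::GRanges].
#' @name interval-algebra
NULL

#' @rdname interval-algebra
#' @export
subtract_overlapping <- function(a, b) {
  a[!IRanges::overlapsAny(a, b, ignore.strand = TRUE)]
}

#' @rdname interval-algebra
#' @export
merge_intervals <- function(a) {
  GenomicRanges::reduce(GenomicRanges::sort(a, ignore.strand = TRUE),
                        ignore.strand = TRUE)
}

#' @rdname interval-algebra
#' @export
extend_upstream <- function(features, d) {
  stopifnot(d >= 0)
  minus <- as.character(GenomicRanges::strand(features)) == "-"
  new_start <- ifelse(minus, GenomicRanges::start(features),
                      pmax(1L, GenomicRanges::start(features) - as.integer(d)))
  new_end <- ifelse(minus, GenomicRanges::end(features) + as.integer(d),
                    GenomicRanges::end(features))
  out <- features
  IRanges::ranges(out) <- IRanges::IRanges(start = new_start, end = new_end)
  GenomicRanges::trim(out)
}
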