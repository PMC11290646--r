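#' Intergenic bin universe
#'
#' Starting from a genome-wide [tile_genome()] grid, removes every bin that
#' overlaps — by one bp or more — any gene body, the strand-aware upstream
#' extension of a gene (`upstream` bp 5' of the TSS, the promoter zone), or
#' any blacklist interval. What remains is the intergenic bin universe on
#' which transcription calls are made.
#'
#' @param bins unstranded `GRanges` from [tile_genome()].
#' @param genes stranded gene `GRanges`.
#' @param upstream promoter extension in bp (default 2000).
#' @param blacklist optional `GRanges` of excluded regions.
#' @return The retained subset of `bins`.
#' @export
intergenic_bins <- function(bins, genes, upstream = 2000, blacklist = NULL) {
  excl <- extend_upstream(genes, upstream)
  if (!is.null(blacklist) && length(blacklist))
    excl <- c(GenomicRanges::granges(excl), GenomicRanges::granges(blacklist))
  subtract_overlapping(bins, excl)
}

#' Library-size adjustment of counts
#'
#' `adjusted = count / (library_size / 1e6)` — reads per million. Doubling
#' all counts together with the library size leaves the value unchanged.
#'
#' @param count raw count(s).
#' @param library_size total reads in the sample (> 0).
#' @return Adjusted numeric value(s).
#' @export
adjust_library_size <- function(count, library_size) {
  stopifnot(all(library_size > 0))
  count / (library_size / 1e6)
}

#' Combine a time course into one value per bin
#'
#' The median of the per-timepoint adjusted counts, the rule used to report
#' time-series XR-seq in a combined fashion (one value per replicate).
#'
#' @param x matrix (bins x timepoints) or data.frame of adjusted counts.
#' @return Numeric vector of per-bin medians.
#' @export
combine_timepoints <- function(x) {
  x <- as.matrix(x)
  apply(x, 1L, stats::median)
}

#' Strand-blind read counts per bin
#'
#' Bin-level counting for the intergenic analysis: a read contributes to a
#' bin when it overlaps it by at least one bp, regardless of strand (bins
#' are unstranded; assay strandedness is collapsed).
#'
#' @param bins `GRanges` of bins.
#' @param reads a [read_set()] or `GRanges`.
#' @return Integer vector of counts per bin.
#' @export
bin_counts <- function(bins, reads) {
  GenomicRanges::countOverlaps(bins, as_reads_granges(reads),
                               ignore.strand = TRUE)
}

#' Detection calls per bin for the three assay classes
#'
#' Applies the call-reduction rules: the XR call requires a non-zero
#' (timepoint-combined) value in *both* replicates; the RNA call requires
#' non-zero counts in *both* the WT and xpc-1 RNA-seq libraries (they are
#' highly correlated); the capped call requires a non-zero count in
#' *either* short- or long-capped RNA-seq (they are complementary).
#'
#' @param xr_rep1,xr_rep2 per-bin combined adjusted XR values, one per
#'   replicate.
#' @param rna_wt,rna_xpc per-bin RNA-seq counts for the two strains.
#' @param shortcap,longcap per-bin capped RNA-seq counts.
#' @return `data.frame` with logical columns `xr`, `rna`, `capped`.
#' @export
call_detected <- function(xr_rep1, xr_rep2, rna_wt, rna_xpc,
                          shortcap, longcap) {
  args <- list(xr_rep1 = xr_rep1, xr_rep2 = xr_rep2, rna_wt = rna_wt,
               rna_xpc = rna_xpc, shortcap = shortcap, longcap = longcap)
  missing <- names(args)[vapply(args, is.null, logical(1))]
  if (length(missing))
    stop("missing assay input(s): ", paste(missing, collapse = ", "))
  n <- unique(vapply(args, length, integer(1)))
  if (length(n) != 1L) stop("assay vectors differ in length")
  data.frame(
    xr = xr_rep1 > 0 & xr_rep2 > 0,
    rna = rna_wt > 0 & rna_xpc > 0,
    capped = shortcap > 0 | longcap > 0
  )
}

#' Three-set Venn partition of detection calls
#'
#' @param calls `data.frame` of logical call columns (e.g. from
#'   [call_detected()]); exactly three columns.
#' @return Named integer vector of the 7 disjoint region sizes
#'   (`"xr_only"`, ..., `"xr_rna_capped"`) plus attribute `union`.
#' @export
venn_partition <- function(calls) {
  stopifnot(ncol(calls) == 3L)
  a <- calls[[1]]; b <- calls[[2]]; c <- calls[[3]]
  nm <- colnames(calls)
  out <- c(
    sum(a & !b & !c), sum(!a & b & !c), sum(!a & !b & c),
    sum(a & b & !c), sum(a & !b & c), sum(!a & b & c),
    sum(a & b & c)
  )
  names(out) <- c(paste0(nm[1], "_only"), paste0(nm[2], "_only"),
                  paste0(nm[3], "_only"),
                  paste(nm[1], nm[2], sep = "_"),
                  paste(nm[1], nm[3], sep = "_"),
                  paste(nm[2], nm[3], sep = "_"),
                  paste(nm[1], nm[2], nm[3], sep = "_"))
  attr(out, "union") <- sum(a | b | c)
  out
}

#' Classify XR-unique bins by overlapping annotation
#'
#' A bin is `annotated` iff it overlaps (>= 1 bp) any annotation record;
#' when several classes overlap one bin, a fixed priority order decides:
#' piRNA > pseudogene > protein_coding > eRNA > lincRNA > ncRNA > other.
#' Unannotated bins are labelled `"unannotated"`.
#'
#' @param bins `GRanges` of the XR-unique bins.
#' @param annotations `GRanges` with a `class` metadata column.
#' @return List with `bins` (input plus `annotated` and `class` columns),
#'   `fractions` (named proportions over all classes plus unannotated;
#'   sums to 1), `by_chromosome` (table of bins per chromosome).
#' @export
classify_unique_bins <- function(bins, annotations) {
  priority <- c("piRNA", "pseudogene", "protein_coding", "eRNA",
                "lincRNA", "ncRNA", "other")
  cls <- as.character(S4Vectors::mcols(annotations)$class)
  if (is.null(cls)) stop("annotations need a 'class' metadata column")
  rank <- match(cls, priority)
  rank[is.na(rank)] <- match("other", priority)
  hits <- GenomicRanges::findOverlaps(bins, annotations, ignore.strand = TRUE)
  assigned <- rep(NA_integer_, length(bins))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    r <- rank[S4Vectors::subjectHits(hits)]
    best <- tapply(r, q, min)
    assigned[as.integer(names(best))] <- as.integer(best)
  }
  label <- ifelse(is.na(assigned), "unannotated", priority[assigned])
  out <- bins
  S4Vectors::mcols(out)$annotated <- !is.na(assigned)
  S4Vectors::mcols(out)$class <- label
  fractions <- table(factor(label, levels = c(priority, "unannotated")))
  fractions <- fractions / max(1L, length(bins))
  list(
    bins = out,
    fractions = structure(as.numeric(fractions), names = names(fractions)),
    by_chromosome = table(as.character(GenomicRanges::seqnames(bins)))
  )
}

#' Sensitivity, specificity and their geometric mean
#'
#' Scores a predicted call set against a truth call set on the same bin
#' universe: sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
#' and the joint F measure = sqrt(sensitivity x specificity). A degenerate
#' truth (all positive or all negative) leaves the undefined metric `NA`.
#'
#' @param predicted,truth logical vectors over the same bins.
#' @return List with `sensitivity`, `specificity`, `f_measure`.
#' @export
detection_metrics <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  tp <- sum(predicted & truth)
  fn <- sum(!predicted & truth)
  tn <- sum(!predicted & !truth)
  fp <- sum(predicted & !truth)
  sens <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0L) NA_real_ else tn / (tn + fp)
  f <- if (is.na(sens) || is.na(spec)) NA_real_ else sqrt(sens * spec)
  list(sensitivity = sens, specificity = spec, f_measure = f)
}
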