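#' Read proportions across chromatin states
#'
#' Assigns every read to the chromatin state it overlaps most (ties broken
#' toward the lowest state id), then reports the proportion of assigned
#' reads per state and its square root (the heatmap transform). Reads
#' overlapping no state are excluded and counted.
#'
#' @param reads a [read_set()] or `GRanges`.
#' @param states `GRanges` segmentation with a `state` metadata column
#'   (integer or factor labels).
#' @return List with `proportion` and `sqrt_proportion` (named numeric over
#'   all state levels, proportions summing to 1 when any read is assigned),
#'   `n_assigned`, `n_unassigned`.
#' @export
state_read_proportions <- function(reads, states) {
  gr <- as_reads_granges(reads)
  st <- S4Vectors::mcols(states)$state
  if (is.null(st)) stop("states need a 'state' metadata column")
  lev <- if (is.factor(st)) levels(st) else sort(unique(st))
  st <- as.character(st)
  hits <- GenomicRanges::findOverlaps(gr, states, ignore.strand = TRUE)
  n_assigned <- 0L
  counts <- stats::setNames(numeric(length(lev)), as.character(lev))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(gr)[q], GenomicRanges::ranges(states)[s]))
    sid <- match(st[s], as.character(lev))
    # per read: maximal overlap, then lowest state id
    ord <- order(q, -ov, sid)
    first <- !duplicated(q[ord])
    winner <- sid[ord][first]
    tab <- table(factor(winner, levels = seq_along(lev)))
    counts[] <- as.numeric(tab)
    n_assigned <- sum(tab)
  }
  prop <- if (n_assigned > 0) counts / n_assigned else counts
  list(
    proportion = prop,
    sqrt_proportion = sqrt(prop),
    n_assigned = as.integer(n_assigned),
    n_unassigned = length(gr) - as.integer(n_assigned)
  )
}

#' Width-weighted track score of regions
#'
#' Averages a bedGraph-style track over each region, weighting every track
#' interval by the width of its overlap with the region:
#' `score = sum(value * overlap) / sum(overlap)`. Regions with no track
#' coverage get `NA`.
#'
#' @param regions `GRanges`.
#' @param track `GRanges` with a numeric `score` column (as returned by
#'   [read_bedgraph()]); intervals assumed non-overlapping.
#' @return Numeric vector, one score per region.
#' @export
region_track_score <- function(regions, track) {
  v <- S4Vectors::mcols(track)$score
  if (is.null(v)) stop("track needs a 'score' column")
  hits <- GenomicRanges::findOverlaps(regions, track, ignore.strand = TRUE)
  out <- rep(NA_real_, length(regions))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(regions)[q], GenomicRanges::ranges(track)[s]))
    num <- tapply(v[s] * ov, q, sum)
    den <- tapply(ov, q, sum)
    out[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  }
  out
}

#' Random genomic regions matching a width distribution
#'
#' Draws `n` regions whose widths are resampled (with replacement) from
#' `widths`, placed uniformly over the genome: the chromosome is chosen
#' with probability proportional to its length among chromosomes that can
#' hold the region, the start uniformly within it. Nothing is excluded by
#' default (regions may span the entire genome).
#'
#' @param n number of regions.
#' @param widths width pool in bp (e.g. widths of a query set).
#' @param genome a [genome_build()].
#' @param exclude optional `GRanges` (e.g. blacklist); sampled regions
#'   overlapping it are redrawn.
#' @param seed optional integer seed.
#' @return Unstranded `GRanges` of `n` regions.
#' @export
sample_random_regions <- function(n, widths, genome, exclude = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- chrom_lengths(genome)
  if (max(widths) > max(lens))
    stop("region width ", max(widths), " exceeds every chromosome")
  draw <- function(k, w) {
    ok <- outer(lens, w, ">=")   # chrom x region eligibility
    chr <- character(k)
    start <- integer(k)
    for (i in seq_len(k)) {
      elig <- which(ok[, i])
      p <- lens[elig] - w[i] + 1
      ci <- elig[sample.int(length(elig), 1L, prob = p)]
      chr[i] <- names(lens)[ci]
      start[i] <- sample.int(lens[ci] - w[i] + 1L, 1L)
    }
    GenomicRanges::GRanges(
      seqnames = chr, ranges = IRanges::IRanges(start, width = w),
      seqinfo = genome$seqinfo
    )
  }
  w <- sample(widths, n, replace = TRUE)
  out <- draw(n, w)
  if (!is.null(exclude) && length(exclude)) {
    for (rep in 1:50) {
      bad <- IRanges::overlapsAny(out, exclude, ignore.strand = TRUE)
      if (!any(bad)) break
      out[bad] <- draw(sum(bad), GenomicRanges::width(out)[bad])
    }
  }
  out
}

#' Compare epigenomic track scores of query regions against random regions
#'
#' For each track, scores the query regions and `n_random` random regions
#' (width-matched, uniform over the genome) with [region_track_score()] and
#' runs a two-sided Wilcoxon rank-sum test. The direction is the sign of
#' the median difference (query minus random).
#'
#' @param query `GRanges` of regions of interest (e.g. XR-unique bins).
#' @param tracks named list of track `GRanges` (with `score`).
#' @param genome a [genome_build()].
#' @param n_random number of random regions (>= `length(query)`;
#'   default equal).
#' @param exclude optional `GRanges` excluded from random placement
#'   (off by default).
#' @param seed optional integer seed.
#' @return `data.frame` with one row per track: `track`, `query_median`,
#'   `random_median`, `direction` (+1/-1/0), `p_value`.
#' @export
compare_to_random <- function(query, tracks, genome, n_random = NULL,
                              exclude = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_random)) n_random <- length(query)
  if (n_random < length(query))
    stop("n_random must be at least the query size")
  rand <- sample_random_regions(n_random, GenomicRanges::width(query),
                                genome, exclude = exclude)
  rows <- lapply(names(tracks), function(nm) {
    qs <- region_track_score(query, tracks[[nm]])
    rs <- region_track_score(rand, tracks[[nm]])
    qs <- qs[!is.na(qs)]; rs <- rs[!is.na(rs)]
    p <- if (length(qs) && length(rs))
      stats::wilcox.test(qs, rs, exact = FALSE)$p.value else NA_real_
    md <- stats::median(qs) - stats::median(rs)
    data.frame(track = nm,
               query_median = stats::median(qs),
               random_median = stats::median(rs),
               direction = sign(md),
               p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
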