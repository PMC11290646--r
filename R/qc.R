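#' Collapse duplicate reads
#'
#' Reads identical in (chromosome, start, end, strand) are collapsed to a
#' single read; metadata of the first occurrence is kept. Read names and
#' mapping qualities do not enter the duplicate definition.
#'
#' @param reads a [read_set()] or `GRanges`.
#' @return Same type as the input, duplicates removed.
#' @export
dedup <- function(reads) {
  gr <- as_reads_granges(reads)
  replace_reads(reads, gr[!duplicated(gr)])
}

#' Post-alignment read quality control
#'
#' Applies the sequential XR-seq read filters in fixed order — duplicate
#' collapse, mapping quality strictly greater than `min_mapq`, chromosome
#' whitelist, read length within `len_range` — and records the survivor
#' count after each stage. Counts are monotone non-increasing by
#' construction.
#'
#' @param reads a [read_set()] or `GRanges` with a `mapq` metadata column.
#' @param min_mapq reads must have mapq strictly greater than this
#'   (default 20).
#' @param allowed_chroms chromosome names to keep; `NULL` keeps all.
#' @param len_range inclusive read-length window, default `c(19, 24)`.
#'
#' @return List with `reads` (filtered, same type as input) and `report`
#'   (`data.frame` with columns `stage`, `n`, `parameter`).
#' @export
qc_filter <- function(reads, min_mapq = 20, allowed_chroms = NULL,
                      len_range = c(19L, 24L)) {
  gr <- as_reads_granges(reads)
  counts <- c(total_mapped = length(gr))

  gr <- gr[!duplicated(gr)]
  counts["dedup"] <- length(gr)

  mapq <- S4Vectors::mcols(gr)$mapq
  if (is.null(mapq)) {
    warning("reads carry no mapq; all fail the mapping-quality filter")
    mapq <- rep(NA_real_, length(gr))
  }
  pass <- !is.na(mapq) & mapq > min_mapq
  gr <- gr[pass]
  counts["mapq"] <- length(gr)

  if (!is.null(allowed_chroms)) {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% allowed_chroms]
  }
  counts["chrom"] <- length(gr)

  w <- GenomicRanges::width(gr)
  gr <- gr[w >= len_range[1] & w <= len_range[2]]
  counts["qwidth"] <- length(gr)

  report <- data.frame(
    stage = names(counts),
    n = as.integer(counts),
    parameter = c("", "coord+strand identity",
                  sprintf("mapq > %g", min_mapq),
                  if (is.null(allowed_chroms)) "all"
                  else paste(allowed_chroms, collapse = ","),
                  sprintf("length %d-%d", len_range[1], len_range[2])),
    stringsAsFactors = FALSE
  )
  list(reads = replace_reads(reads, gr), report = report)
}

#' Strand-resolved TT dinucleotide map of a genome
#'
#' Finds every TT dinucleotide on both strands: TT occurrences in the given
#' (plus-strand) sequence, and AA occurrences, which read as TT on the minus
#' strand. Overlapping occurrences (runs of T) all count.
#'
#' @param seq [Biostrings::DNAStringSet], one entry per chromosome.
#' @param genome optional [genome_build()] whose seqinfo to attach.
#' @return Stranded `GRanges` of width-2 TT positions.
#' @export
build_tt_map <- function(seq, genome = NULL) {
  per_chrom <- lapply(names(seq), function(chr) {
    tt <- Biostrings::matchPattern("TT", seq[[chr]])
    aa <- Biostrings::matchPattern("AA", seq[[chr]])
    GenomicRanges::GRanges(
      seqnames = factor(chr, levels = names(seq)),
      ranges = c(IRanges::IRanges(start = Biostrings::start(tt), width = 2L),
                 IRanges::IRanges(start = Biostrings::start(aa), width = 2L)),
      strand = rep(c("+", "-"), c(length(tt), length(aa)))
    )
  })
  gr <- do.call(c, per_chrom)
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome$seqinfo)
    GenomeInfoDb::seqinfo(gr) <- genome$seqinfo
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Positional dinucleotide frequencies anchored at the 3' read end
#'
#' Computes, per read-length stratum and pooled, the frequency of each of
#' the 16 dinucleotides as a function of distance from the 3' end of the
#' read. Minus-strand reads are reverse-complemented before profiling, so
#' positions always run in read orientation.
#'
#' Position convention: the reported `position` is the number of
#' nucleotides strictly 3' of the dinucleotide, i.e. a dinucleotide
#' followed by g nucleotides before the 3' terminus has position g. Under
#' the dual-incision geometry (3' incision 6 nt past the dimer) the damage
#' TT sits at position 6 for every 3'-preserving trim length.
#'
#' @param reads a [read_set()] or `GRanges`.
#' @param seq genome sequence ([Biostrings::DNAStringSet]).
#'
#' @return Long-format `data.frame` with columns `stratum` (read length as
#'   character, plus `"pooled"`), `position`, `dinuc`, `freq`, `n` (reads
#'   observed at that position). Reads extending beyond their chromosome
#'   are excluded; the count is in `attr(,"excluded")`.
#' @seealso [tt_peak_position()]
#' @export
positional_dinuc_freq <- function(reads, seq) {
  gr <- as_reads_granges(reads)
  lens <- vapply(names(seq), function(n) length(seq[[n]]), integer(1))
  on_chrom <- as.character(GenomicRanges::seqnames(gr)) %in% names(seq)
  inside <- on_chrom &
    GenomicRanges::end(gr) <= lens[as.character(GenomicRanges::seqnames(gr))] &
    GenomicRanges::start(gr) >= 1L
  excluded <- sum(!inside)
  gr <- gr[inside]
  if (length(gr) == 0L) stop("no profilable reads")
  rseq <- extract_read_seqs(seq, gr)

  dinucs <- paste0(rep(c("A", "C", "G", "T"), each = 4),
                   rep(c("A", "C", "G", "T"), times = 4))
  strata <- split(rseq, nchar(rseq))
  count_stratum <- function(ss) {
    L <- nchar(ss[1])
    gaps <- 0:(L - 2L)
    counts <- matrix(0L, nrow = length(gaps), ncol = 16,
                     dimnames = list(gaps, dinucs))
    for (i in seq_along(gaps)) {
      g <- gaps[i]
      d <- substring(ss, L - g - 1L, L - g)
      tab <- table(factor(d, levels = dinucs))
      counts[i, ] <- as.integer(tab)
    }
    counts
  }
  stratum_counts <- lapply(strata, count_stratum)

  rows <- list()
  add_rows <- function(counts, label) {
    n_at <- rowSums(counts)
    freq <- counts / ifelse(n_at == 0, 1, n_at)
    data.frame(
      stratum = label,
      position = rep(as.integer(rownames(counts)), times = 16),
      dinuc = rep(colnames(counts), each = nrow(counts)),
      freq = as.vector(freq),
      n = rep(as.integer(n_at), times = 16),
      stringsAsFactors = FALSE
    )
  }
  for (L in names(stratum_counts))
    rows[[L]] <- add_rows(stratum_counts[[L]], L)
  # pooled across strata at matching 3'-anchored positions
  max_gap <- max(vapply(stratum_counts, nrow, integer(1)))
  pooled <- matrix(0L, nrow = max_gap, ncol = 16,
                   dimnames = list(0:(max_gap - 1L), dinucs))
  for (cc in stratum_counts)
    pooled[seq_len(nrow(cc)), ] <- pooled[seq_len(nrow(cc)), ] + cc
  rows[["pooled"]] <- add_rows(pooled, "pooled")

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

# Extract read sequences from a per-chromosome DNAStringSet, in read
# orientation (minus-strand reads reverse-complemented), preserving order.
extract_read_seqs <- function(seq, gr) {
  out <- character(length(gr))
  chr <- as.character(GenomicRanges::seqnames(gr))
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    v <- Biostrings::Views(seq[[ch]], start = GenomicRanges::start(gr)[idx],
                           end = GenomicRanges::end(gr)[idx])
    out[idx] <- as.character(v)
  }
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  if (any(minus))
    out[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[minus])))
  out
}

#' Position of maximal TT frequency in a dinucleotide profile
#'
#' @param profile output of [positional_dinuc_freq()].
#' @param stratum which stratum to use (default `"pooled"`).
#' @return Integer position (nt 3' of the dinucleotide) with the highest TT
#'   frequency.
#' @export
tt_peak_position <- function(profile, stratum = "pooled") {
  sub <- profile[profile$stratum == stratum & profile$dinuc == "TT" &
                   profile$n > 0, ]
  if (nrow(sub) == 0L) stop("no TT observations in stratum '", stratum, "'")
  sub$position[which.max(sub$freq)]
}

#' Per-gene TT counts on the transcribed and non-transcribed strands
#'
#' Counts TT dinucleotides fully inside each gene body, split by strand
#' class: the transcribed (template) strand is the complement of the
#' annotated gene strand, the non-transcribed (coding) strand matches it.
#' Also reports the natural-log-scale correlations between TS and NTS
#' counts and between counts and gene length, excluding zero-count genes
#' (exclusion counts in attributes).
#'
#' @param genes gene `GRanges`.
#' @param tt_map [build_tt_map()] result.
#' @return `data.frame` with `gene_id`, `length`, `tt_ts`, `tt_nts`, with
#'   attributes `cor_ts_nts_log`, `cor_tt_length_log`, `n_excluded_log`.
#' @export
tt_vs_length <- function(genes, tt_map) {
  ts_count <- intersect_count(genes, tt_map, min_read_overlap_frac = 1,
                              strand_rule = "opposite")
  nts_count <- intersect_count(genes, tt_map, min_read_overlap_frac = 1,
                               strand_rule = "same")
  gene_id <- S4Vectors::mcols(genes)$gene_id
  if (is.null(gene_id)) gene_id <- as.character(seq_along(genes))
  out <- data.frame(
    gene_id = gene_id,
    length = GenomicRanges::width(genes),
    tt_ts = ts_count,
    tt_nts = nts_count,
    stringsAsFactors = FALSE
  )
  ok <- out$tt_ts > 0 & out$tt_nts > 0
  attr(out, "cor_ts_nts_log") <-
    if (sum(ok) >= 3) stats::cor(log(out$tt_ts[ok]), log(out$tt_nts[ok]))
    else NA_real_
  tot <- out$tt_ts + out$tt_nts
  ok2 <- tot > 0
  attr(out, "cor_tt_length_log") <-
    if (sum(ok2) >= 3) stats::cor(log(tot[ok2]), log(out$length[ok2]))
    else NA_real_
  attr(out, "n_excluded_log") <- sum(!ok)
  out
}

#' Mean TT content along the 100-bin metagene layout
#'
#' Counts TT dinucleotides per metagene bin (same 100-bin TSS/TES layout as
#' [metagene_profile()]) for each strand class and averages over genes,
#' yielding the expected-damage profile that read-level metagenes are
#' compared against.
#'
#' @param genes gene `GRanges` (should satisfy [select_profile_genes()]).
#' @param tt_map [build_tt_map()] result.
#' @return `data.frame` with `bin` (1--100), `strand_class` (`TS`/`NTS`),
#'   `mean_tt`.
#' @export
tt_metagene <- function(genes, tt_map) {
  layout <- metagene_bin_layout(genes)
  ts <- intersect_count(layout$bins, tt_map, min_read_overlap_frac = 1,
                        strand_rule = "opposite")
  nts <- intersect_count(layout$bins, tt_map, min_read_overlap_frac = 1,
                         strand_rule = "same")
  bin <- S4Vectors::mcols(layout$bins)$bin
  data.frame(
    bin = rep(1:100, 2),
    strand_class = rep(c("TS", "NTS"), each = 100),
    mean_tt = c(as.vector(tapply(ts, bin, mean)),
                as.vector(tapply(nts, bin, mean)))
  )
}
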