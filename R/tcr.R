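#' Select well-separated long genes for strand-resolved profiling
#'
#' Keeps genes strictly longer than `min_length` bp whose distance to the
#' nearest neighbouring gene on either side — any strand, any biotype — is
#' at least `min_gap` bp. The separation requirement protects the
#' transcribed/non-transcribed strand assignment from reads belonging to a
#' neighbouring gene.
#'
#' @param genes gene `GRanges`.
#' @param min_length minimum gene length, exclusive (default 2000).
#' @param min_gap minimum intergenic distance in bp (default 500).
#' @return The retained subset of `genes`.
#' @export
select_profile_genes <- function(genes, min_length = 2000, min_gap = 500) {
  if (length(genes) == 0L) return(genes)
  # order by coordinate only (GRanges order would sort by strand as well)
  ord <- order(as.character(GenomicRanges::seqnames(genes)),
               GenomicRanges::start(genes), GenomicRanges::end(genes))
  g <- genes[ord]
  chr <- as.character(GenomicRanges::seqnames(g))
  n <- length(g)
  gap_prev <- rep(Inf, n)
  gap_next <- rep(Inf, n)
  if (n > 1L) {
    same <- chr[-1] == chr[-n]
    gp <- GenomicRanges::start(g)[-1] - GenomicRanges::end(g)[-n] - 1L
    gap_prev[-1][same] <- gp[same]
    gap_next[-n][same] <- gp[same]
  }
  keep <- GenomicRanges::width(g) > min_length &
    pmin(gap_prev, gap_next) >= min_gap
  sel <- logical(n)
  sel[ord] <- keep   # map back to input order
  genes[sel]
}

#' Gene-level quality control on damage opportunity and read support
#'
#' Retains genes that have at least `min_tt` TT dinucleotides on the
#' transcribed OR the non-transcribed strand, and at least `min_reads`
#' reads in total across all supplied XR-seq samples (strand-blind,
#' half-read overlap).
#'
#' @param genes gene `GRanges`.
#' @param tt_map [build_tt_map()] result.
#' @param read_sets list of [read_set()]s (or `GRanges`).
#' @param min_tt,min_reads thresholds (default 10 each).
#' @return The retained subset of `genes`.
#' @export
gene_qc <- function(genes, tt_map, read_sets, min_tt = 10, min_reads = 10) {
  tt <- tt_vs_length(genes, tt_map)
  total <- integer(length(genes))
  for (rs in read_sets)
    total <- total + intersect_count(genes, rs, min_read_overlap_frac = 0.5,
                                     strand_rule = "ignore")
  genes[(tt$tt_ts >= min_tt | tt$tt_nts >= min_tt) & total >= min_reads]
}

#' Strand-resolved read counts over genes
#'
#' Counts reads on the transcribed strand (template; opposite of the
#' annotated gene strand, bedtools `-S`) and the non-transcribed strand
#' (coding; same strand, `-s`), requiring at least `frac` of the read
#' inside the gene.
#'
#' @param genes stranded gene `GRanges`.
#' @param reads a [read_set()] or stranded `GRanges`.
#' @param frac minimum overlap fraction of the read (default 0.5).
#' @return `data.frame` with columns `ts` and `nts`.
#' @export
ts_nts_counts <- function(genes, reads, frac = 0.5) {
  gr <- as_reads_granges(reads)
  if (any(as.character(GenomicRanges::strand(gr)) == "*"))
    stop("unstranded reads: XR-seq reads must carry a strand")
  if (any(as.character(GenomicRanges::strand(genes)) == "*"))
    stop("unstranded genes: strand is required to define the template")
  data.frame(
    ts = intersect_count(genes, gr, frac, "opposite"),
    nts = intersect_count(genes, gr, frac, "same")
  )
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / (length_bp / 1000) / (library_size / 1e6)`. Invariant
#' under duplicating every read together with the library size.
#'
#' @param count read count(s).
#' @param length_bp feature length(s) in bp (> 0).
#' @param library_size total mapped reads in the sample (> 0).
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, length_bp, library_size) {
  stopifnot(all(length_bp > 0), all(library_size > 0))
  count / (length_bp / 1000) / (library_size / 1e6)
}

#' Transcribed-strand fraction TS / (TS + NTS)
#'
#' The per-gene proxy statistic for transcription-coupled repair: 0.5 means
#' no strand preference, values near 1 indicate repair confined to the
#' template strand. Genes with zero reads on both strands are undefined and
#' reported as `NA`, never 0.
#'
#' @param ts,nts read counts on the transcribed / non-transcribed strand.
#' @return Numeric vector in `[0, 1]` with `NA` where both counts are 0.
#' @export
ts_fraction <- function(ts, nts) {
  tot <- ts + nts
  ifelse(tot == 0, NA_real_, ts / tot)
}

#' Per-gene repair strand summary
#'
#' Combines strand-resolved counts, RPKM normalisation and the TS fraction
#' into the per-gene table used for genome-wide TCR quantification.
#'
#' @inheritParams ts_nts_counts
#' @param library_size total reads in the sample; defaults to
#'   `library_size(reads)`.
#' @return `data.frame` with `gene_id`, `ts_count`, `nts_count`, `ts_rpkm`,
#'   `nts_rpkm`, `ts_fraction`; attribute `n_undefined` counts 0/0 genes.
#' @export
repair_strand_summary <- function(genes, reads, frac = 0.5,
                                  library_size = NULL) {
  if (is.null(library_size)) library_size <- xrtcr::library_size(reads)
  cnt <- ts_nts_counts(genes, reads, frac)
  gene_id <- S4Vectors::mcols(genes)$gene_id
  if (is.null(gene_id)) gene_id <- as.character(seq_along(genes))
  len <- GenomicRanges::width(genes)
  out <- data.frame(
    gene_id = gene_id,
    ts_count = cnt$ts,
    nts_count = cnt$nts,
    ts_rpkm = rpkm(cnt$ts, len, library_size),
    nts_rpkm = rpkm(cnt$nts, len, library_size),
    ts_fraction = ts_fraction(cnt$ts, cnt$nts),
    stringsAsFactors = FALSE
  )
  attr(out, "n_undefined") <- sum(is.na(out$ts_fraction))
  out
}

# The fixed 100-bin metagene layout: 50 bins over [TSS-500, TSS+1000) and
# 50 bins over [TES-1000, TES+500), each 30 bp, laid out in transcription
# orientation (bin 1 is 500 bp upstream of the TSS for both strands).
# Genes whose windows leave the chromosome are dropped and counted.
metagene_bin_layout <- function(genes, upstream = 500L, downstream = 1000L,
                                n_bins = 50L) {
  span <- upstream + downstream
  bw <- span / n_bins
  if (bw != floor(bw)) stop("window of ", span, " bp not divisible into ",
                            n_bins, " equal bins")
  bw <- as.integer(bw)
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  tss <- ifelse(plus, GenomicRanges::start(genes), GenomicRanges::end(genes))
  tes <- ifelse(plus, GenomicRanges::end(genes), GenomicRanges::start(genes))
  lens <- GenomeInfoDb::seqlengths(genes)[
    as.character(GenomicRanges::seqnames(genes))]
  lo <- pmin(tss - upstream, tes - downstream)
  hi <- pmax(tss + downstream - 1L, tes + upstream - 1L)
  ok <- lo >= 1L & (is.na(lens) | hi <= lens)
  dropped <- sum(!ok)
  g <- genes[ok]
  plus <- plus[ok]; tss <- tss[ok]; tes <- tes[ok]
  ng <- length(g)
  if (ng == 0L) stop("no genes with in-bounds metagene windows")

  rel <- seq_len(n_bins)   # bin index within a window
  # offsets of bin starts in transcription coordinates
  tss_off <- -upstream + (rel - 1L) * bw
  tes_off <- -downstream + (rel - 1L) * bw
  one_gene <- function(i) {
    if (plus[i]) {
      starts <- c(tss[i] + tss_off, tes[i] + tes_off)
      IRanges::IRanges(start = starts, width = bw)
    } else {
      ends <- c(tss[i] - tss_off, tes[i] - tes_off)
      IRanges::IRanges(end = ends, width = bw)
    }
  }
  rngs <- lapply(seq_len(ng), one_gene)
  bins <- GenomicRanges::GRanges(
    seqnames = rep(GenomicRanges::seqnames(g), each = 2L * n_bins),
    ranges = do.call(c, rngs),
    strand = rep(GenomicRanges::strand(g), each = 2L * n_bins),
    gene = rep(seq_len(ng), each = 2L * n_bins),
    bin = rep(seq_len(2L * n_bins), ng),
    seqinfo = GenomeInfoDb::seqinfo(genes)
  )
  list(bins = bins, genes = g, bin_width = bw, dropped = dropped)
}

#' Metagene repair profile over 100 gene-anchored bins
#'
#' For each gene, 50 bins span 500 bp upstream of the TSS to 1 kb
#' downstream, and 50 bins span 1 kb upstream of the TES to 500 bp
#' downstream — 100 bins of 30 bp per gene, in transcription orientation.
#' Reads are counted per bin with the half-read overlap rule on the
#' requested strand class (TS = opposite of gene strand, NTS = same) and
#' RPKM-normalised by bin width and library size.
#'
#' @param genes gene `GRanges`, ideally from [select_profile_genes()].
#' @param reads a [read_set()] or stranded `GRanges`.
#' @param strand_class `"TS"` or `"NTS"`.
#' @param frac minimum read-overlap fraction (default 0.5).
#' @param library_size defaults to `library_size(reads)`.
#'
#' @return Object of class `"MetageneMatrix"`: list with `matrix` (genes x
#'   100 RPKM), `mean` (length-100 column means), `strand_class`,
#'   `bin_width`, `dropped` (genes with out-of-bounds windows).
#' @export
metagene_profile <- function(genes, reads, strand_class = c("TS", "NTS"),
                             frac = 0.5, library_size = NULL) {
  strand_class <- match.arg(strand_class)
  if (is.null(library_size)) library_size <- xrtcr::library_size(reads)
  layout <- metagene_bin_layout(genes)
  rule <- if (strand_class == "TS") "opposite" else "same"
  cnt <- intersect_count(layout$bins, reads, frac, rule)
  val <- rpkm(cnt, layout$bin_width, library_size)
  m <- matrix(val, ncol = 100L, byrow = TRUE)
  ids <- S4Vectors::mcols(layout$genes)$gene_id
  if (!is.null(ids)) rownames(m) <- ids
  structure(
    list(matrix = m, mean = colMeans(m), strand_class = strand_class,
         bin_width = layout$bin_width, dropped = layout$dropped),
    class = "MetageneMatrix"
  )
}

#' @export
print.MetageneMatrix <- function(x, ...) {
  cat(sprintf("MetageneMatrix (%s): %d genes x %d bins, %d dropped\n",
              x$strand_class, nrow(x$matrix), ncol(x$matrix), x$dropped))
  invisible(x)
}

#' Strand-resolved signal matrices around TSSs
#'
#' Deduplicates the supplied TSSs and enforces a minimum pairwise
#' separation by scanning each chromosome in coordinate order and keeping a
#' TSS iff it lies at least `min_sep` bp from the last kept one. For every
#' kept TSS the window `[TSS - flank, TSS + flank)` is divided into bins of
#' `bin_width` bp (in transcription orientation) and reads are counted per
#' bin on the transcribed and non-transcribed strands, RPKM-normalised.
#' Rows are ranked by total signal (descending), the deepTools-style
#' default.
#'
#' @param tss stranded `GRanges` of width-1 TSS positions.
#' @param reads a [read_set()] or stranded `GRanges`.
#' @param flank half-window in bp (default 500).
#' @param min_sep minimum TSS separation in bp (default 1000).
#' @param bin_width column bin width in bp (default 50).
#' @param frac minimum read-overlap fraction (default 0.5).
#' @param library_size defaults to `library_size(reads)`.
#'
#' @return List with `ts` and `nts` matrices (rows = kept TSSs in ranked
#'   order), `order` (ranking permutation of the kept TSSs), `tss` (the
#'   kept TSSs, input order), `best_half` (row indices, within the ranked
#'   matrices, of the best-represented half).
#' @export
tss_heatmap <- function(tss, reads, flank = 500L, min_sep = 1000L,
                        bin_width = 50L, frac = 0.5, library_size = NULL) {
  if (is.null(library_size)) library_size <- xrtcr::library_size(reads)
  tss <- tss[!duplicated(tss)]
  ord <- order(as.character(GenomicRanges::seqnames(tss)),
               GenomicRanges::start(tss))
  keep <- logical(length(tss))
  last_chr <- ""
  last_pos <- -Inf
  for (i in ord) {
    chr <- as.character(GenomicRanges::seqnames(tss))[i]
    pos <- GenomicRanges::start(tss)[i]
    if (chr != last_chr || pos - last_pos >= min_sep) {
      keep[i] <- TRUE
      last_chr <- chr
      last_pos <- pos
    }
  }
  tss <- tss[keep]
  n <- length(tss)
  n_bins <- as.integer(2L * flank / bin_width)
  plus <- as.character(GenomicRanges::strand(tss)) == "+"
  pos <- GenomicRanges::start(tss)
  offs <- -flank + (seq_len(n_bins) - 1L) * bin_width
  rngs <- lapply(seq_len(n), function(i) {
    if (plus[i]) IRanges::IRanges(start = pos[i] + offs, width = bin_width)
    else IRanges::IRanges(end = pos[i] - offs, width = bin_width)
  })
  bins <- GenomicRanges::GRanges(
    seqnames = rep(GenomicRanges::seqnames(tss), each = n_bins),
    ranges = do.call(c, rngs),
    strand = rep(GenomicRanges::strand(tss), each = n_bins)
  )
  ts <- matrix(rpkm(intersect_count(bins, reads, frac, "opposite"),
                    bin_width, library_size), ncol = n_bins, byrow = TRUE)
  nts <- matrix(rpkm(intersect_count(bins, reads, frac, "same"),
                     bin_width, library_size), ncol = n_bins, byrow = TRUE)
  ranking <- order(rowSums(ts) + rowSums(nts), decreasing = TRUE)
  list(
    ts = ts[ranking, , drop = FALSE],
    nts = nts[ranking, , drop = FALSE],
    order = ranking,
    tss = tss,
    best_half = seq_len(floor(n / 2))
  )
}
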