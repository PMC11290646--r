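#' Simulate a genome with i.i.d. base composition
#'
#' Draws every base independently from `config$genome$base_probs`. With the
#' default AT-rich composition the expected TT density on each strand is
#' p(T)^2 per dinucleotide position, which downstream damage maps inherit.
#'
#' @param config a [sim_config()].
#' @param seed optional integer; when given, `set.seed()` is called first.
#'
#' @return List with `genome` (a [genome_build()]) and `seq`
#'   (a [Biostrings::DNAStringSet], one entry per chromosome).
#' @export
simulate_genome <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- config$genome$chrom_lengths
  if (any(lens <= 0)) stop("zero-length chromosome in config")
  probs <- config$genome$base_probs[c("A", "C", "G", "T")]
  probs <- probs / sum(probs)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  seq <- Biostrings::DNAStringSet(seqs)
  names(seq) <- names(lens)
  list(genome = genome_build("sim", lens), seq = seq)
}

# Place `widths` intervals inside `gaps` (GRanges of allowed space) with at
# least `min_sep` bp between placed intervals: greedy gap allocation with
# exact capacity accounting, then a stars-and-bars spread of the slack
# within each gap — placement succeeds whenever the space allows it,
# without rejection sampling.
place_in_gaps <- function(gaps, widths, min_sep = 10L) {
  n <- length(widths)
  if (n == 0L)
    return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(gaps)))
  gw <- GenomicRanges::width(gaps)
  # greedy allocation with exact capacity accounting: a gap holding k
  # intervals of total width W uses W + (k-1)*min_sep bp; items are
  # considered widest-first (better packing), each assigned to a random
  # feasible gap with probability proportional to its remaining space
  used_w <- numeric(length(gaps))
  used_n <- integer(length(gaps))
  gap_of_item <- integer(n)
  for (it in order(widths, decreasing = TRUE)) {
    need <- widths[it] + ifelse(used_n > 0L, min_sep, 0)
    free <- gw - used_w - pmax(0L, used_n - 1L) * min_sep
    feasible <- which(free >= need)
    if (length(feasible) == 0L) {
      placed <- sum(gap_of_item > 0L)
      stop("cannot place ", n, " intervals; achievable count is ~", placed)
    }
    g <- feasible[sample.int(length(feasible), 1L,
                             prob = (free - need)[feasible] + 1)]
    gap_of_item[it] <- g
    used_w[g] <- used_w[g] + widths[it]
    used_n[g] <- used_n[g] + 1L
  }
  i_split <- split(seq_len(n), gap_of_item)
  out <- vector("list", length(i_split))
  for (j in seq_along(i_split)) {
    gi <- as.integer(names(i_split))[j]
    items <- i_split[[j]]
    ws <- widths[items]
    k <- length(ws)
    slack <- gw[gi] - sum(ws) - (k - 1L) * min_sep
    if (slack < 0) stop("gap overfilled during placement")
    # random composition of slack into k+1 parts
    cuts <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
    starts <- GenomicRanges::start(gaps)[gi] + cuts +
      cumsum(c(0L, ws[-k] + min_sep))
    out[[j]] <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(gaps)[gi],
      ranges = IRanges::IRanges(start = starts, width = ws),
      item = items,
      seqinfo = GenomeInfoDb::seqinfo(gaps)
    )
  }
  GenomicRanges::sort(do.call(c, out), ignore.strand = TRUE)
}

#' Simulate gene and ncRNA annotations plus the ground truth
#'
#' Places non-overlapping protein-coding genes with a minimum inter-gene gap,
#' then intergenic ncRNA loci well clear of genes: piRNA loci confined to a
#' cluster span on one chromosome, eRNA loci (a configured fraction
#' bidirectional) and lincRNA loci. A blacklist of arbitrary intervals is
#' drawn unconstrained. The returned `truth` records which loci are truly
#' transcribed and on which strand, and the per-gene expression levels used
#' by every read simulator, so detection can be scored against ground truth.
#'
#' @param config a [sim_config()].
#' @param genome a [genome_build()] (from [simulate_genome()]).
#' @param seed optional integer seed.
#'
#' @return List with elements
#'   \describe{
#'     \item{genes}{`GRanges` with `gene_id`, `biotype`, `expression`.}
#'     \item{annotations}{`GRanges` of ncRNA loci with `class`
#'       (`piRNA`/`eRNA`/`lincRNA`) and `locus_id`.}
#'     \item{blacklist}{`GRanges`.}
#'     \item{truth}{list: `transcribed_intergenic` (stranded `GRanges` of
#'       truly transcribed intergenic loci with `class` and `expression`),
#'       `gene_expression` (named numeric), `pirna_cluster` (`GRanges`).}
#'   }
#' @export
simulate_annotations <- function(config = sim_config(), genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(genome, "GenomeBuild"))
  lens <- chrom_lengths(genome)
  whole <- GenomicRanges::GRanges(
    seqnames = names(lens),
    ranges = IRanges::IRanges(start = 1L, width = lens),
    seqinfo = genome$seqinfo
  )

  ## --- genes ---------------------------------------------------------------
  gcfg <- config$genes
  glen <- pmax(gcfg$min_length,
               round(stats::rlnorm(gcfg$n, gcfg$length_meanlog, gcfg$length_sdlog)))
  genes <- place_in_gaps(whole, glen, min_sep = gcfg$min_gap)
  S4Vectors::mcols(genes)$item <- NULL
  GenomicRanges::strand(genes) <- sample(
    c("+", "-"), length(genes), replace = TRUE,
    prob = c(gcfg$plus_strand_prob, 1 - gcfg$plus_strand_prob)
  )
  S4Vectors::mcols(genes)$gene_id <- sprintf("gene%04d", seq_along(genes))
  S4Vectors::mcols(genes)$biotype <- "protein_coding"
  expr <- stats::rlnorm(length(genes), gcfg$expr_meanlog, gcfg$expr_sdlog)
  S4Vectors::mcols(genes)$expression <- expr

  ## --- intergenic space for ncRNA placement --------------------------------
  ncfg <- config$ncrna
  buffered <- GenomicRanges::trim(suppressWarnings(GenomicRanges::resize(
    genes, GenomicRanges::width(genes) + 2L * ncfg$buffer, fix = "center"
  )))
  free <- GenomicRanges::setdiff(whole, merge_intervals(buffered),
                                 ignore.strand = TRUE)

  ## piRNAs: restricted to the cluster span on the designated chromosome
  span <- ncfg$pirna_cluster_span
  clen <- lens[[ncfg$pirna_chrom]]
  cluster <- GenomicRanges::GRanges(
    seqnames = ncfg$pirna_chrom,
    ranges = IRanges::IRanges(start = max(1L, floor(span[1] * clen)),
                              end = ceiling(span[2] * clen)),
    seqinfo = genome$seqinfo
  )
  pir_space <- GenomicRanges::intersect(free, cluster, ignore.strand = TRUE)
  pirna <- place_in_gaps(pir_space, rep(ncfg$pirna_width, ncfg$pirna_n),
                         min_sep = 12L)
  GenomicRanges::strand(pirna) <- sample(c("+", "-"), length(pirna), TRUE)
  S4Vectors::mcols(pirna)$class <- rep("piRNA", length(pirna))

  ## eRNAs and lincRNAs anywhere intergenic (cluster left for piRNAs)
  other_space <- GenomicRanges::setdiff(free, cluster, ignore.strand = TRUE)
  ew <- sample(ncfg$erna_width_range[1]:ncfg$erna_width_range[2],
               ncfg$erna_n, replace = TRUE)
  lw <- sample(ncfg$lincrna_width_range[1]:ncfg$lincrna_width_range[2],
               ncfg$lincrna_n, replace = TRUE)
  both <- place_in_gaps(other_space, c(ew, lw), min_sep = 200L)
  is_linc <- S4Vectors::mcols(both)$item > length(ew)
  S4Vectors::mcols(both)$item <- NULL
  erna <- both[!is_linc]
  linc <- both[is_linc]
  GenomicRanges::strand(linc) <- sample(c("+", "-"), length(linc), TRUE)
  S4Vectors::mcols(linc)$class <- rep("lincRNA", length(linc))
  bidir <- stats::runif(length(erna)) < ncfg$erna_bidirectional_frac
  GenomicRanges::strand(erna) <- ifelse(bidir, "*",
                                        sample(c("+", "-"), length(erna), TRUE))
  S4Vectors::mcols(erna)$class <- rep("eRNA", length(erna))
  S4Vectors::mcols(erna)$bidirectional <- bidir

  S4Vectors::mcols(pirna)$item <- NULL
  ann <- GenomicRanges::sort(c(
    pirna,
    erna[, "class"],
    linc
  ), ignore.strand = TRUE)
  S4Vectors::mcols(ann)$locus_id <- sprintf(
    "%s%04d", tolower(as.character(S4Vectors::mcols(ann)$class)),
    seq_along(ann)
  )

  ## --- blacklist (unconstrained) -------------------------------------------
  bcfg <- config$blacklist
  bl_w <- sample(bcfg$width_range[1]:bcfg$width_range[2], bcfg$n, replace = TRUE)
  bl_chr <- sample(names(lens), bcfg$n, replace = TRUE, prob = lens / sum(lens))
  bl_start <- vapply(seq_len(bcfg$n), function(i) {
    sample.int(lens[[bl_chr[i]]] - bl_w[i], 1L)
  }, integer(1))
  blacklist <- GenomicRanges::GRanges(
    seqnames = bl_chr, ranges = IRanges::IRanges(bl_start, width = bl_w),
    seqinfo = genome$seqinfo
  )

  ## --- ground truth ---------------------------------------------------------
  # all ncRNA loci are truly transcribed; bidirectional eRNAs on both strands
  tx <- ann
  n_tx <- length(tx)
  tx_expr <- stats::rlnorm(n_tx, gcfg$expr_meanlog, gcfg$expr_sdlog)
  # keep every planted locus detectable at default depth
  tx_expr <- pmax(tx_expr, 0.5)
  S4Vectors::mcols(tx)$expression <- tx_expr
  truth <- list(
    transcribed_intergenic = tx,
    gene_expression = structure(expr, names = S4Vectors::mcols(genes)$gene_id),
    pirna_cluster = cluster
  )

  list(genes = genes, annotations = ann, blacklist = blacklist, truth = truth)
}
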