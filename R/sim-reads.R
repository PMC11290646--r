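#' Simulate primary excision products around pyrimidine dimers
#'
#' Applies the dual-incision geometry of nucleotide excision repair to a set
#' of damage sites (TT dinucleotides with a strand): the 5' incision falls
#' `five_prime_nt` (+/- jitter) upstream of the dimer and the 3' incision
#' `three_prime_nt` downstream, in the orientation of the damaged strand.
#' With the default 19/6 offsets around a 2-nt dimer and zero jitter every
#' product is 19 + 2 + 6 = 27 nt, and the dimer always sits exactly
#' `three_prime_nt` nucleotides from the product's 3' end — the property
#' that 3'-preserving trimming keeps for the sequenced reads.
#'
#' Jitter is drawn as `Binomial(2 * jitter, 1/2) - jitter` (mode 0), applied
#' to the 5' incision only, so the modal product length stays 27 nt and the
#' 3' geometry is exact. Events whose product would run off the chromosome
#' are dropped and counted in `attr(,"dropped")`.
#'
#' @param config a [sim_config()] (only `config$xr$excision` is used).
#' @param damage_sites stranded [GenomicRanges::GRanges] of dimer positions
#'   (width = `dimer_len`), carrying seqinfo with chromosome lengths.
#' @param seed optional integer seed.
#'
#' @return Stranded `GRanges` of excision products with metadata column
#'   `dimer_start` (1-based start of the damaged dinucleotide).
#' @export
simulate_excision_products <- function(config = sim_config(), damage_sites,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ex <- config$xr$excision
  n <- length(damage_sites)
  if (n == 0L) return(damage_sites)
  jit <- if (ex$jitter > 0)
    stats::rbinom(n, 2L * ex$jitter, 0.5) - ex$jitter else integer(n)
  five <- ex$five_prime_nt + jit
  minus <- as.character(GenomicRanges::strand(damage_sites)) == "-"
  ds <- GenomicRanges::start(damage_sites)
  de <- GenomicRanges::end(damage_sites)
  start <- ifelse(minus, ds - ex$three_prime_nt, ds - five)
  end <- ifelse(minus, de + five, de + ex$three_prime_nt)
  lens <- GenomeInfoDb::seqlengths(damage_sites)[
    as.character(GenomicRanges::seqnames(damage_sites))]
  ok <- start >= 1L & (is.na(lens) | end <= lens)
  frag <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(damage_sites)[ok],
    ranges = IRanges::IRanges(start = start[ok], end = end[ok]),
    strand = GenomicRanges::strand(damage_sites)[ok],
    dimer_start = ds[ok],
    seqinfo = GenomeInfoDb::seqinfo(damage_sites)
  )
  attr(frag, "dropped") <- sum(!ok)
  frag
}

# 3'-preserving trim: shorten each fragment from its 5' end to a target
# length drawn uniformly from trim_range (never lengthening), so the
# dimer-to-3'-end geometry survives in the sequenced read.
trim_fragments <- function(frags, trim_range) {
  n <- length(frags)
  if (n == 0L) return(frags)
  target <- sample(trim_range[1]:trim_range[2], n, replace = TRUE)
  target <- pmin(target, GenomicRanges::width(frags))
  minus <- as.character(GenomicRanges::strand(frags)) == "-"
  new_start <- ifelse(minus, GenomicRanges::start(frags),
                      GenomicRanges::end(frags) - target + 1L)
  new_end <- ifelse(minus, GenomicRanges::start(frags) + target - 1L,
                    GenomicRanges::end(frags))
  IRanges::ranges(frags) <- IRanges::IRanges(start = new_start, end = new_end)
  frags
}

# Candidate TCR damage sites: TT dinucleotides on the template strand of
# each transcribed locus, weighted by exp(-d / decay) where d is the
# distance from the locus 5' end (TSS) in transcription orientation, and
# normalised within each locus so locus read shares follow `expression`.
tcr_site_table <- function(tt_map, loci, decay_bp) {
  if (length(loci) == 0L)
    return(list(sites = GenomicRanges::GRanges(), weight = numeric(0)))
  lstrand <- as.character(GenomicRanges::strand(loci))
  # bidirectional loci (strand "*") transcribe both strands: duplicate
  both <- lstrand == "*"
  if (any(both)) {
    plus <- loci[both]; GenomicRanges::strand(plus) <- "+"
    minus <- loci[both]; GenomicRanges::strand(minus) <- "-"
    ex <- S4Vectors::mcols(loci)$expression
    S4Vectors::mcols(plus)$expression <- ex[both] / 2
    S4Vectors::mcols(minus)$expression <- ex[both] / 2
    loci <- c(loci[!both], plus, minus)
    lstrand <- as.character(GenomicRanges::strand(loci))
  }
  hits <- GenomicRanges::findOverlaps(tt_map, loci, type = "within",
                                      ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(list(sites = GenomicRanges::GRanges(), weight = numeric(0)))
  s <- S4Vectors::queryHits(hits)
  l <- S4Vectors::subjectHits(hits)
  template <- ifelse(lstrand[l] == "+", "-", "+")
  keep <- as.character(GenomicRanges::strand(tt_map))[s] == template
  s <- s[keep]; l <- l[keep]
  if (length(s) == 0L)
    return(list(sites = GenomicRanges::GRanges(), weight = numeric(0)))
  d <- ifelse(lstrand[l] == "+",
              GenomicRanges::start(tt_map)[s] - GenomicRanges::start(loci)[l],
              GenomicRanges::end(loci)[l] - GenomicRanges::end(tt_map)[s])
  w <- exp(-d / decay_bp)
  # normalise within locus, scale by locus expression
  wsum <- tapply(w, l, sum)
  w <- w / as.numeric(wsum[as.character(l)])
  w <- w * S4Vectors::mcols(loci)$expression[l]
  empty <- setdiff(which(S4Vectors::mcols(loci)$expression > 0 &
                           GenomicRanges::width(loci) >= 2), unique(l))
  if (length(empty))
    warning(length(empty), " transcribed locus/loci contain no template-",
            "strand TT and contribute zero TCR reads")
  list(sites = tt_map[s], weight = w, locus = l)
}

#' Simulate one XR-seq sample
#'
#' Generates mapped XR-seq reads for a genotype/timepoint/replicate under
#' the two-pathway repair model. A fraction `tcr_weight` of reads derives
#' from transcription-coupled repair: damage at TT dinucleotides on the
#' template strand of transcribed loci (genes plus the truth's intergenic
#' loci), positionally weighted by an exponential 5'-to-3' gradient whose
#' decay length is `decay_bp * timepoint_decay_multiplier[timepoint]` (the
#' TSS-proximal skew flattens as repair proceeds). The remaining
#' `global_weight` fraction is global repair: TT sites drawn uniformly from
#' both strands genome-wide. Each damage event is turned into a dual-incision
#' excision product and trimmed 3'-preservingly to 19--24 nt; per-read
#' mapping qualities are drawn from `config$xr$mapq_values`.
#'
#' Genotype presets: WT repairs by both pathways, `csb-1` has
#' `tcr_weight = 0`, `xpc-1` has `global_weight = 0`.
#'
#' @param config a [sim_config()].
#' @param genome a [genome_build()].
#' @param seq genome sequence ([Biostrings::DNAStringSet]); used to build
#'   the TT map unless `tt_map` is supplied.
#' @param genes gene `GRanges` from [simulate_annotations()].
#' @param truth truth list from [simulate_annotations()].
#' @param genotype `"WT"`, `"csb-1"` or `"xpc-1"`.
#' @param timepoint one of [xr_timepoints()].
#' @param replicate integer replicate index.
#' @param n_reads reads to draw (default `config$xr$reads_per_sample`).
#' @param tt_map optional precomputed [build_tt_map()] result.
#' @param seed optional integer seed.
#'
#' @return A [read_set()] with `mapq` metadata on the reads.
#' @export
simulate_xrseq <- function(config = sim_config(), genome, seq, genes, truth,
                           genotype = "xpc-1", timepoint = "1h",
                           replicate = 1L, n_reads = NULL, tt_map = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xcfg <- config$xr
  preset <- xcfg$genotypes[[genotype]]
  if (is.null(preset)) stop("no genotype preset '", genotype, "'")
  if (is.null(n_reads)) n_reads <- xcfg$reads_per_sample
  if (is.null(tt_map)) tt_map <- build_tt_map(seq, genome)

  wsum <- preset$tcr_weight + preset$global_weight
  n_tcr <- stats::rbinom(1L, n_reads, preset$tcr_weight / wsum)
  n_glob <- n_reads - n_tcr

  decay <- xcfg$decay_bp *
    xcfg$timepoint_decay_multiplier[[timepoint]]

  damage <- GenomicRanges::GRanges(seqinfo = genome$seqinfo)
  if (n_tcr > 0L) {
    loci <- c(
      granges_with_expression(genes),
      granges_with_expression(truth$transcribed_intergenic)
    )
    tab <- tcr_site_table(tt_map, loci, decay)
    if (length(tab$sites) == 0L) stop("no TCR-eligible TT sites in genome")
    pick <- sample.int(length(tab$sites), n_tcr, replace = TRUE,
                       prob = tab$weight)
    damage <- c(damage, GenomicRanges::granges(tab$sites[pick]))
  }
  if (n_glob > 0L) {
    pick <- sample.int(length(tt_map), n_glob, replace = TRUE)
    damage <- c(damage, GenomicRanges::granges(tt_map[pick]))
  }

  frags <- simulate_excision_products(config, damage)
  reads <- trim_fragments(frags, xcfg$trim_range)
  S4Vectors::mcols(reads) <- NULL
  S4Vectors::mcols(reads)$mapq <- sample(xcfg$mapq_values, length(reads),
                                         replace = TRUE,
                                         prob = xcfg$mapq_probs)
  if (xcfg$duplicate_frac > 0 && length(reads) > 1L) {
    n_dup <- round(xcfg$duplicate_frac * length(reads))
    dup <- reads[sample.int(length(reads), n_dup, replace = TRUE)]
    reads <- c(reads, dup)
    attr(reads, "injected_duplicates") <- n_dup
  }
  reads <- GenomicRanges::sort(reads, ignore.strand = TRUE)
  read_set(reads,
           sample_id = sprintf("%s_XR_%s_rep%d", genotype, timepoint, replicate),
           genotype = genotype, assay = "XR",
           timepoint = timepoint, replicate = replicate)
}

granges_with_expression <- function(gr) {
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$expression <- S4Vectors::mcols(gr)$expression
  out
}

#' Simulate poly(A) RNA-seq gene counts for two strains
#'
#' Negative-binomial counts around shared per-gene means (expression x
#' depth), independently for a "WT" and an "xpc-1" strain, mimicking two
#' biologically equivalent libraries. Only poly(A) genes (biotype
#' `protein_coding`) receive counts; ncRNA loci are invisible to this assay.
#'
#' @param config a [sim_config()].
#' @param genes gene `GRanges`.
#' @param truth truth list (per-gene expression).
#' @param seed optional integer seed.
#'
#' @return `data.frame` with columns `gene_id`, `WT`, `xpc.1`.
#' @export
simulate_rnaseq <- function(config = sim_config(), genes, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rcfg <- config$rna
  polyA <- S4Vectors::mcols(genes)$biotype == "protein_coding"
  mu <- ifelse(polyA, truth$gene_expression * rcfg$depth, 0)
  size <- 1 / rcfg$dispersion
  draw <- function() {
    out <- integer(length(mu))
    out[mu > 0] <- stats::rnbinom(sum(mu > 0), mu = mu[mu > 0], size = size)
    out
  }
  data.frame(
    gene_id = S4Vectors::mcols(genes)$gene_id,
    WT = draw(),
    xpc.1 = draw(),
    stringsAsFactors = FALSE
  )
}

#' Simulate positioned RNA-seq reads (for bin-level analyses)
#'
#' Uniformly places stranded reads within poly(A) gene bodies,
#' with per-gene read numbers proportional to expression times length.
#' ncRNA and intergenic loci receive none, emulating the assay's
#' poly(A) restriction.
#'
#' @inheritParams simulate_rnaseq
#' @param strain label stored in the returned [read_set()].
#' @param n_reads total reads (default `config$rna$reads_per_sample`).
#' @return A [read_set()] with assay `"RNA"`.
#' @export
simulate_rna_reads <- function(config = sim_config(), genes, truth,
                               strain = "WT", n_reads = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rcfg <- config$rna
  if (is.null(n_reads)) n_reads <- rcfg$reads_per_sample
  polyA <- which(S4Vectors::mcols(genes)$biotype == "protein_coding")
  w <- truth$gene_expression[polyA] * GenomicRanges::width(genes)[polyA]
  n_rt <- stats::rbinom(1L, n_reads, rcfg$readthrough_frac)
  reads <- sample_reads_in(genes[polyA], n_reads - n_rt, w,
                           read_len = rcfg$read_length,
                           strand_mode = "locus")
  if (n_rt > 0L) {
    # 3' UTR read-through: a window just downstream of the TES
    rt_win <- GenomicRanges::trim(suppressWarnings(GenomicRanges::flank(
      genes[polyA], width = rcfg$readthrough_bp, start = FALSE)))
    rt <- sample_reads_in(rt_win, n_rt, w, read_len = rcfg$read_length,
                          strand_mode = "locus")
    reads <- GenomicRanges::sort(c(reads, rt), ignore.strand = TRUE)
  }
  read_set(reads, sample_id = paste0(strain, "_RNA"),
           genotype = strain, assay = "RNA")
}

# Sample `n` reads of length `read_len` uniformly within `loci`, locus chosen
# with prob `w`. strand_mode: "locus" = locus strand ("*" loci random strand),
# "both" = random strand. Reads are clipped to locus bounds when the locus is
# shorter than read_len.
sample_reads_in <- function(loci, n, w, read_len, strand_mode = "locus") {
  if (length(loci) == 0L || n == 0L)
    return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(loci)))
  li <- sample.int(length(loci), n, replace = TRUE, prob = w)
  lw <- GenomicRanges::width(loci)[li]
  rl <- pmin(read_len, lw)
  off <- floor(stats::runif(n) * (lw - rl + 1))
  start <- GenomicRanges::start(loci)[li] + as.integer(off)
  str <- as.character(GenomicRanges::strand(loci))[li]
  rand <- str == "*" | strand_mode == "both"
  str[rand] <- sample(c("+", "-"), sum(rand), replace = TRUE)
  GenomicRanges::sort(GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(loci)[li],
    ranges = IRanges::IRanges(start = start, width = rl),
    strand = str,
    seqinfo = GenomeInfoDb::seqinfo(loci)
  ), ignore.strand = TRUE)
}

#' Simulate short- and long-capped RNA-seq read sets
#'
#' Short-capped reads (transcription initiation, < 100 nt) are placed in a
#' window downstream of the TSS of expressed genes and across eRNA loci
#' (both strands for bidirectional eRNAs) — but never at piRNA loci,
#' which lack short-cap signal. Long-capped reads (nuclear RNAs > 200 nt)
#' cover gene bodies, lincRNA loci, and piRNA precursors, the latter as
#' exact 28-nt reads.
#'
#' @inheritParams simulate_xrseq
#' @param annotations ncRNA `GRanges` from [simulate_annotations()].
#' @return List with `shortcap` and `longcap` [read_set()]s.
#' @export
simulate_capped <- function(config = sim_config(), genome, genes,
                            annotations, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ccfg <- config$capped
  cls <- S4Vectors::mcols(truth$transcribed_intergenic)$class
  tx <- truth$transcribed_intergenic
  tx_expr <- S4Vectors::mcols(tx)$expression

  ## short-cap: TSS windows of genes + eRNA loci
  tss_win <- suppressWarnings(GenomicRanges::promoters(
    genes, upstream = 0, downstream = ccfg$short_tss_window))
  tss_win <- GenomicRanges::trim(tss_win)
  short_loci <- c(granges_with_expression_val(tss_win,
                                              truth$gene_expression),
                  granges_with_expression_val(tx[cls == "eRNA"],
                                              tx_expr[cls == "eRNA"]))
  short_len <- sample(ccfg$short_len_range[1]:ccfg$short_len_range[2],
                      1L)  # per-sample typical length
  short_reads <- sample_reads_in(
    short_loci, ccfg$short_reads,
    S4Vectors::mcols(short_loci)$expression, read_len = short_len
  )

  ## long-cap: gene bodies + lincRNA + piRNA precursors (28 nt)
  long_gene <- granges_with_expression_val(genes, truth$gene_expression)
  long_linc <- granges_with_expression_val(tx[cls == "lincRNA"],
                                           tx_expr[cls == "lincRNA"])
  long_pir <- granges_with_expression_val(tx[cls == "piRNA"],
                                          tx_expr[cls == "piRNA"])
  n_long <- ccfg$long_reads
  wts <- c(sum(S4Vectors::mcols(long_gene)$expression *
                 GenomicRanges::width(long_gene)),
           sum(S4Vectors::mcols(long_linc)$expression *
                 GenomicRanges::width(long_linc)),
           sum(S4Vectors::mcols(long_pir)$expression * 1000))
  alloc <- as.vector(stats::rmultinom(1, n_long, wts / sum(wts)))
  r_gene <- sample_reads_in(long_gene, alloc[1],
                            S4Vectors::mcols(long_gene)$expression *
                              GenomicRanges::width(long_gene),
                            read_len = ccfg$long_read_length)
  r_linc <- sample_reads_in(long_linc, alloc[2],
                            S4Vectors::mcols(long_linc)$expression *
                              GenomicRanges::width(long_linc),
                            read_len = ccfg$long_read_length)
  r_pir <- sample_reads_in(long_pir, alloc[3],
                           S4Vectors::mcols(long_pir)$expression,
                           read_len = ccfg$pirna_precursor_length)
  long_reads <- GenomicRanges::sort(c(r_gene, r_linc, r_pir),
                                    ignore.strand = TRUE)
  list(
    shortcap = read_set(short_reads, "WT_shortcap", "WT", "shortcap"),
    longcap = read_set(long_reads, "WT_longcap", "WT", "longcap")
  )
}

granges_with_expression_val <- function(gr, expr) {
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$expression <- expr
  out
}
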