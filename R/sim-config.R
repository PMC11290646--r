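#' Simulation configuration for the synthetic assay generator
#'
#' Builds the nested parameter list consumed by every `simulate_*()`
#' function. Defaults describe a compact worm-like genome (six chromosomes,
#' 0.6--0.9 Mb each, AT-rich base composition) with the assay structure the
#' pipeline expects: genotype-specific XR-seq strand behaviour (WT repairs by
#' both pathways, csb-1 by global repair only, xpc-1 by TCR only),
#' dual-incision excision geometry around TT dinucleotides (19 nt 5', 6 nt
#' 3', 27-nt products) with 3'-preserving trimming to 19--24-nt reads, a
#' 5'-to-3' TCR gradient that flattens over the six post-UV timepoints,
#' poly(A)-restricted RNA-seq versus capped RNA-seq that also covers
#' intergenic loci, piRNA loci confined to two cluster spans on one
#' chromosome, mostly-bidirectional eRNAs, and promoter/enhancer-enriched
#' epigenomic tracks.
#'
#' Any element can be overridden by passing a replacement (partial lists are
#' merged into the defaults).
#'
#' @param ... named overrides for top-level blocks `genome`, `genes`,
#'   `ncrna`, `blacklist`, `xr`, `rna`, `capped`, `tracks`, or `seed`.
#'
#' @return A list of class `"sim_config"`.
#'
#' @examples
#' cfg <- sim_config(genes = list(n = 40))
#' cfg$genes$n
#' @export
sim_config <- function(...) {
  defaults <- list(
    seed = 1L,
    genome = list(
      chrom_lengths = c(chrI = 800000, chrII = 700000, chrIII = 600000,
                        chrIV = 900000, chrV = 700000, chrX = 600000),
      base_probs = c(A = 0.33, C = 0.17, G = 0.17, T = 0.33)
    ),
    genes = list(
      n = 150,
      length_meanlog = log(3000), length_sdlog = 0.35,
      min_length = 2100,
      min_gap = 600,
      plus_strand_prob = 0.5,
      expr_meanlog = log(1), expr_sdlog = 0.8
    ),
    ncrna = list(
      pirna_chrom = "chrIV", pirna_cluster_span = c(0.25, 0.75),
      pirna_n = 300, pirna_width = 28,
      erna_n = 60, erna_width_range = c(150, 400),
      erna_bidirectional_frac = 0.9,
      lincrna_n = 15, lincrna_width_range = c(800, 2000),
      buffer = 2200   # bp kept clear of genes so ncRNA loci stay intergenic
    ),
    blacklist = list(n = 20, width_range = c(500, 2000)),
    xr = list(
      reads_per_sample = 100000,
      excision = list(five_prime_nt = 19L, three_prime_nt = 6L,
                      dimer_len = 2L, jitter = 2L),
      trim_range = c(19L, 24L),
      decay_bp = 1500,
      genotypes = list(
        "WT"    = list(tcr_weight = 0.6, global_weight = 0.4),
        "csb-1" = list(tcr_weight = 0,   global_weight = 1),
        "xpc-1" = list(tcr_weight = 1,   global_weight = 0)
      ),
      # multiplies decay_bp: the TSS-proximal skew flattens at later times
      timepoint_decay_multiplier = c("5min" = 1, "1h" = 1.5, "8h" = 3,
                                     "16h" = 5, "24h" = 8, "48h" = 12),
      mapq_values = c(0L, 10L, 20L, 25L, 30L, 42L),
      mapq_probs = c(0.02, 0.03, 0.03, 0.07, 0.15, 0.70),
      duplicate_frac = 0
    ),
    rna = list(
      depth = 40,          # mean counts per unit expression
      dispersion = 0.05,   # NB dispersion (size = 1/dispersion)
      reads_per_sample = 100000,
      read_length = 75L,
      readthrough_frac = 0.03,   # reads past the TES (3' UTR spillover)
      readthrough_bp = 400L
    ),
    capped = list(
      short_reads = 100000, short_len_range = c(25L, 80L),
      short_tss_window = 120L,
      long_reads = 100000, long_read_length = 80L,
      pirna_precursor_length = 28L
    ),
    tracks = list(
      window = 200L, noise_sd = 0.2, baseline = 1,
      promoter_fold = 6, enhancer_fold = 5, repressed_fold = 4,
      promoter_halfwidth = 300L,
      n_states = 20L,
      repressed_domain_n = 10L, repressed_domain_width = 20000L
    )
  )
  overrides <- list(...)
  if (length(overrides) && is.null(names(overrides)))
    stop("overrides must be named")
  cfg <- modify_defaults(defaults, overrides)
  class(cfg) <- c("sim_config", "list")
  cfg
}

# Recursive merge of named lists; non-list leaves are replaced wholesale.
# NULL overrides are kept as explicit NULL entries, not deletions.
modify_defaults <- function(defaults, overrides) {
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(overrides[[nm]])))
      defaults[[nm]] <- modify_defaults(defaults[[nm]], overrides[[nm]])
    else
      defaults[nm] <- list(overrides[[nm]])
  }
  defaults
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      length(x$genome$chrom_lengths), "chromosomes,",
      format(sum(x$genome$chrom_lengths), big.mark = ","), "bp;",
      x$genes$n, "genes;",
      x$ncrna$pirna_n, "piRNAs /", x$ncrna$erna_n, "eRNAs /",
      x$ncrna$lincrna_n, "lincRNAs\n")
  invisible(x)
}

#' Chromosome lengths of the ce11 reference assembly
#'
#' The `chrom.sizes` preset shipped with the package (chrI--chrV, chrX and
#' the mitochondrial chromosome), used for full-scale genome-tiling checks.
#'
#' @return Named integer vector of chromosome lengths in bp.
#' @examples
#' sum(ceiling(ce11_chrom_sizes() / 200))
#' @export
ce11_chrom_sizes <- function() {
  read_chrom_sizes(system.file("extdata", "ce11.chrom.sizes",
                               package = "xrtcr", mustWork = TRUE))
}
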