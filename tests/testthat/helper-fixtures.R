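# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Compact simulated study: small genome, annotations, TT map, one xpc-1
# XR sample. Deterministic (fixed seed) and reused across test files.
small_assets <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  set.seed(424242)
  cfg <- sim_config(
    genome = list(chrom_lengths = c(chrI = 150000, chrII = 120000,
                                    chrIV = 150000)),
    genes = list(n = 25),
    ncrna = list(pirna_chrom = "chrIV", pirna_n = 40, erna_n = 10,
                 lincrna_n = 3),
    blacklist = list(n = 5),
    xr = list(reads_per_sample = 20000),
    rna = list(reads_per_sample = 20000),
    capped = list(short_reads = 20000, long_reads = 20000)
  )
  gen <- simulate_genome(cfg)
  ann <- simulate_annotations(cfg, gen$genome)
  tt_map <- build_tt_map(gen$seq, gen$genome)
  xr <- suppressWarnings(simulate_xrseq(
    cfg, gen$genome, gen$seq, ann$genes, ann$truth,
    genotype = "xpc-1", timepoint = "1h", replicate = 1L, tt_map = tt_map
  ))
  .fixture_env$small <- list(cfg = cfg, genome = gen$genome, seq = gen$seq,
                             genes = ann$genes, annotations = ann$annotations,
                             blacklist = ann$blacklist, truth = ann$truth,
                             tt_map = tt_map, xr = xr)
  .fixture_env$small
}

# Plain-arithmetic brute-force oracle for bedtools-style counting, kept
# independent of the package's findOverlaps-based implementation: features
# and reads given as 0-based half-open data.frames.
brute_force_count <- function(features, reads, frac, rule) {
  counts <- integer(nrow(features))
  for (i in seq_len(nrow(features))) {
    n <- 0L
    for (j in seq_len(nrow(reads))) {
      if (features$chrom[i] != reads$chrom[j]) next
      ov <- min(features$end[i], reads$end[j]) -
        max(features$start[i], reads$start[j])
      if (ov <= 0) next
      rlen <- reads$end[j] - reads$start[j]
      if (ov / rlen < frac) next
      ok <- switch(rule,
        ignore = TRUE,
        same = features$strand[i] != "*" && reads$strand[j] != "*" &&
          features$strand[i] == reads$strand[j],
        opposite = features$strand[i] != "*" && reads$strand[j] != "*" &&
          features$strand[i] != reads$strand[j]
      )
      if (ok) n <- n + 1L
    }
    counts[i] <- n
  }
  counts
}

random_interval_df <- function(n, chroms = c("c1", "c2"), max_pos = 5000,
                               min_w = 5, max_w = 300) {
  chrom <- sample(chroms, n, replace = TRUE)
  w <- sample(min_w:max_w, n, replace = TRUE)
  start <- sapply(w, function(x) sample.int(max_pos - x, 1L)) - 1L
  data.frame(chrom = chrom, start = start, end = start + w,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

df_to_granges <- function(df) {
  stranded_intervals(df$chrom, df$start, df$end, df$strand)
}
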