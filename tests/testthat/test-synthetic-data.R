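test_that("simulated genomes follow the configured base composition", {
  cfg_a <- sim_config(genome = list(
    chrom_lengths = c(chr1 = 2000),
    base_probs = c(A = 1, C = 0, G = 0, T = 0)))
  gen_a <- simulate_genome(cfg_a, seed = 1)
  expect_equal(length(build_tt_map(gen_a$seq)[
    as.character(GenomicRanges::strand(build_tt_map(gen_a$seq))) == "+"]), 0L)

  cfg_t <- sim_config(genome = list(
    chrom_lengths = c(chr1 = 100),
    base_probs = c(A = 0, C = 0, G = 0, T = 1)))
  gen_t <- simulate_genome(cfg_t, seed = 1)
  tt <- build_tt_map(gen_t$seq)
  expect_equal(sum(as.character(GenomicRanges::strand(tt)) == "+"), 99L)

  # default composition: TT count within 3 sigma of the binomial expectation
  cfg <- sim_config(genome = list(chrom_lengths = c(chr1 = 100000)))
  gen <- simulate_genome(cfg, seed = 2)
  p_t <- 0.33
  n_tt <- sum(as.character(GenomicRanges::strand(
    build_tt_map(gen$seq))) == "+")
  expected <- p_t^2 * (100000 - 1)
  sigma <- sqrt((100000 - 1) * p_t^2 * (1 - p_t^2))
  expect_lt(abs(n_tt - expected), 3 * sigma)

  expect_error(simulate_genome(sim_config(
    genome = list(chrom_lengths = c(chr1 = 0)))), "zero-length")
})

test_that("annotation placement respects spacing, clusters and strandedness", {
  a <- small_assets()
  # pairwise gene gaps >= configured min_gap
  g <- GenomicRanges::sort(a$genes, ignore.strand = TRUE)
  for (chr in unique(as.character(GenomicRanges::seqnames(g)))) {
    gc <- g[as.character(GenomicRanges::seqnames(g)) == chr]
    if (length(gc) < 2) next
    gaps <- GenomicRanges::start(gc)[-1] - GenomicRanges::end(gc)[-length(gc)]
    expect_true(all(gaps >= a$cfg$genes$min_gap))
  }
  # every piRNA inside the designated cluster span on its chromosome
  pir <- a$annotations[S4Vectors::mcols(a$annotations)$class == "piRNA"]
  expect_true(all(as.character(GenomicRanges::seqnames(pir)) == "chrIV"))
  expect_true(all(IRanges::overlapsAny(pir, a$truth$pirna_cluster,
                                       type = "within")))
  # requesting more genes than fit fails with an achievable count
  expect_error(
    simulate_annotations(sim_config(
      genome = list(chrom_lengths = c(chr1 = 50000)),
      genes = list(n = 100)), genome_build("t", c(chr1 = 50000))),
    "achievable"
  )
})

test_that("eRNA bidirectional fraction matches its binomial expectation", {
  cfg <- sim_config(ncrna = list(pirna_n = 0, lincrna_n = 0, erna_n = 1000))
  set.seed(33)
  gen_build <- genome_build("t", cfg$genome$chrom_lengths)
  ann <- simulate_annotations(cfg, gen_build)
  erna <- ann$annotations[S4Vectors::mcols(ann$annotations)$class == "eRNA"]
  expect_length(erna, 1000L)
  frac <- mean(as.character(GenomicRanges::strand(erna)) == "*")
  ci <- 2.576 * sqrt(0.9 * 0.1 / 1000)
  expect_lt(abs(frac - 0.9), ci)
})

test_that("excision products obey the dual-incision geometry", {
  a <- small_assets()
  cfg0 <- sim_config(xr = list(excision = list(jitter = 0L)))

  # plus-strand dimer 0-based [100,102) -> fragment [81,108), 27 nt
  dimer <- stranded_intervals("chrI", 100, 102, "+", genome = a$genome)
  fr <- simulate_excision_products(cfg0, dimer)
  expect_equal(GenomicRanges::start(fr), 82L)   # 0-based 81
  expect_equal(GenomicRanges::end(fr), 108L)
  expect_equal(GenomicRanges::width(fr), 27L)

  # minus-strand dimer [100,102)- -> fragment [94,121)-
  dm <- stranded_intervals("chrI", 100, 102, "-", genome = a$genome)
  fm <- simulate_excision_products(cfg0, dm)
  expect_equal(GenomicRanges::start(fm), 95L)   # 0-based 94
  expect_equal(GenomicRanges::end(fm), 121L)
  expect_equal(GenomicRanges::width(fm), 27L)

  # with 5'-only jitter the length distribution is peaked at 27
  set.seed(5)
  sites <- a$tt_map[sample.int(length(a$tt_map), 10000)]
  frj <- simulate_excision_products(sim_config(), sites)
  tab <- table(GenomicRanges::width(frj))
  expect_equal(names(tab)[which.max(tab)], "27")
  expect_true(all(GenomicRanges::width(frj) >= 25 &
                    GenomicRanges::width(frj) <= 29))

  # events too close to the chromosome edge are dropped and counted
  edge <- stranded_intervals("chrI", 2, 4, "+", genome = a$genome)
  fe <- simulate_excision_products(cfg0, edge)
  expect_length(fe, 0L)
  expect_equal(attr(fe, "dropped"), 1L)
})

test_that("every XR read covers a template TT exactly 6 nt from its 3' end", {
  a <- small_assets()
  reads <- a$xr$reads
  expect_true(all(GenomicRanges::width(reads) >= 19 &
                    GenomicRanges::width(reads) <= 24))
  idx <- sample(length(reads), 2000)
  gr <- reads[idx]
  seqs <- vapply(seq_along(gr), function(i) {
    chr <- as.character(GenomicRanges::seqnames(gr))[i]
    s <- as.character(Biostrings::subseq(a$seq[[chr]],
                                         GenomicRanges::start(gr)[i],
                                         GenomicRanges::end(gr)[i]))
    if (as.character(GenomicRanges::strand(gr))[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  L <- nchar(seqs)
  dimer <- substring(seqs, L - 7, L - 6)   # 6-nt gap before the 3' end
  expect_true(all(dimer == "TT"))
})

test_that("genotype presets control the strand distribution of XR reads", {
  a <- small_assets()
  # xpc-1, zero background: all gene-overlapping reads on the template
  cnt <- ts_nts_counts(a$genes, a$xr)
  expect_true(sum(cnt$ts) > 0)
  expect_equal(sum(cnt$nts), 0L)

  # csb-1: strand-symmetric; aggregate TS fraction within binomial 99% CI
  csb <- suppressWarnings(simulate_xrseq(
    a$cfg, a$genome, a$seq, a$genes, a$truth,
    genotype = "csb-1", tt_map = a$tt_map, seed = 99))
  cc <- ts_nts_counts(a$genes, csb)
  tot <- sum(cc$ts + cc$nts)
  frac <- sum(cc$ts) / tot
  expect_lt(abs(frac - 0.5), 2.576 * sqrt(0.25 / tot))
})

test_that("fixing the seed fixes the simulated output", {
  cfg <- sim_config(genome = list(chrom_lengths = c(chr1 = 100000)),
                    genes = list(n = 5),
                    ncrna = list(pirna_chrom = "chr1", pirna_n = 5,
                                 erna_n = 2, lincrna_n = 1),
                    xr = list(reads_per_sample = 2000))
  run <- function() {
    gen <- simulate_genome(cfg, seed = 77)
    ann <- simulate_annotations(cfg, gen$genome)
    xr <- suppressWarnings(simulate_xrseq(cfg, gen$genome, gen$seq,
                                          ann$genes, ann$truth,
                                          tt_map = build_tt_map(gen$seq)))
    list(seq = as.character(gen$seq), genes = as.data.frame(ann$genes),
         reads = as.data.frame(xr$reads))
  }
  expect_identical(run(), run())
})

test_that("RNA-seq sees only poly(A) genes; capped RNA-seq sees ncRNA loci", {
  a <- small_assets()
  set.seed(8)
  counts <- simulate_rnaseq(a$cfg, a$genes, a$truth)
  expect_true(all(counts$WT >= 0))
  expect_gt(suppressWarnings(
    cor(counts$WT, counts$xpc.1, method = "spearman")), 0.9)

  capped <- simulate_capped(a$cfg, a$genome, a$genes, a$annotations, a$truth)
  tx <- a$truth$transcribed_intergenic
  cls <- S4Vectors::mcols(tx)$class
  pir <- tx[cls == "piRNA"]
  # piRNA loci: long-cap signal but no short-cap signal
  expect_equal(sum(GenomicRanges::countOverlaps(
    pir, capped$shortcap$reads, ignore.strand = TRUE)), 0L)
  expect_gt(sum(GenomicRanges::countOverlaps(
    pir, capped$longcap$reads, ignore.strand = TRUE)), 0L)
  # ncRNA loci get no RNA-seq reads placed inside the locus body
  rna <- simulate_rna_reads(a$cfg, a$genes, a$truth, "WT", seed = 3)
  linc <- tx[cls == "lincRNA"]
  expect_equal(sum(GenomicRanges::countOverlaps(
    linc, rna$reads, ignore.strand = TRUE, type = "any",
    minoverlap = 10L)), 0L)
})

test_that("planted intergenic loci with TT content receive TCR reads", {
  a <- small_assets()
  tx <- a$truth$transcribed_intergenic
  lstr <- as.character(GenomicRanges::strand(tx))
  has_tt <- vapply(seq_along(tx), function(i) {
    tm <- if (lstr[i] == "+") "-" else if (lstr[i] == "-") "+" else c("+", "-")
    sub <- a$tt_map[as.character(GenomicRanges::strand(a$tt_map)) %in% tm]
    any(IRanges::overlapsAny(sub, tx[i], type = "within"))
  }, logical(1))
  hits <- GenomicRanges::countOverlaps(tx, a$xr$reads, ignore.strand = TRUE)
  expect_true(all(hits[has_tt] >= 1L))
})
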