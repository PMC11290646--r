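test_that("duplicate collapse uses coordinates and strand only", {
  r <- stranded_intervals("chr1", c(0, 0, 0), c(24, 24, 24),
                          c("+", "+", "-"), mapq = c(30, 10, 30))
  d <- dedup(r)
  expect_length(d, 2L)
  expect_length(dedup(GenomicRanges::GRanges()), 0L)

  # survivor count equals the truth recorded by the duplicate injector
  set.seed(21)
  base <- df_to_granges(random_interval_df(1000, max_pos = 100000))
  base <- base[!duplicated(base)]
  n_dup <- 150L
  with_dups <- c(base, base[sample.int(length(base), n_dup, replace = FALSE)])
  expect_length(dedup(with_dups), length(base))
})

test_that("qc_filter applies dedup, mapq, chromosome and length in order", {
  gr <- stranded_intervals(
    chrom = c("chrI", "chrI", "chrI", "chrM", "chrI", "chrI", "chrI"),
    start = c(0, 0, 100, 200, 300, 400, 500),
    end = c(24, 24, 124, 224, 325, 419, 522),
    strand = "+",
    mapq = c(42, 42, 20, 42, 42, 42, 21)
  )
  # reads: dup pair (1 removed), mapq 20 (removed, strictly > 20 required),
  # chrM (removed), length 25 (removed), length 19 and 22 kept
  res <- qc_filter(gr, min_mapq = 20, allowed_chroms = c("chrI", "chrII"))
  expect_equal(res$report$n, c(7L, 6L, 5L, 4L, 3L))
  expect_equal(res$report$stage,
               c("total_mapped", "dedup", "mapq", "chrom", "qwidth"))
  w <- GenomicRanges::width(res$reads)
  expect_true(all(w >= 19 & w <= 24))

  # boundary: length 24 kept, mapq 21 kept
  expect_true(any(w == 22))

  # counts are monotone non-increasing for arbitrary inputs
  set.seed(3)
  rnd <- df_to_granges(random_interval_df(500, min_w = 15, max_w = 30))
  S4Vectors::mcols(rnd)$mapq <- sample(0:60, 500, replace = TRUE)
  rep2 <- qc_filter(rnd, allowed_chroms = "c1")$report
  expect_true(all(diff(rep2$n) <= 0))

  # missing mapq fails the filter with a warning
  nomapq <- stranded_intervals("chrI", 0, 24, "+")
  expect_warning(res3 <- qc_filter(nomapq), "mapq")
  expect_length(res3$reads, 0L)
})

test_that("TT map is strand-symmetric with the sequence complement", {
  seqs <- Biostrings::DNAStringSet(c(chrA = "TTTT", chrB = "TTAA"))
  tt <- build_tt_map(seqs)
  strand_chr <- paste(as.character(GenomicRanges::seqnames(tt)),
                      as.character(GenomicRanges::strand(tt)))
  expect_equal(sum(strand_chr == "chrA +"), 3L)
  expect_equal(sum(strand_chr == "chrA -"), 0L)
  expect_equal(sum(strand_chr == "chrB +"), 1L)
  expect_equal(sum(strand_chr == "chrB -"), 1L)

  # genome-scale symmetry: TT on minus == AA on plus, per chromosome
  a <- small_assets()
  for (chr in names(a$seq)) {
    sub <- a$tt_map[as.character(GenomicRanges::seqnames(a$tt_map)) == chr]
    n_minus <- sum(as.character(GenomicRanges::strand(sub)) == "-")
    n_aa <- length(Biostrings::matchPattern("AA", a$seq[[chr]]))
    expect_equal(n_minus, n_aa)
  }
})

test_that("positional dinucleotide profile anchors at the 3' end", {
  # read with the dimer 6 nt from its 3' end: CCCCC TT GAGCAG
  seqs <- Biostrings::DNAStringSet(c(chr1 = "CCCCCTTGAGCAG"))
  r <- stranded_intervals("chr1", 0, 13, "+")
  prof <- positional_dinuc_freq(r, seqs)
  tt_rows <- prof[prof$dinuc == "TT" & prof$stratum == "13", ]
  expect_equal(tt_rows$freq[tt_rows$position == 6], 1)
  expect_equal(sum(tt_rows$freq), 1)
  expect_equal(tt_peak_position(prof), 6L)

  # the same dimer on the minus strand is found after reverse-complement
  rc <- stranded_intervals("chr1", 0, 13, "-")
  seqs_rc <- Biostrings::DNAStringSet(
    c(chr1 = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("CCCCCTTGAGCAG")))))
  prof_rc <- positional_dinuc_freq(rc, seqs_rc)
  expect_equal(tt_peak_position(prof_rc), 6L)

  # all-A genome: TT frequency zero everywhere
  seqs_a <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 1000)))
  ra <- stranded_intervals("chr1", c(0, 50), c(24, 71), "+")
  prof_a <- positional_dinuc_freq(ra, seqs_a)
  expect_true(all(prof_a$freq[prof_a$dinuc == "TT"] == 0))

  # frequencies over the 16 dinucleotides sum to 1 at observed positions
  a <- small_assets()
  prof_x <- positional_dinuc_freq(a$xr, a$seq)
  sums <- tapply(prof_x$freq, list(prof_x$stratum, prof_x$position), sum)
  expect_true(all(abs(sums[!is.na(sums) & sums > 0] - 1) < 1e-9))

  # reads off the chromosome end are excluded and counted
  off <- stranded_intervals("chr1", c(0, 990), c(24, 1014), "+")
  prof_off <- positional_dinuc_freq(off, seqs_a)
  expect_equal(attr(prof_off, "excluded"), 1L)
})

test_that("TT counts track gene length on an i.i.d. genome", {
  set.seed(55)
  cfg <- sim_config(genome = list(chrom_lengths = c(chr1 = 2000000)),
                    genes = list(n = 220, length_sdlog = 0.6),
                    ncrna = list(pirna_chrom = "chr1", pirna_n = 0,
                                 erna_n = 0, lincrna_n = 0))
  gen <- simulate_genome(cfg)
  ann <- simulate_annotations(cfg, gen$genome)
  tt <- tt_vs_length(ann$genes, build_tt_map(gen$seq, gen$genome))
  expect_gt(cor(tt$tt_ts + tt$tt_nts, tt$length), 0.95)
  expect_gt(attr(tt, "cor_ts_nts_log"), 0.9)
})

test_that("TT metagene uses the same 100-bin layout as repair profiles", {
  a <- small_assets()
  sel <- select_profile_genes(a$genes)
  mg <- tt_metagene(sel, a$tt_map)
  expect_equal(nrow(mg), 200L)
  expect_equal(sort(unique(mg$bin)), 1:100)
  expect_true(all(mg$mean_tt >= 0))
})
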