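test_that("profile-gene selection enforces length and separation", {
  g <- stranded_intervals("chr1", c(0, 3100, 6300), c(3000, 6200, 7000),
                          c("+", "-", "+"))
  expect_length(select_profile_genes(g), 0L)

  # strictly longer than 2 kb: a lone 2,001-bp gene passes
  lone <- stranded_intervals("chr1", 0, 2001, "+")
  expect_length(select_profile_genes(lone), 1L)
  lone2 <- stranded_intervals("chr1", 0, 2000, "+")
  expect_length(select_profile_genes(lone2), 0L)

  # exact 500-bp gap passes, 499 fails
  pair <- stranded_intervals("chr1", c(0, 2600), c(2100, 4800), "+")
  expect_length(select_profile_genes(pair), 2L)
  pair2 <- stranded_intervals("chr1", c(0, 2599), c(2100, 4800), "+")
  expect_length(select_profile_genes(pair2), 0L)

  # generator-guaranteed spacing and length keep every gene
  a <- small_assets()
  long_enough <- a$genes[GenomicRanges::width(a$genes) > 2000]
  expect_length(select_profile_genes(a$genes), length(long_enough))
})

test_that("gene QC combines the TT OR-rule with total read support", {
  gb <- genome_build("t", c(chr1 = 100000))
  # gene A: few TS TTs, many NTS TTs -> passes TT rule
  seq <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("G", 1000),
    strrep("TTG", 40),    # 40 TT on + in [1000,1120)
    strrep("G", 880),
    strrep("C", 98000))))
  tt <- build_tt_map(seq, gb)
  genes <- stranded_intervals("chr1", c(1000, 50000), c(2000, 51000),
                              c("-", "+"), genome = gb,
                              gene_id = c("gA", "gB"))
  # gA is minus-strand: TT on + is template (TS); gB has no TTs at all
  reads <- stranded_intervals("chr1", rep(c(1100, 50100), c(12, 12)),
                              rep(c(1124, 50124), c(12, 12)), "+",
                              genome = gb)
  kept <- gene_qc(genes, tt, list(reads), min_tt = 10, min_reads = 10)
  expect_equal(S4Vectors::mcols(kept)$gene_id, "gA")

  # read support below threshold drops a TT-rich gene
  few <- reads[1:9]
  expect_length(gene_qc(genes[1], tt, list(few)), 0L)

  # random toy table against a hand-computed filter
  set.seed(9)
  a <- small_assets()
  sub <- a$genes[1:20]
  ttdf <- tt_vs_length(sub, a$tt_map)
  total <- intersect_count(sub, a$xr, 0.5, "ignore")
  manual <- (ttdf$tt_ts >= 10 | ttdf$tt_nts >= 10) & total >= 10
  expect_equal(
    S4Vectors::mcols(gene_qc(sub, a$tt_map, list(a$xr)))$gene_id,
    S4Vectors::mcols(sub)$gene_id[manual]
  )
})

test_that("TS/NTS counting is template-strand counting", {
  gene <- stranded_intervals("chr1", 0, 1000, "+")
  reads <- stranded_intervals("chr1", c(100, 200, 300, 400),
                              c(124, 224, 324, 424),
                              c("-", "-", "-", "+"))
  cnt <- ts_nts_counts(gene, reads)
  expect_equal(cnt$ts, 3L)
  expect_equal(cnt$nts, 1L)

  # TS of a minus-strand gene is the plus strand
  gm <- stranded_intervals("chr1", 0, 1000, "-")
  rm <- stranded_intervals("chr1", c(10, 50), c(34, 74), "-")
  cm <- ts_nts_counts(gm, rm)
  expect_equal(cm$ts, 0L)
  expect_equal(cm$nts, 2L)

  # unstranded reads are an error
  ru <- stranded_intervals("chr1", 10, 34, "*")
  expect_error(ts_nts_counts(gene, ru), "unstranded")

  # random instance equals the brute-force oracle
  set.seed(13)
  fdf <- random_interval_df(30, min_w = 500, max_w = 2000, max_pos = 20000)
  rdf <- random_interval_df(500, min_w = 19, max_w = 24, max_pos = 20000)
  cnt2 <- ts_nts_counts(df_to_granges(fdf), df_to_granges(rdf))
  expect_equal(cnt2$ts, brute_force_count(fdf, rdf, 0.5, "opposite"))
  expect_equal(cnt2$nts, brute_force_count(fdf, rdf, 0.5, "same"))
})

test_that("RPKM and TS fraction behave as defined", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(ts_fraction(78, 22), 0.78)
  expect_true(is.na(ts_fraction(0, 0)))
  expect_equal(ts_fraction(0, 5), 0)

  # RPKM invariant under duplicating the library
  expect_equal(rpkm(7, 1500, 2e6), rpkm(14, 1500, 4e6))

  # xpc-1 zero-background: ts_fraction 1 for every gene with reads
  a <- small_assets()
  s <- repair_strand_summary(a$genes, a$xr)
  covered <- s$ts_count + s$nts_count > 0
  expect_true(all(s$ts_fraction[covered] == 1))
  expect_equal(attr(s, "n_undefined"), sum(!covered))
})

test_that("metagene profiles have 100 bins and reflect the repair gradient", {
  a <- small_assets()
  sel <- select_profile_genes(a$genes)
  mg_ts <- metagene_profile(sel, a$xr, "TS")
  mg_nts <- metagene_profile(sel, a$xr, "NTS")
  expect_equal(ncol(mg_ts$matrix), 100L)
  expect_length(mg_ts$mean, 100L)
  expect_true(all(is.finite(mg_ts$mean)))

  # xpc-1: TS signal dwarfs NTS, and the TS gene-body profile decays 5'->3'
  expect_gt(sum(mg_ts$mean), 10 * sum(mg_nts$mean))
  body_bins <- 20:50   # downstream of the TSS within the first window
  rho <- cor(body_bins, mg_ts$mean[body_bins], method = "spearman")
  expect_lt(rho, 0)

  # strand-symmetric global repair: TS and NTS profiles indistinguishable
  csb <- suppressWarnings(simulate_xrseq(
    a$cfg, a$genome, a$seq, a$genes, a$truth,
    genotype = "csb-1", tt_map = a$tt_map, seed = 4))
  g_ts <- metagene_profile(sel, csb, "TS")
  g_nts <- metagene_profile(sel, csb, "NTS")
  tot_ts <- sum(g_ts$mean); tot_nts <- sum(g_nts$mean)
  expect_lt(abs(tot_ts - tot_nts) / (tot_ts + tot_nts), 0.05)
})

test_that("TSS heatmaps enforce separation and rank rows by signal", {
  # closer than min_sep: keep the first by coordinate
  tss <- stranded_intervals("chr1", c(100, 900), c(101, 901), "+")
  hm <- tss_heatmap(tss, stranded_intervals("chr1", 0, 24, "+"),
                    library_size = 1000)
  expect_length(hm$tss, 1L)
  expect_equal(GenomicRanges::start(hm$tss), 101L)

  # all-zero reads: all-zero matrices, stable ordering
  tss2 <- stranded_intervals("chr1", c(2000, 5000, 9000),
                             c(2001, 5001, 9001), c("+", "-", "+"))
  none <- stranded_intervals("chr1", 0, 24, "+")[0]
  hm2 <- tss_heatmap(tss2, none, library_size = 1)
  expect_true(all(hm2$ts == 0) && all(hm2$nts == 0))
  expect_equal(hm2$order, 1:3)
  expect_equal(dim(hm2$ts), c(3L, 20L))
  expect_equal(hm2$best_half, 1L)

  # planted antisense signal upstream of a subset of TSSs shows as
  # NTS > TS in those rows while the cohort mean stays TS-dominated
  a <- small_assets()
  plus_genes <- a$genes[as.character(GenomicRanges::strand(a$genes)) == "+"]
  tss3 <- GenomicRanges::resize(plus_genes, 1L, fix = "start")
  anti_idx <- seq_len(max(1L, length(tss3) %/% 5))
  # antisense = same strand as the gene, upstream of the TSS
  anti <- do.call(c, lapply(anti_idx, function(i) {
    p <- GenomicRanges::start(tss3)[i]
    GenomicRanges::GRanges(GenomicRanges::seqnames(tss3)[i],
                           IRanges::IRanges(start = p - 300 + (0:49) * 2,
                                            width = 24),
                           strand = "+")
  }))
  combined <- c(GenomicRanges::granges(a$xr$reads), anti)
  hm3 <- tss_heatmap(tss3, combined, library_size = length(combined))
  up_cols <- 1:10
  row_of <- match(anti_idx, hm3$order)
  planted_excess <- rowSums(hm3$nts[row_of, up_cols, drop = FALSE]) -
    rowSums(hm3$ts[row_of, up_cols, drop = FALSE])
  expect_true(all(planted_excess > 0))
  cohort <- colMeans(hm3$nts[, up_cols]) - colMeans(hm3$ts[, up_cols])
  expect_lt(mean(cohort), mean(planted_excess) / 2)
})
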