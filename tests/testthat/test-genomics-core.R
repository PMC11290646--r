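test_that("genome tiling partitions chromosomes with terminal partial bins", {
  gb <- genome_build("toy", c(chr1 = 1000))
  expect_length(tile_genome(gb, 200), 5L)

  gb2 <- genome_build("toy2", c(chr1 = 13794))
  bins <- tile_genome(gb2, 200)
  expect_length(bins, 69L)  # ceiling(13794 / 200)
  last <- bins[length(bins)]
  expect_equal(GenomicRanges::start(last), 13601L)  # 0-based 13600
  expect_equal(GenomicRanges::end(last), 13794L)

  # partition property on a multi-chromosome genome
  gb3 <- genome_build("toy3", c(a = 1234, b = 999, c = 200))
  b3 <- tile_genome(gb3, 250)
  expect_length(b3, ceiling(1234 / 250) + ceiling(999 / 250) + 1L)
  per_chr <- tapply(GenomicRanges::width(b3),
                    as.character(GenomicRanges::seqnames(b3)), sum)
  expect_equal(per_chr[c("a", "b", "c")],
               c(a = 1234, b = 999, c = 200), ignore_attr = TRUE)
  expect_false(any(GenomicRanges::countOverlaps(b3, b3) > 1L))

  expect_error(tile_genome(gb, 0), "width")
  expect_error(genome_build("bad", numeric(0)), "empty")
  expect_error(genome_build("bad", c(a = 0)), "positive")
})

test_that("intersect_count follows bedtools -c -F frac -s/-S semantics", {
  f <- stranded_intervals("chr1", 0, 1000, "+")
  r <- stranded_intervals("chr1", 100, 124, "+")
  expect_equal(intersect_count(f, r, 0.5, "same"), 1L)
  expect_equal(intersect_count(f, r, 0.5, "opposite"), 0L)

  # boundary arithmetic: 10 of 22 nt inside = 0.4545
  f2 <- stranded_intervals("chr1", 0, 100, "+")
  r2 <- stranded_intervals("chr1", 90, 112, "+")
  expect_equal(intersect_count(f2, r2, 0.5, "same"), 0L)
  expect_equal(intersect_count(f2, r2, 0.45, "same"), 1L)
  # ties at the threshold count (>=)
  r3 <- stranded_intervals("chr1", 90, 110, "+")  # 10 of 20
  expect_equal(intersect_count(f2, r3, 0.5, "same"), 1L)

  # a read overlapping two features counts in both
  ff <- stranded_intervals("chr1", c(0, 95), c(100, 200), "+")
  expect_equal(intersect_count(ff, r3, 0.5, "same"), c(1L, 1L))

  # reads on unknown chromosomes warn and contribute nothing
  r4 <- stranded_intervals(c("chr1", "chrZ"), c(0, 0), c(24, 24), "+")
  expect_warning(cnt <- intersect_count(f2, r4, 0.5, "same"), "absent")
  expect_equal(cnt, 1L)
})

test_that("intersect_count equals an all-pairs brute-force oracle", {
  set.seed(101)
  for (case in 1:4) {
    frac <- sample(c(0.3, 0.5, 0.9, 1), 1)
    rule <- sample(c("same", "opposite", "ignore"), 1)
    fdf <- random_interval_df(50, min_w = 50, max_w = 800)
    rdf <- random_interval_df(200, min_w = 10, max_w = 40)
    expect_equal(
      intersect_count(df_to_granges(fdf), df_to_granges(rdf), frac, rule),
      brute_force_count(fdf, rdf, frac, rule),
      info = sprintf("case %d frac=%g rule=%s", case, frac, rule)
    )
  }
})

test_that("interval algebra: subtract, merge, upstream extension", {
  # minus-strand upstream extension is rightward
  gene <- stranded_intervals("chr1", 5000, 6000, "-")
  ext <- extend_upstream(gene, 2000)
  expect_equal(GenomicRanges::start(ext), 5001L)  # 0-based 5000
  expect_equal(GenomicRanges::end(ext), 8000L)    # 0-based exclusive 8000

  m <- merge_intervals(stranded_intervals("chr1", c(0, 5), c(10, 20)))
  expect_length(m, 1L)
  expect_equal(GenomicRanges::width(m), 20L)

  # 10 toy bins, feature spanning bins 3-5 -> 7 bins remain
  bins <- tile_genome(genome_build("t", c(chr1 = 2000)), 200)
  feat <- stranded_intervals("chr1", 450, 950)
  expect_length(subtract_overlapping(bins, feat), 7L)

  # merge is idempotent and results are disjoint and sorted
  set.seed(7)
  x <- df_to_granges(random_interval_df(100))
  m1 <- merge_intervals(x)
  expect_identical(merge_intervals(m1), m1)
  expect_false(any(GenomicRanges::countOverlaps(m1, m1) > 1L))
  expect_false(is.unsorted(GenomicRanges::start(m1)[
    as.character(GenomicRanges::seqnames(m1)) == "c1"]))

  # clipping at chromosome start
  gb <- genome_build("t", c(chr1 = 10000))
  g2 <- stranded_intervals("chr1", 500, 1500, "+", genome = gb)
  e2 <- extend_upstream(g2, 2000)
  expect_equal(GenomicRanges::start(e2), 1L)
})

test_that("format readers and writers round-trip and convert coordinates", {
  gb <- genome_build("toy", c(chrI = 100000))
  tmp <- withr::local_tempfile(fileext = ".bed")

  # BED line chrI 100 124 + -> 0-based [100,124)+ -> 1-based 101..124
  writeLines("chrI\t100\t124\tr1\t0\t+", tmp)
  gr <- read_bed(tmp, genome = gb)
  expect_equal(GenomicRanges::start(gr), 101L)
  expect_equal(GenomicRanges::end(gr), 124L)
  expect_equal(as.character(GenomicRanges::strand(gr)), "+")

  # GFF 101..124 is the same interval
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrI\tsrc\tgene\t101\t124\t.\t+\t.\tID=g1"), gff)
  gg <- read_gff_subset(gff, types = "gene", genome = gb)
  expect_equal(GenomicRanges::start(gg), 101L)
  expect_equal(GenomicRanges::end(gg), 124L)

  # write -> read identity for many random records
  set.seed(11)
  orig <- df_to_granges(random_interval_df(1000, chroms = "chrI"))
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(orig, out)
  back <- read_bed(out)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(orig))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(orig))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(orig)))

  # chrom.sizes and unknown-chromosome validation
  cs <- withr::local_tempfile()
  writeLines(c("chrI\t100000", "chrII\t50000"), cs)
  expect_equal(read_chrom_sizes(cs), c(chrI = 100000L, chrII = 50000L))
  writeLines("chrZ\t10\t20\tx\t0\t+", tmp)
  expect_error(read_bed(tmp, genome = gb), "chrZ")
})

test_that("stranded interval construction enforces the coordinate contract", {
  gb <- genome_build("toy", c(chrI = 1000))
  expect_error(stranded_intervals("chrI", 10, 10), "start < end")
  expect_error(stranded_intervals("chrI", -1, 10), "start < end|0 <=")
  expect_error(stranded_intervals("chrI", 10, 2000, genome = gb), "beyond")
  expect_error(stranded_intervals("chrQ", 0, 10, genome = gb), "unknown")
  ok <- stranded_intervals("chrI", 0, 1000, "+", genome = gb)
  expect_equal(GenomicRanges::width(ok), 1000L)
})
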