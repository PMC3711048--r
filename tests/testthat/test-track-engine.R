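test_that("BED and SAM readers enforce their formats and conventions", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrI\t100\t149\tr1\t0\t+", bed)
  rd <- read_alignments(bed, "BED")
  expect_equal(rd, data.frame(chrom = "chrI", start = 100L, end = 149L,
                              strand = "+"), ignore_attr = TRUE)

  writeLines("chrI\t200\t150\tr1\t0\t+", bed)
  expect_error(read_alignments(bed, "BED"), "line 1")
  writeLines(c("chrI\t0\t49\tr1\t0\t+", "chrI\tx\t49\tr2\t0\t+"), bed)
  expect_error(read_alignments(bed, "BED"), "line 2")

  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:chrI\tLN:1000",
               "r1\t0\tchrI\t101\t60\t49M\t*\t0\t0\t*\t*",
               "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
               "r3\t16\tchrI\t301\t60\t49M\t*\t0\t0\t*\t*"), sam)
  expect_message(rd <- read_alignments(sam, "SAM"), "skipped 1 unmapped")
  expect_equal(attr(rd, "skipped"), 1L)
  expect_equal(rd$start, c(100L, 300L))  # 1-based POS converted
  expect_equal(rd$end, c(149L, 349L))
  expect_equal(rd$strand, c("+", "-"))

  writeLines(c("r1\t0\tchrI\t101\t60\t49M\t*\t0\t0\t*\t*"), sam)
  expect_error(read_alignments(sam, "SAM"), "@SQ")
})

test_that("SAM writer round-trips through the reader", {
  rd <- random_reads(50, 5000, seed = 3)
  sizes <- c(chrT = 5000)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_reads_sam(rd, sizes, sam)
  back <- read_alignments(sam, "SAM")
  expect_equal(back[, c("chrom", "start", "end", "strand")],
               rd[, c("chrom", "start", "end", "strand")],
               ignore_attr = TRUE)
})

test_that("pileup counts bases exactly", {
  reads <- data.frame(chrom = "chrT", start = c(0L, 3L), end = c(5L, 8L),
                      strand = "+")
  tr <- pileup(reads, c(chrT = 10))
  expect_equal(tr$values$chrT, c(1, 1, 1, 2, 2, 1, 1, 1, 0, 0))
  expect_equal(tr$library_size, 2)
  # conservation: sum equals the sum of read spans
  expect_equal(sum(tr$values$chrT), sum(reads$end - reads$start))
  expect_error(pileup(data.frame(chrom = "chrT", start = 5L, end = 20L,
                                 strand = "+"), c(chrT = 10)), "bounds")
})

test_that("pileup matches brute-force per-base counting, with and without extension", {
  for (i in 1:20) {
    set.seed(100 + i)
    len <- sample(500:2000, 1)
    reads <- random_reads(sample(50:300, 1), len, read_len = sample(20:50, 1),
                          seed = 200 + i)
    tr <- pileup(reads, c(chrT = len))
    expect_identical(tr$values$chrT, brute_force_pileup(reads, c(chrT = len))$chrT)
    tre <- pileup(reads, c(chrT = len), extend_to = 100)
    expect_identical(tre$values$chrT,
                     brute_force_pileup(reads, c(chrT = len), extend_to = 100)$chrT)
  }
})

test_that("per-million normalization scales once and only once", {
  tr <- flat_track(rep(3, 10), library_size = 1e6)
  expect_equal(normalize_fpm(tr)$values$chrT, rep(3, 10))
  tr2 <- flat_track(rep(3, 10), library_size = 2e6)
  expect_equal(normalize_fpm(tr2)$values$chrT, rep(1.5, 10))
  expect_error(normalize_fpm(normalize_fpm(tr)), "already")
  expect_error(normalize_fpm(flat_track(rep(1, 5), library_size = 0)), "library_size")
})

test_that("log2 ratio is zero on equality, antisymmetric, and scale invariant", {
  a <- normalize_fpm(flat_track(c(0, 1, 3, 5, 2), 1e6))
  b <- normalize_fpm(flat_track(c(0, 2, 1, 5, 7), 1e6))
  expect_equal(log2_ratio(a, a)$values$chrT, rep(0, 5))
  expect_equal(log2_ratio(a, b, 1)$values$chrT, -log2_ratio(b, a, 1)$values$chrT)
  expect_equal(log2_ratio(normalize_fpm(flat_track(3, 1e6)),
                          normalize_fpm(flat_track(1, 1e6)), 1)$values$chrT, 1.0)
  # doubling both raw libraries leaves the per-million ratio unchanged
  a2 <- normalize_fpm(flat_track(2 * c(0, 1, 3, 5, 2), 2e6))
  b2 <- normalize_fpm(flat_track(2 * c(0, 2, 1, 5, 7), 2e6))
  expect_equal(log2_ratio(a2, b2, 0.5)$values$chrT,
               log2_ratio(a, b, 0.5)$values$chrT)
  short <- normalize_fpm(flat_track(c(1, 2), 1e6))
  expect_error(log2_ratio(a, short), "lengths differ")
})

test_that("binning averages partial bins over their true width", {
  tr <- flat_track(c(1, 2, 3, 4), 10)
  b <- bin_track(tr, 2, "mean")
  expect_equal(b$value, c(1.5, 3.5))
  expect_equal(b$start, c(0, 2))
  const <- flat_track(rep(2, 7), 10)
  expect_true(all(bin_track(const, 3, "mean")$value == 2))
  tot <- bin_track(tr, 4, "sum")
  expect_equal(tot$value, 10)
  expect_error(bin_track(tr, 0), "width")
})

test_that("bedGraph writes merged runs and round-trips exactly", {
  tr <- flat_track(c(0, 0, 2, 2, 1), 5, chrom = "chr")
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  expect_equal(readLines(f), c("chr\t2\t4\t2", "chr\t4\t5\t1"))

  # round trip is the identity on random integer tracks
  for (i in 1:10) {
    set.seed(300 + i)
    v <- as.numeric(rpois(sample(50:500, 1), 2))
    t0 <- flat_track(v, 100)
    write_bedgraph(t0, f)
    back <- read_bedgraph(f, c(chrT = length(v)), library_size = 100)
    expect_identical(back$values$chrT, v)
  }

  # fractional values round-trip within 1e-9
  vf <- c(0.125, 0.125, 3.5, 1e-4, 0)
  write_bedgraph(flat_track(vf, 10), f)
  expect_equal(read_bedgraph(f, c(chrT = 5))$values$chrT, vf, tolerance = 1e-9)

  # empty track: valid empty data section
  write_bedgraph(flat_track(numeric(10), 1), f)
  expect_equal(length(readLines(f)), 0)
  expect_equal(read_bedgraph(f, c(chrT = 10))$values$chrT, numeric(10))

  writeLines(c("chrT\t0\t5\t1", "chrT\t3\t8\t2"), f)
  expect_error(read_bedgraph(f, c(chrT = 10)), "overlap")
})
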