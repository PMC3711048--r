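test_that("fragments are assigned by read midpoint, half-open", {
  genes <- data.frame(id = c("g1", "g2"), chrom = "chrT",
                      start = c(0L, 300L), end = c(200L, 500L), strand = "+")
  # read [100,149): midpoint 124 lies in g1
  reads <- data.frame(chrom = "chrT", start = 100L, end = 149L, strand = "+")
  expect_equal(count_fragments(reads, genes), c(g1 = 1L, g2 = 0L))
  # midpoint exactly at the gene end coordinate is not counted
  reads2 <- data.frame(chrom = "chrT", start = 176L, end = 225L, strand = "+")
  expect_equal((reads2$start + reads2$end - 1L) %/% 2L, 200L)
  expect_equal(count_fragments(reads2, genes), c(g1 = 0L, g2 = 0L))
  expect_error(count_fragments(reads, data.frame(id = c("a", "b"), chrom = "chrT",
                                                 start = c(0L, 100L),
                                                 end = c(200L, 300L), strand = "+")),
               "overlap")
})

test_that("fragment counts match brute-force midpoint membership", {
  set.seed(42)
  genes <- data.frame(id = sprintf("g%d", 1:10), chrom = "chrT",
                      start = seq(0L, 9000L, by = 1000L),
                      end = seq(0L, 9000L, by = 1000L) + sample(400:900, 10),
                      strand = "+")
  for (i in 1:5) {
    reads <- random_reads(500, 10000, seed = 400 + i)
    mid <- (reads$start + reads$end - 1L) %/% 2L
    brute <- vapply(seq_len(nrow(genes)), function(g)
      sum(mid >= genes$start[g] & mid < genes$end[g]), integer(1))
    expect_equal(unname(count_fragments(reads, genes)), brute)
  }
})

test_that("FPKM follows its definition and scaling law", {
  expect_equal(fpkm(10, 1000, 1e6), 10.0)
  expect_equal(fpkm(0, 1000, 1e6), 0.0)
  expect_equal(fpkm(c(5, 10), c(500, 2000), 2e6), fpkm(c(5, 10), c(500, 2000), 1e6) / 2)
  expect_error(fpkm(1, 0, 1e6), "lengths")
  expect_error(fpkm(1, 1000, 0), "library_size")
})

test_that("fold-change flags use strict inequalities at the cutoffs", {
  cfg <- threshold_config()
  fc <- c(0.79, 0.80, 1.0, 2.0, 2.5, 0.4)
  rec <- classify(data.frame(fold_change_h3 = fc, fold_change_polII = fc), cfg)
  expect_equal(rec$h3_loss, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(rec$polII_change, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  # idempotent and a function of fold_change and cfg only
  expect_equal(classify(rec, cfg), rec)
  expect_error(threshold_config(loss_cutoff = 1.2), "loss_cutoff")
})

test_that("expression stratification splits quartiles with stable ties", {
  expect_equal(as.character(stratify_expression(c(8, 7, 6, 5, 4, 3, 2, 1))),
               c("Very high", "Very high", "High", "High",
                 "Medium", "Medium", "Low", "Low"))
  ties <- stratify_expression(rep(2, 8))
  expect_equal(as.vector(table(ties)), rep(2L, 4))
  expect_equal(as.character(ties[1:2]), c("Very high", "Very high"))
  expect_error(stratify_expression(c(1, 2, 3)), ">= 4")
})

test_that("gene table writes a fixed header and round-trips", {
  genes <- data.frame(id = c("g1", "g2", "g3", "g4"), chrom = "chrT",
                      start = c(0L, 1000L, 2000L, 3000L),
                      end = c(800L, 1900L, 2700L, 3900L),
                      strand = c("+", "-", "+", "-"))
  wt <- random_reads(2000, 5000, seed = 7)
  mut <- random_reads(1500, 5000, seed = 8)
  pol <- random_reads(1000, 5000, seed = 9)
  rec <- gene_occupancy(genes, wt, mut, reads_pol_wt = pol)
  expect_equal(rec$fpkm_h3_wt,
               rec$frag_h3_wt * 1e9 / (rec$length * nrow(wt)))
  expect_s3_class(rec$class, "factor")

  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(rec, f)
  back <- read_gene_table(f)
  expect_equal(back$gene, rec$gene)
  expect_equal(back$fold_change_h3, signif(rec$fold_change_h3, 6))
  expect_equal(nchar(readLines(f)[1]) > 0, TRUE)

  write_gene_table(rec[0, ], f)
  expect_equal(length(readLines(f)), 1)  # header only
})

test_that("GFF3 annotations round-trip through the 1-based boundary", {
  genes <- data.frame(id = c("gA", "gB"), chrom = c("chrI", "chrI"),
                      start = c(100L, 1000L), end = c(700L, 1600L),
                      strand = c("+", "-"))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3_genes(genes, f)
  back <- read_gff3_genes(f, sizes = c(chrI = 2000))
  expect_equal(back[, c("id", "chrom", "start", "end", "strand")], genes,
               ignore_attr = TRUE)
  expect_error(read_gff3_genes(f, sizes = c(chrI = 1500)), "outside")
})

test_that("H3 fold change anti-correlates with Pol II occupancy in the mutant", {
  rhos <- vapply(1:5, function(s) {
    model <- build_genome(40, seed = 1)
    cfg <- sim_config(n_reads = 3e4, seed = 500 + s)
    wt <- simulate_turnover(model, genotype("WT"), cfg)
    mut <- simulate_turnover(model, genotype("spt6d"), cfg)
    rec <- gene_occupancy(model_genes(model),
                          sample_chip_reads(wt, "H3", cfg),
                          sample_chip_reads(mut, "H3", cfg),
                          reads_pol_wt = sample_chip_reads(wt, "PolII", cfg))
    cor(rec$fpkm_pol_wt, rec$fold_change_h3, method = "spearman")
  }, numeric(1))
  expect_lt(median(rhos), -0.5)
})
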