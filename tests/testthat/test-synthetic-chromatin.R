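test_that("build_genome lays out strata, heterochromatin and is deterministic", {
  m <- build_genome(n_genes = 4, strata_rates = c(8, 4, 2, 0.5), het_domains = 1)
  genes <- m$domains[m$domains$kind == "euchromatic-gene", ]
  expect_equal(nrow(genes), 4)
  expect_equal(as.vector(table(genes$stratum)[c("Very high", "High", "Medium", "Low")]),
               rep(1L, 4))
  expect_equal(sum(m$domains$kind == "heterochromatin"), 1)
  # strands alternate and genes do not overlap
  expect_equal(genes$strand, c("+", "-", "+", "-"))
  expect_true(all(genes$start[-1] >= genes$end[-nrow(genes)]))

  expect_error(build_genome(0), "n_genes")
  expect_error(build_genome(6), "n_genes")
  expect_error(build_genome(8, strata_rates = c(1, 2, 3, 4)), "decreasing")

  expect_identical(build_genome(40, seed = 11), build_genome(40, seed = 11))
  expect_false(identical(build_genome(40, seed = 11), build_genome(40, seed = 12)))
})

test_that("genome_model enforces its invariants", {
  expect_error(genome_model(data.frame(name = "c", length = 0),
                            data.frame(id = "g", chrom = "c", start = 0, end = 1,
                                       kind = "euchromatic-gene", strand = "+",
                                       passage_rate = 1)),
               "length")
  base <- data.frame(id = c("a", "b"), chrom = "c", start = c(0, 500),
                     end = c(600, 900), kind = "euchromatic-gene",
                     strand = "+", passage_rate = 1)
  expect_error(genome_model(data.frame(name = "c", length = 1000), base), "overlap")
  het <- data.frame(id = "h", chrom = "c", start = 0, end = 500,
                    kind = "heterochromatin", strand = "+", passage_rate = 1)
  expect_error(genome_model(data.frame(name = "c", length = 1000), het),
               "undefined strand")
})

test_that("genotype presets satisfy the model's constraints", {
  expect_equal(genotype("WT")$retention, 1)
  expect_equal(genotype("spt6d")$retention, 0)
  k20 <- genotype("spt6-K20")
  expect_true(k20$retention > 0 && k20$retention < 1)
  expect_equal(genotype("WT")$het_derepression, 1)
  expect_false(genotype("clr4d")$clr4_active)
  expect_identical(genotype("spt6Δ")$name, "spt6d")
  expect_error(genotype("nosuch"), "unknown genotype")
  expect_error(genotype("WT", retention = 0.5), "WT")
})

test_that("turnover is inert without eviction or transcription", {
  m <- one_gene_model(n_nuc = 50, rate = 5)
  cfg <- sim_config(seed = 4)
  wt <- simulate_turnover(m, genotype("WT"), cfg)
  expect_equal(wt$occupancy, rep("OLD", 50))
  expect_equal(wt$marks, rep("K4me2", 50))

  m0 <- one_gene_model(n_nuc = 50, rate = 0)
  mut <- simulate_turnover(m0, genotype("spt6d"), cfg)
  expect_equal(mut$occupancy, rep("OLD", 50))
})

test_that("forced-passage OLD fraction matches the closed form (1-p0)^n", {
  n_nuc <- 2000
  m <- one_gene_model(n_nuc = n_nuc)
  cfg <- sim_config(p0 = 0.5, p_fill = 0, p_fill_5prime = 0, seed = 21)
  st <- simulate_turnover(m, genotype("spt6d"), cfg, forced_passages = 3)
  k <- sum(st$occupancy == "OLD")
  # exact binomial 99% interval around (1 - 0.5)^3 = 0.125
  ci <- qbinom(c(0.005, 0.995), n_nuc, 0.125)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("turnover never adds K4me2/K9me2 and respects state invariants", {
  m <- build_genome(8, het_domains = 1, seed = 5)
  for (s in 1:5) {
    cfg <- sim_config(seed = s)
    st <- simulate_turnover(m, genotype("spt6-K20"), cfg)
    ini <- initial_state(m, genotype("spt6-K20"))
    expect_lte(sum(grepl("K4me2", st$marks)), sum(grepl("K4me2", ini$marks)))
    expect_lte(sum(grepl("K9me2", st$marks)), sum(grepl("K9me2", ini$marks)))
    # NAKED has no marks; NEW carries K56Ac only
    expect_true(all(st$marks[st$occupancy == "NAKED"] == ""))
    expect_true(all(st$marks[st$occupancy == "NEW"] == "K56Ac"))
    # OLD nucleosomes keep their locus-specific mark
    expect_equal(st$marks[st$occupancy == "OLD"],
                 ini$marks[st$occupancy == "OLD"])
  }
  # clr4-inactive states carry no K9me2 anywhere
  st4 <- simulate_turnover(m, genotype("clr4d"), sim_config(seed = 1))
  expect_false(any(grepl("K9me2", st4$marks)))
})

test_that("refilling compensates occupancy and all excess is new K56Ac histone", {
  m <- one_gene_model(n_nuc = 500, rate = 6)
  base <- sim_config(p0 = 0.3, p_fill = 0, p_fill_5prime = 0, seed = 8)
  with_fill <- sim_config(p0 = 0.3, p_fill = 0.5, p_fill_5prime = 0.5, seed = 8)
  st0 <- simulate_turnover(m, genotype("spt6d"), base, forced_passages = 6)
  st1 <- simulate_turnover(m, genotype("spt6d"), with_fill, forced_passages = 6)
  occ0 <- st0$occupancy != "NAKED"
  occ1 <- st1$occupancy != "NAKED"
  expect_gt(sum(occ1), sum(occ0))
  # same eviction stream: every OLD survivor is shared, excess is NEW
  expect_equal(which(st1$occupancy == "OLD"), which(st0$occupancy == "OLD"))
  extra <- occ1 & !occ0
  expect_true(all(st1$occupancy[extra] == "NEW"))
  expect_true(all(st1$marks[extra] == "K56Ac"))
})

test_that("expected OLD fraction decreases with passage rate and rises with retention", {
  m <- build_genome(8, strata_rates = c(8, 4, 2, 0.5), het_domains = 0, seed = 2)
  genes <- m$domains
  strata <- c("Very high", "High", "Medium", "Low")
  old_frac <- matrix(0, 200, 4, dimnames = list(NULL, strata))
  for (s in seq_len(200)) {
    st <- simulate_turnover(m, genotype("spt6d"), sim_config(seed = 1000 + s))
    olds <- tapply(st$occupancy == "OLD", genes$stratum[match(st$domain, genes$id)], mean)
    old_frac[s, ] <- olds[strata]
  }
  means <- colMeans(old_frac)
  expect_true(all(diff(means) > 0))  # VH < H < M < L

  # K4me2 density non-decreasing in retention at fixed rates
  dens <- vapply(c("spt6d", "spt6-K20", "WT"), function(g) {
    mean(vapply(1:20, function(s) {
      st <- simulate_turnover(m, genotype(g), sim_config(seed = 2000 + s))
      mean(grepl("K4me2", st$marks))
    }, numeric(1)))
  }, numeric(1))
  expect_true(dens[["spt6d"]] < dens[["spt6-K20"]])
  expect_true(dens[["spt6-K20"]] < dens[["WT"]])
})

test_that("read sampling respects geometry, support and determinism", {
  m <- build_genome(8, het_domains = 1, seed = 3)
  cfg <- sim_config(n_reads = 1000, seed = 6)
  st <- simulate_turnover(m, genotype("spt6d"), cfg)

  rd <- sample_chip_reads(st, "input", cfg)
  expect_equal(nrow(rd), 1000)
  expect_true(all(rd$end - rd$start == cfg$read_length))
  sz <- chrom_sizes_vec(m)
  expect_true(all(rd$start >= 0 & rd$end <= sz[rd$chrom]))

  # K9me2 in a clr4-inactive state with no background is unsampleable
  st4 <- simulate_turnover(m, genotype("clr4d"), sim_config(seed = 1, background_fraction = 0))
  expect_error(sample_chip_reads(st4, "K9me2",
                                 sim_config(seed = 1, background_fraction = 0)),
               "unsampleable")

  # single occupied nucleosome: all read midpoints near its dyad
  m1 <- one_gene_model(n_nuc = 1, rate = 0)
  cfg1 <- sim_config(n_reads = 500, background_fraction = 0, seed = 9)
  st1 <- simulate_turnover(m1, genotype("WT"), cfg1)
  rd1 <- sample_chip_reads(st1, "H3", cfg1)
  mid <- (rd1$start + rd1$end - 1) %/% 2
  expect_true(all(abs(mid - st1$dyad[1]) <= cfg1$fragment_length))

  expect_identical(sample_chip_reads(st, "H3", cfg), sample_chip_reads(st, "H3", cfg))
})

test_that("qPCR emission honors replicate structure, noise and K9me2 absence", {
  m <- build_genome(8, het_domains = 1, seed = 3)
  amp <- default_amplicons(m)
  cfg0 <- sim_config(noise_cv = 0, qpcr_replicates = 3, seed = 2)
  st <- simulate_turnover(m, genotype("WT"), cfg0)
  tbl <- emit_qpcr_table(st, amp, cfg0)
  expect_true(all(table(tbl$amplicon, tbl$mark) == 3))
  # zero noise: replicates identical
  spread <- tapply(tbl$efficiency, paste(tbl$amplicon, tbl$mark), function(x) diff(range(x)))
  expect_true(all(spread == 0))
  # WT euchromatic amplicon: K4me2 and H3 efficiencies are density + background
  g1 <- tbl[tbl$amplicon == "gene001" & tbl$mark == "K4me2", "efficiency"]
  expect_equal(unique(g1), 1 + cfg0$background_fraction)

  # K9me2 in a clr4-inactive state is exactly the background term
  st4 <- simulate_turnover(m, genotype("clr4d"), cfg0)
  tbl4 <- emit_qpcr_table(st4, amp, cfg0)
  k9 <- tbl4[tbl4$mark == "K9me2", "efficiency"]
  expect_true(all(k9 == cfg0$background_fraction))

  expect_error(emit_qpcr_table(st, amp[0, ], cfg0), "empty amplicon")
})

test_that("state, reads and qPCR tables round-trip through their text formats", {
  m <- build_genome(4, het_domains = 0, seed = 13)
  cfg <- sim_config(n_reads = 200, seed = 13)
  st <- simulate_turnover(m, genotype("spt6d"), cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_state_tsv(st, f)
  back <- read.delim(f, na.strings = NULL, colClasses = c(marks = "character"))
  expect_equal(back$occupancy, st$occupancy)
  expect_equal(back$dyad, st$dyad)

  rd <- sample_chip_reads(st, "H3", cfg)
  fb <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed(rd, fb)
  rd2 <- read_alignments(fb, "BED", sizes = m)
  expect_equal(rd2[, c("chrom", "start", "end", "strand")],
               rd[, c("chrom", "start", "end", "strand")])

  tbl <- emit_qpcr_table(st, default_amplicons(m, n_gene_amplicons = 2), cfg)
  fq <- withr::local_tempfile(fileext = ".tsv")
  write_qpcr_table(tbl, fq)
  long <- read_qpcr_table(fq)
  key <- function(d) d[order(d$amplicon, d$mark, d$genotype, d$replicate),
                       c("amplicon", "mark", "genotype", "replicate", "efficiency")]
  a <- key(tbl); b <- key(long)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b, a, tolerance = 1e-12)
})
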