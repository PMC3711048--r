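# Fixtures built in code: tiny genomes, read sets and tracks.

# a single-gene genome with a known number of nucleosomes
one_gene_model <- function(n_nuc = 100, rate = 1, spacing = 150,
                           strand = "+") {
  len <- n_nuc * spacing
  genome_model(
    chromosomes = data.frame(name = "chrT", length = len + 2000),
    domains = data.frame(id = "geneT", chrom = "chrT", start = 1000,
                         end = 1000 + len, kind = "euchromatic-gene",
                         strand = strand, passage_rate = rate,
                         stringsAsFactors = FALSE),
    nucleosome_spacing = spacing)
}

# uniform random reads of fixed length on one chromosome
random_reads <- function(n, chrom_len, read_len = 49, chrom = "chrT",
                         seed = 1) {
  set.seed(seed)
  start <- sample.int(chrom_len - read_len, n, replace = TRUE) - 1L
  data.frame(chrom = chrom, start = start, end = start + read_len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# brute-force per-base pileup: per-base membership counting, independent
# of the coverage machinery under test
brute_force_pileup <- function(reads, sizes, extend_to = NULL) {
  sz <- chrom_sizes_vec(sizes)
  vals <- lapply(sz, function(n) numeric(n))
  for (i in seq_len(nrow(reads))) {
    s <- reads$start[i]; e <- reads$end[i]
    n <- sz[[reads$chrom[i]]]
    if (!is.null(extend_to)) {
      if (reads$strand[i] == "+") e <- s + extend_to else s <- e - extend_to
      s <- max(0, s); e <- min(e, n)
    }
    for (b in seq(s, e - 1)) {
      vals[[reads$chrom[i]]][b + 1] <- vals[[reads$chrom[i]]][b + 1] + 1
    }
  }
  vals
}

chrom_sizes_vec <- function(sizes) {
  if (inherits(sizes, "genome_model"))
    stats::setNames(sizes$chromosomes$length, sizes$chromosomes$name)
  else sizes
}

# caller configuration reducing a 300-bp chromosome to a single window,
# so keep/drop equals one Poisson tail decision
single_window_cfg <- function() {
  caller_config(window = 300, step = 300, p_threshold = 1e-3, merge_gap = 0,
                min_length = 300, local_spans = 300, fragment_scale = 1)
}

# a raw coverage track with given per-base values on one chromosome
flat_track <- function(values, library_size, chrom = "chrT") {
  coverage_track(stats::setNames(list(values), chrom),
                 library_size = library_size, units = "raw")
}
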