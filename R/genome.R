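## Model genome: domains (euchromatic genes in four transcription strata,
## pericentromeric heterochromatin blocks) laid out on a small set of
## chromosomes, with regularly spaced nucleosome dyads.

#' Construct a genome model
#'
#' A genome model holds chromosome sizes, the nucleosome spacing, and a table
#' of domains (euchromatic genes and heterochromatin blocks). Coordinates are
#' 0-based half-open throughout.
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp).
#' @param domains data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `kind` (`"euchromatic-gene"` or `"heterochromatin"`), `strand`
#'   (`"+"`/`"-"` for genes, `NA` for heterochromatin), `passage_rate`
#'   (expected Pol II passages per epoch).
#' @param nucleosome_spacing bp between adjacent dyads (default 150).
#' @return A `genome_model` object.
#' @export
genome_model <- function(chromosomes, domains, nucleosome_spacing = 150) {
  chromosomes <- as.data.frame(chromosomes)
  domains <- as.data.frame(domains)
  if (any(chromosomes$length <= 0)) stopf("chromosome lengths must be > 0")
  if (anyDuplicated(chromosomes$name)) stopf("duplicated chromosome names")
  if (anyDuplicated(domains$id)) stopf("duplicated domain ids")
  if (any(domains$passage_rate < 0)) stopf("passage_rate must be >= 0")
  if (!all(domains$kind %in% c("euchromatic-gene", "heterochromatin")))
    stopf("unknown domain kind")
  het <- domains$kind == "heterochromatin"
  if (any(!is.na(domains$strand[het])))
    stopf("heterochromatin domains must have undefined strand")
  if (any(is.na(domains$strand[!het]) | !domains$strand[!het] %in% c("+", "-")))
    stopf("gene domains must have strand '+' or '-'")
  sizes <- stats::setNames(chromosomes$length, chromosomes$name)
  if (!all(domains$chrom %in% names(sizes))) stopf("domain on unknown chromosome")
  if (any(domains$start < 0 | domains$end > sizes[domains$chrom] |
          domains$start >= domains$end))
    stopf("domains must lie within their chromosome")
  ## overlap check within chromosome
  for (ch in unique(domains$chrom)) {
    d <- domains[domains$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stopf("domains overlap on %s", ch)
  }
  structure(list(chromosomes = chromosomes,
                 domains = domains,
                 nucleosome_spacing = nucleosome_spacing),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %d gene(s), %d heterochromatin domain(s), spacing %d bp\n",
              nrow(x$chromosomes),
              sum(x$domains$kind == "euchromatic-gene"),
              sum(x$domains$kind == "heterochromatin"),
              as.integer(x$nucleosome_spacing)))
  invisible(x)
}

#' Build a desk-scale model genome with stratified genes
#'
#' Lays out `n_genes` euchromatic genes on chromosome `chrI`, assigned
#' cyclically to four transcription strata (so stratum membership is not
#' confounded with chromosomal position), with alternating strands and
#' randomized gene lengths and intergenic gaps; heterochromatin blocks are
#' placed on `chrIII` with a low basal passage rate, mimicking the
#' pericentromeric repeats.
#'
#' @param n_genes Number of genes; must be >= 4 and divisible by 4.
#' @param strata_rates Four strictly decreasing expected Pol II passage rates
#'   per epoch (Very high, High, Medium, Low).
#' @param het_domains Number of heterochromatin blocks (may be 0).
#' @param seed Integer seed; identical seeds give identical models.
#' @param gene_nucleosomes Integer range (min, max) of nucleosomes per gene.
#' @param gap_range Integer range (min, max) of intergenic gap sizes in bp.
#' @param het_size Size of each heterochromatin block in bp.
#' @param het_rate Basal heterochromatic passage rate per epoch.
#' @param nucleosome_spacing bp between adjacent dyads.
#' @return A `genome_model`.
#' @export
build_genome <- function(n_genes, strata_rates = c(8, 4, 2, 0.5),
                         het_domains = 1, seed = 1,
                         gene_nucleosomes = c(10, 20),
                         gap_range = c(400, 800),
                         het_size = 15000, het_rate = 1.0,
                         nucleosome_spacing = 150) {
  if (!is_count(n_genes) || n_genes < 4 || n_genes %% 4 != 0)
    stopf("n_genes must be >= 4 and divisible by 4 (got %s)", format(n_genes))
  if (length(strata_rates) != 4 || any(diff(strata_rates) >= 0))
    stopf("strata_rates must be 4 strictly decreasing rates")
  if (!is_count(het_domains)) stopf("het_domains must be a non-negative integer")
  set.seed(derive_seed(seed, "build_genome"))

  strata <- c("Very high", "High", "Medium", "Low")
  n_nuc <- sample(seq(gene_nucleosomes[1], gene_nucleosomes[2]), n_genes, replace = TRUE)
  gaps <- sample(seq(gap_range[1], gap_range[2]), n_genes, replace = TRUE)
  lens <- n_nuc * nucleosome_spacing
  starts <- 1000 + cumsum(c(0, (lens + gaps)[-n_genes]))
  genes <- data.frame(
    id = sprintf("gene%03d", seq_len(n_genes)),
    chrom = "chrI",
    start = starts,
    end = starts + lens,
    kind = "euchromatic-gene",
    strand = rep(c("+", "-"), length.out = n_genes),
    passage_rate = strata_rates[((seq_len(n_genes) - 1L) %% 4L) + 1L],
    stratum = strata[((seq_len(n_genes) - 1L) %% 4L) + 1L],
    stringsAsFactors = FALSE)
  chrI_len <- max(genes$end) + 1000

  domains <- genes
  chroms <- data.frame(name = "chrI", length = chrI_len)
  if (het_domains > 0) {
    hs <- 1000 + (seq_len(het_domains) - 1L) * (het_size + 2000)
    het <- data.frame(
      id = sprintf("het%02d", seq_len(het_domains)),
      chrom = "chrIII",
      start = hs, end = hs + het_size,
      kind = "heterochromatin",
      strand = NA_character_,
      passage_rate = het_rate,
      stratum = NA_character_,
      stringsAsFactors = FALSE)
    domains <- rbind(genes, het)
    chroms <- rbind(chroms, data.frame(name = "chrIII", length = max(het$end) + 1000))
  }
  genome_model(chroms, domains, nucleosome_spacing)
}

#' Genotype presets for the turnover model
#'
#' A genotype carries three knobs: `retention` r, the efficiency with which
#' Spt6 retains histones during a Pol II passage (per-passage eviction
#' probability is p0 * (1 - r)); `het_derepression`, a multiplier on
#' heterochromatic passage rates (silencing loss); and `clr4_active`, which
#' controls whether heterochromatic old histones carry K9me2.
#'
#' Presets: `WT` (r = 1), `spt6-K20` (hypomorph, r = 0.3), `spt6d` (null,
#' r = 0), `clr3d` (strongly derepressed heterochromatin, mildly reduced
#' retention r = 0.9 reflecting the deacetylase's own contribution to
#' preventing turnover), `clr4d` (derepressed, no K9me2), and the
#' `spt6-K20 clr3d` double mutant (combined derepression, low retention).
#' Every silencing-defective preset, including the spt6 mutants, carries
#' `het_derepression > 1`: loss of any of these factors licenses cryptic
#' pericentromeric transcription. Unicode delta spellings are accepted as
#' aliases.
#'
#' @param name Preset name, or any name when the other arguments are given.
#' @param retention Override retention r in \[0, 1\].
#' @param het_derepression Override heterochromatin derepression (>= 1).
#' @param clr4_active Override K9me2 placement flag.
#' @return A `genotype` object.
#' @export
genotype <- function(name, retention = NULL, het_derepression = NULL,
                     clr4_active = NULL) {
  canon <- c("spt6Δ" = "spt6d", "clr3Δ" = "clr3d",
             "clr4Δ" = "clr4d", "spt6-K20 clr3Δ" = "spt6-K20 clr3d")
  if (name %in% names(canon)) name <- canon[[name]]
  ## heterochromatic derepression: cryptic pericentromeric transcription
  ## rises in every silencing-defective genotype, including the spt6
  ## mutants, and further in the spt6-K20 clr3 double mutant
  presets <- list(
    "WT"             = list(r = 1.0, het = 1,  clr4 = TRUE),
    "spt6-K20"       = list(r = 0.3, het = 4,  clr4 = TRUE),
    "spt6d"          = list(r = 0.0, het = 6,  clr4 = TRUE),
    "clr3d"          = list(r = 0.9, het = 8,  clr4 = TRUE),
    "clr4d"          = list(r = 1.0, het = 10, clr4 = FALSE),
    "spt6-K20 clr3d" = list(r = 0.3, het = 12, clr4 = TRUE))
  p <- presets[[name]]
  if (is.null(p)) {
    if (is.null(retention))
      stopf("unknown genotype '%s'; give retention (and optionally het_derepression, clr4_active)", name)
    p <- list(r = retention, het = het_derepression %||% 1, clr4 = clr4_active %||% TRUE)
  } else {
    p$r <- retention %||% p$r
    p$het <- het_derepression %||% p$het
    p$clr4 <- clr4_active %||% p$clr4
  }
  if (p$r < 0 || p$r > 1) stopf("retention must lie in [0, 1]")
  if (p$het < 1) stopf("het_derepression must be >= 1")
  if (name == "WT" && (p$r != 1 || p$het != 1))
    stopf("WT must have retention 1 and het_derepression 1")
  structure(list(name = name, retention = p$r, het_derepression = p$het,
                 clr4_active = isTRUE(p$clr4)),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat(sprintf("genotype %s: retention %.2f, het_derepression %.1f, clr4 %s\n",
              x$name, x$retention, x$het_derepression,
              if (x$clr4_active) "active" else "inactive"))
  invisible(x)
}

#' Simulation configuration
#'
#' Parameters of the turnover and sampling model. `p0` is the per-passage
#' eviction probability of an unprotected nucleosome; the effective eviction
#' probability is `p0 * (1 - retention)`. `p_fill` is the per-passage
#' probability that a naked position is refilled with a newly synthesized,
#' K56-acetylated histone; within the first `k_5prime` nucleosomes of a gene
#' the reduced `p_fill_5prime` applies. Reads are single-end, `read_length`
#' bp, drawn from `fragment_length`-bp fragments.
#'
#' @param p0 Per-passage eviction probability when unprotected.
#' @param p_fill Per-passage refill probability for naked positions.
#' @param p_fill_5prime Refill probability within the first `k_5prime`
#'   nucleosomes downstream of the TSS; must be <= `p_fill`.
#' @param k_5prime Number of 5'-proximal nucleosomes with reduced refill.
#' @param epochs Passage-sampling duration (Poisson exposure multiplier).
#' @param read_length Read length in bp.
#' @param fragment_length ChIP fragment length in bp; >= `read_length`.
#' @param background_fraction Fraction of reads drawn uniformly from the
#'   genome, in \[0, 1).
#' @param n_reads Reads per ChIP sample.
#' @param qpcr_replicates Replicates per qPCR measurement.
#' @param noise_cv Coefficient of variation of lognormal replicate noise.
#' @param seed Integer seed governing all randomness downstream.
#' @return A `sim_config` object.
#' @export
sim_config <- function(p0 = 0.2, p_fill = 0.3, p_fill_5prime = 0.05,
                       k_5prime = 3, epochs = 1, read_length = 49,
                       fragment_length = 250, background_fraction = 0.05,
                       n_reads = 1e5, qpcr_replicates = 3, noise_cv = 0.1,
                       seed = 1) {
  probs <- c(p0 = p0, p_fill = p_fill, p_fill_5prime = p_fill_5prime,
             background_fraction = background_fraction)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (background_fraction >= 1) stopf("background_fraction must be < 1")
  if (p_fill_5prime > p_fill) stopf("p_fill_5prime must be <= p_fill")
  if (read_length > fragment_length) stopf("read_length must be <= fragment_length")
  structure(list(p0 = p0, p_fill = p_fill, p_fill_5prime = p_fill_5prime,
                 k_5prime = as.integer(k_5prime), epochs = epochs,
                 read_length = as.integer(read_length),
                 fragment_length = as.integer(fragment_length),
                 background_fraction = background_fraction,
                 n_reads = as.integer(n_reads),
                 qpcr_replicates = as.integer(qpcr_replicates),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "sim_config")
}
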