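## ChIP-seq read sampling and ChIP-qPCR immunoprecipitation-efficiency
## emission from a simulated chromatin state. Both draw on the same target
## density definition (target_weights) so sequencing and qPCR views of a
## state agree.

#' Sample aligned ChIP-seq reads from a chromatin state
#'
#' Fragments are drawn from nucleosome positions weighted by the target
#' density (H3: any occupied nucleosome; mark targets: nucleosomes carrying
#' the mark; Pol II: the domain's effective passage rate; Swi6: K9me2
#' density; input: uniform over the genome), mixed with a
#' `background_fraction` of uniformly placed fragments. Each fragment is
#' dyad-centered with uniform jitter of half the nucleosome spacing, shifted
#' to fit its chromosome; the read is the 5' `read_length` bases of either
#' fragment end with equal probability.
#'
#' @param state A `chromatin_state` from [simulate_turnover()].
#' @param target One of `"H3"`, `"K4me2"`, `"K9me2"`, `"K56Ac"`, `"AcH3"`,
#'   `"AcH4"`, `"PolII"`, `"Swi6"`, `"input"`.
#' @param cfg A `sim_config`.
#' @return data.frame of read alignments with columns `chrom`, `start`,
#'   `end` (0-based half-open), `strand`; exactly `cfg$n_reads` rows.
#' @export
sample_chip_reads <- function(state, target = "H3", cfg = sim_config()) {
  stopifnot(inherits(state, "chromatin_state"), inherits(cfg, "sim_config"))
  target <- match.arg(target, .chip_targets)
  if (cfg$n_reads <= 0) stopf("n_reads must be > 0")
  model <- attr(state, "model")
  genotype <- attr(state, "genotype")
  if (is.null(model)) stopf("state carries no genome model")
  set.seed(derive_seed(cfg$seed, "chip", genotype$name, target))

  sizes <- chrom_sizes(model)
  n <- cfg$n_reads
  fl <- cfg$fragment_length
  rl <- cfg$read_length

  if (target == "input") {
    is_bg <- rep(TRUE, n)
  } else {
    is_bg <- stats::runif(n) < cfg$background_fraction
  }
  w <- if (target == "input") rep(0, nrow(state))
       else target_weights(state, target, model, genotype)
  if (target != "input" && sum(w) <= 0) {
    if (cfg$background_fraction == 0)
      stopf("target '%s' has zero density everywhere and background_fraction is 0: unsampleable", target)
    is_bg[] <- TRUE
  }

  chrom <- character(n)
  fstart <- numeric(n)

  n_bg <- sum(is_bg)
  if (n_bg > 0) {
    ci <- sample(seq_along(sizes), n_bg, replace = TRUE, prob = sizes)
    chrom[is_bg] <- names(sizes)[ci]
    fstart[is_bg] <- floor(stats::runif(n_bg) * pmax(1, sizes[ci] - fl))
  }
  n_sig <- n - n_bg
  if (n_sig > 0) {
    ni <- sample.int(nrow(state), n_sig, replace = TRUE, prob = w)
    half <- floor(model$nucleosome_spacing / 2)
    jitter <- floor(stats::runif(n_sig, -half, half + 1))
    center <- state$dyad[ni] + jitter
    s <- center - floor(fl / 2)
    len <- sizes[state$chrom[ni]]
    s <- pmax(0, pmin(s, len - fl))
    chrom[!is_bg] <- state$chrom[ni]
    fstart[!is_bg] <- s
  }
  fend <- fstart + fl
  plus <- stats::runif(n) < 0.5
  reads <- data.frame(
    chrom = chrom,
    start = ifelse(plus, fstart, fend - rl),
    end = ifelse(plus, fstart + rl, fend),
    strand = ifelse(plus, "+", "-"),
    stringsAsFactors = FALSE)
  reads$start <- as.integer(reads$start)
  reads$end <- as.integer(reads$end)
  reads
}

#' Emit a replicate ChIP-qPCR immunoprecipitation-efficiency table
#'
#' For every (mark, amplicon) pair, emits `cfg$qpcr_replicates` IP
#' efficiencies equal to (mean target density over the nucleosomes in the
#' amplicon + background) multiplied by lognormal noise with coefficient of
#' variation `cfg$noise_cv` (unit mean). Reference rows for the H3
#' C-terminus (`H3-Cterm`, occupancy density) and histone H4 (`H4`, same
#' density; the AcH4 reference) are always included.
#'
#' @param state A `chromatin_state`.
#' @param amplicons data.frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param cfg A `sim_config`.
#' @param marks ChIP targets to emit in addition to the reference rows.
#' @return data.frame with columns `amplicon`, `mark`, `genotype`,
#'   `replicate`, `efficiency` (long format; see [write_qpcr_table()] for
#'   the wide TSV form).
#' @export
emit_qpcr_table <- function(state, amplicons, cfg = sim_config(),
                            marks = c("K4me2", "K9me2", "K56Ac", "AcH3",
                                      "AcH4", "PolII", "Swi6")) {
  stopifnot(inherits(state, "chromatin_state"))
  amplicons <- as.data.frame(amplicons)
  if (nrow(amplicons) == 0) stopf("empty amplicon list")
  model <- attr(state, "model")
  genotype <- attr(state, "genotype")
  sizes <- chrom_sizes(model)
  if (!all(amplicons$chrom %in% names(sizes)) ||
      any(amplicons$start < 0 | amplicons$end > sizes[amplicons$chrom]))
    stopf("amplicon outside the genome")
  set.seed(derive_seed(cfg$seed, "qpcr", genotype$name))

  all_marks <- c("H3-Cterm", "H4", marks)
  dens_target <- function(mark) {
    if (mark %in% c("H3-Cterm", "H4")) "H3" else mark
  }
  rows <- list()
  for (ai in seq_len(nrow(amplicons))) {
    a <- amplicons[ai, ]
    ## amplicons in gene-free regions contain no nucleosome position and
    ## therefore report pure background (the role of a gfr control)
    in_amp <- state$chrom == a$chrom & state$dyad >= a$start & state$dyad < a$end
    for (mark in all_marks) {
      w <- target_weights(state, dens_target(mark), model, genotype)
      dens <- if (any(in_amp)) mean(w[in_amp]) else 0
      mu <- dens + cfg$background_fraction
      eff <- if (cfg$noise_cv > 0) {
        sdlog <- sqrt(log(1 + cfg$noise_cv^2))
        mu * stats::rlnorm(cfg$qpcr_replicates, -sdlog^2 / 2, sdlog)
      } else rep(mu, cfg$qpcr_replicates)
      rows[[length(rows) + 1L]] <- data.frame(
        amplicon = a$name, mark = mark, genotype = genotype$name,
        replicate = seq_len(cfg$qpcr_replicates), efficiency = eff,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Default amplicon set for a built genome
#'
#' One amplicon per selected gene (centered on the gene body), a `dg`
#' amplicon inside the first heterochromatin block (when present), and an
#' `act1`-like highly transcribed control plus a `gfr2`-like gene-free
#' region on chrI.
#'
#' The heterochromatic `dg` amplicon is wider than the gene amplicons: the
#' simulator tracks a single chromatin fiber, so averaging more nucleosome
#' positions stands in for the population averaging inherent in real
#' ChIP-qPCR of repeat elements.
#'
#' @param model A `genome_model` from [build_genome()].
#' @param n_gene_amplicons Number of gene amplicons (one per stratum cycle).
#' @param width Amplicon width in bp.
#' @param het_width Width of the heterochromatic `dg` amplicon in bp.
#' @return data.frame with columns `name`, `chrom`, `start`, `end`.
#' @export
default_amplicons <- function(model, n_gene_amplicons = 4, width = 600,
                              het_width = 3000) {
  dom <- model$domains
  genes <- dom[dom$kind == "euchromatic-gene", ]
  het <- dom[dom$kind == "heterochromatin", ]
  pick <- genes[seq_len(min(n_gene_amplicons, nrow(genes))), ]
  mid <- floor((pick$start + pick$end) / 2)
  amp <- data.frame(name = pick$id, chrom = pick$chrom,
                    start = mid - width %/% 2, end = mid + width %/% 2,
                    stringsAsFactors = FALSE)
  ## act1 stands in for a highly transcribed control: the top-stratum gene
  act1_gene <- genes[which.max(genes$passage_rate), ]
  amid <- floor((act1_gene$start + act1_gene$end) / 2)
  amp <- rbind(amp, data.frame(name = "act1", chrom = act1_gene$chrom,
                               start = amid - width %/% 2,
                               end = amid + width %/% 2))
  ## gfr2 stands in for a gene-free region: the gap after the last gene
  sizes <- chrom_sizes(model)
  amp <- rbind(amp, data.frame(name = "gfr2", chrom = "chrI",
                               start = sizes[["chrI"]] - 900,
                               end = sizes[["chrI"]] - 300))
  if (nrow(het) > 0) {
    hmid <- floor((het$start[1] + het$end[1]) / 2)
    amp <- rbind(amp, data.frame(name = "dg", chrom = het$chrom[1],
                                 start = hmid - het_width %/% 2,
                                 end = hmid + het_width %/% 2))
  }
  amp
}
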