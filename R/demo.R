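## End-to-end synthetic experiment: simulate wild type and a mutant, emit
## reads and tracks, call regions of H3 loss, tabulate per-gene metrics,
## metagene profiles and qPCR results, and summarize per expression class.

#' Run configuration for the end-to-end demo
#'
#' Serializable to and from YAML losslessly (see [write_run_config()] /
#' [read_run_config()]).
#'
#' @param seed Master seed; overrides `sim$seed`.
#' @param genotypes Genotype names to simulate; must include `"WT"`.
#' @param n_genes,strata_rates,het_domains Passed to [build_genome()].
#' @param sim A `sim_config`.
#' @param caller A `caller_config`.
#' @param thresholds A `threshold_config`.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1, genotypes = c("WT", "spt6d"),
                       n_genes = 40, strata_rates = c(8, 4, 2, 0.5),
                       het_domains = 1, sim = sim_config(),
                       caller = caller_config(),
                       thresholds = threshold_config()) {
  if (!"WT" %in% genotypes) stopf("genotypes must include 'WT'")
  for (g in genotypes) genotype(g)  # validate names before any simulation
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), genotypes = genotypes,
                 n_genes = n_genes, strata_rates = strata_rates,
                 het_domains = het_domains, sim = sim, caller = caller,
                 thresholds = thresholds),
            class = "run_config")
}

#' Write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$caller <- unclass(x$caller)
  x$thresholds <- unclass(x$thresholds)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file written by [write_run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(seed = x$seed, genotypes = unlist(x$genotypes),
             n_genes = x$n_genes, strata_rates = unlist(x$strata_rates),
             het_domains = x$het_domains,
             sim = do.call(sim_config, x$sim),
             caller = do.call(caller_config, as.list(x$caller)),
             thresholds = do.call(threshold_config, x$thresholds))
}

#' Run the end-to-end synthetic experiment
#'
#' Simulates each configured genotype, samples H3, Pol II and input reads,
#' writes reads (BED), per-million tracks (bedGraph), the mutant-vs-WT H3
#' log2 ratio track, called H3-decrease regions, the per-gene occupancy
#' table, TSS metagene profiles, qPCR tables and per-histone results, and
#' a per-class summary (median H3 fold change, fraction of genes flagged
#' `h3_loss`). Identical seeds give identical outputs; a partially written
#' directory from a failed run is removed.
#'
#' @param config A `run_config`.
#' @param outdir Output directory (created; must not already exist).
#' @return Invisibly, the output directory path.
#' @export
run_demo <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "run_config"))
  mutant <- setdiff(config$genotypes, "WT")[1]
  if (is.na(mutant)) stopf("config must include a mutant genotype besides WT")
  if (dir.exists(outdir)) stopf("output directory '%s' already exists", outdir)
  dir.create(outdir, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(outdir, recursive = TRUE))

  cfg <- config$sim
  model <- build_genome(config$n_genes, config$strata_rates,
                        config$het_domains, seed = config$seed)
  genes <- model_genes(model)
  write_chrom_sizes(chrom_sizes(model), file.path(outdir, "genome.sizes"))
  write_gff3_genes(genes, file.path(outdir, "genes.gff3"))
  amplicons <- default_amplicons(model)

  reads <- list()
  tracks <- list()
  qpcr_rows <- list()
  for (g in config$genotypes) {
    gt <- genotype(g)
    state <- simulate_turnover(model, gt, cfg)
    write_state_tsv(state, file.path(outdir, sprintf("state_%s.tsv", gsub("[ /]", "_", g))))
    for (target in c("H3", "PolII", "input")) {
      rd <- sample_chip_reads(state, target, cfg)
      key <- paste(g, target, sep = "_")
      reads[[key]] <- rd
      write_reads_bed(rd, file.path(outdir, sprintf("reads_%s.bed", gsub("[ /]", "_", key))))
      ext <- if (target == "input") NULL else cfg$fragment_length
      tracks[[key]] <- pileup(rd, model, extend_to = ext)
      write_bedgraph(normalize_fpm(tracks[[key]]),
                     file.path(outdir, sprintf("track_%s.fpm.bedgraph", gsub("[ /]", "_", key))))
    }
    qpcr_rows[[g]] <- emit_qpcr_table(state, amplicons, cfg)
  }

  ratio <- log2_ratio(normalize_fpm(tracks[[paste0(mutant, "_H3")]]),
                      normalize_fpm(tracks[["WT_H3"]]))
  write_bedgraph(ratio, file.path(outdir, "h3_log2_mut_vs_wt.bedgraph"))

  regions <- call_regions(tracks[[paste0(mutant, "_H3")]], tracks[["WT_H3"]],
                          config$caller, direction = "decrease")
  write_regions(regions, file.path(outdir, "h3_decrease_regions.bed"))

  records <- gene_occupancy(genes,
                            reads_h3_wt = reads[["WT_H3"]],
                            reads_h3_mut = reads[[paste0(mutant, "_H3")]],
                            reads_pol_wt = reads[["WT_PolII"]],
                            reads_pol_mut = reads[[paste0(mutant, "_PolII")]],
                            cfg = config$thresholds)
  write_gene_table(records, file.path(outdir, "genes.tsv"))

  gcl <- genes
  gcl$class <- records$class
  for (g in c("WT", mutant)) {
    prof <- compute_metagene(normalize_fpm(tracks[[paste0(g, "_H3")]]), gcl, "TSS")
    write_profile(prof, file.path(outdir, sprintf("metagene_tss_%s.tsv", gsub("[ /]", "_", g))))
  }

  qpcr <- do.call(rbind, qpcr_rows)
  write_qpcr_table(qpcr, file.path(outdir, "qpcr_table.tsv"))
  utils::write.table(per_histone_table(qpcr, relative_to = "WT"),
                     file.path(outdir, "qpcr_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- do.call(rbind, lapply(levels(records$class), function(cl) {
    r <- records[records$class == cl, ]
    data.frame(class = cl, n = nrow(r),
               median_h3_fold_change = signif(stats::median(r$fold_change_h3), 6),
               fraction_h3_loss = signif(mean(r$h3_loss), 6),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(summary, file.path(outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ok <- TRUE
  invisible(outdir)
}
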