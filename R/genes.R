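## Per-gene occupancy metrics: fragment counting by read midpoint, FPKM,
## mutant/wild-type fold changes with the study's cutoffs, and expression
## stratification into four classes.

#' Threshold configuration for gene classification
#'
#' @param loss_cutoff H3-loss cutoff: a gene is flagged when its mutant/WT
#'   H3 fold change is strictly below this (default 0.8).
#' @param change_cutoff Pol II-change cutoff: flagged when the fold change
#'   is strictly above this or strictly below its reciprocal (default 2).
#' @param pseudocount FPKM pseudocount used in fold changes (default 0.1),
#'   keeping ratios finite on silent genes.
#' @return A `threshold_config` object.
#' @export
threshold_config <- function(loss_cutoff = 0.8, change_cutoff = 2,
                             pseudocount = 0.1) {
  if (!(loss_cutoff > 0 && loss_cutoff < 1 && change_cutoff > 1))
    stopf("need 0 < loss_cutoff < 1 < change_cutoff")
  structure(list(loss_cutoff = loss_cutoff, change_cutoff = change_cutoff,
                 pseudocount = pseudocount),
            class = "threshold_config")
}

#' Read gene annotations from GFF3
#'
#' Returns 0-based half-open gene coordinates (GFF3 is 1-based inclusive;
#' the conversion happens here at the boundary).
#'
#' @param path GFF3 file.
#' @param sizes Optional chromosome sizes for bounds checking.
#' @param feature_type Feature type(s) to keep (default `"gene"`).
#' @return data.frame with `id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff3_genes <- function(path, sizes = NULL, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) ids <- gr$Name %||% as.character(seq_along(gr))
  genes <- data.frame(
    id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (!is.null(sizes)) {
    sz <- chrom_sizes(sizes)
    if (!all(genes$chrom %in% names(sz)))
      stopf("GFF3 gene on unknown chromosome '%s'",
            setdiff(genes$chrom, names(sz))[1])
    if (any(genes$start < 0 | genes$end > sz[genes$chrom]))
      stopf("GFF3 coordinate outside chromosome")
  }
  genes
}

#' Write gene annotations as GFF3
#'
#' @param genes data.frame with `id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$source <- "histurn"
  gr$ID <- genes$id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Gene annotations of a genome model
#'
#' @param model A `genome_model`.
#' @return data.frame with `id`, `chrom`, `start`, `end`, `strand`.
#' @export
model_genes <- function(model) {
  g <- model$domains[model$domains$kind == "euchromatic-gene", ]
  data.frame(id = g$id, chrom = g$chrom, start = g$start, end = g$end,
             strand = g$strand, stringsAsFactors = FALSE)
}

#' Count fragments per gene by read midpoint
#'
#' A read is assigned to a gene iff its midpoint (the lower-median base of
#' the interval) lies in `[start, end)`; strand-agnostic; each read counts
#' at most once (genes are required to be non-overlapping).
#'
#' @param reads data.frame with `chrom`, `start`, `end`.
#' @param genes data.frame with `id`, `chrom`, `start`, `end`.
#' @return Named integer vector of counts, in gene order.
#' @export
count_fragments <- function(reads, genes) {
  ## non-overlap check per chromosome
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
      stopf("overlapping genes on %s: set an overlap policy first", ch)
  }
  mid <- (reads$start + reads$end - 1L) %/% 2L
  counts <- stats::setNames(integer(nrow(genes)), genes$id)
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    m <- mid[reads$chrom == ch]
    if (length(m) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(m + 1L, m + 1L),
      IRanges::IRanges(genes$start[gi] + 1L, genes$end[gi]))
    tab <- table(S4Vectors::subjectHits(hits))
    counts[gi[as.integer(names(tab))]] <- as.integer(tab)
  }
  counts
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM = counts * 1e9 / (length * library_size)`.
#'
#' @param counts Per-gene fragment counts.
#' @param lengths Gene lengths in bp (> 0).
#' @param library_size Total mapped reads (> 0).
#' @return Numeric vector of FPKM values.
#' @export
fpkm <- function(counts, lengths, library_size) {
  if (any(lengths <= 0)) stopf("gene lengths must be > 0")
  if (library_size <= 0) stopf("library_size must be > 0")
  counts * 1e9 / (lengths * library_size)
}

#' Flag genes by fold-change cutoffs
#'
#' `h3_loss` iff the H3 fold change is strictly below `loss_cutoff`;
#' `polII_change` iff the Pol II fold change is strictly above
#' `change_cutoff` or strictly below `1/change_cutoff`. Values exactly at
#' a cutoff are not flagged.
#'
#' @param records data.frame with `fold_change_h3` and/or
#'   `fold_change_polII` columns (or a numeric vector of H3 fold changes).
#' @param cfg A `threshold_config`.
#' @return `records` with logical `h3_loss` and `polII_change` columns.
#' @export
classify <- function(records, cfg = threshold_config()) {
  if (is.numeric(records))
    records <- data.frame(fold_change_h3 = records)
  if (!is.null(records$fold_change_h3))
    records$h3_loss <- records$fold_change_h3 < cfg$loss_cutoff
  if (!is.null(records$fold_change_polII))
    records$polII_change <- records$fold_change_polII > cfg$change_cutoff |
      records$fold_change_polII < 1 / cfg$change_cutoff
  records
}

#' Stratify genes into four expression classes
#'
#' Genes are ranked by the reference FPKM (highest first) and split at the
#' 25/50/75 percentiles into `Very high`, `High`, `Medium`, `Low`. Ties are
#' broken by stable input order.
#'
#' @param reference Numeric reference FPKM (e.g. wild-type Pol II), one
#'   value per gene, length >= 4.
#' @return Factor of class labels, levels `Very high`, `High`, `Medium`,
#'   `Low`.
#' @export
stratify_expression <- function(reference) {
  n <- length(reference)
  if (n < 4) stopf("need >= 4 genes to stratify into four classes")
  rank_desc <- order(order(-reference, seq_len(n)))
  q <- (rank_desc - 0.5) / n
  labels <- c("Very high", "High", "Medium", "Low")
  factor(labels[findInterval(q, c(0.25, 0.5, 0.75)) + 1L], levels = labels)
}

#' Build per-gene occupancy records
#'
#' Counts fragments, computes FPKM per sample, mutant/WT fold changes with
#' the configured pseudocount, flags per [classify()], and stratifies
#' expression by wild-type Pol II FPKM.
#'
#' @param genes data.frame with `id`, `chrom`, `start`, `end`, `strand`.
#' @param reads_h3_wt,reads_h3_mut H3 ChIP reads for wild type and mutant.
#' @param reads_pol_wt,reads_pol_mut Pol II ChIP reads (optional;
#'   `reads_pol_wt` is required for stratification).
#' @param cfg A `threshold_config`.
#' @return data.frame of gene occupancy records.
#' @export
gene_occupancy <- function(genes, reads_h3_wt, reads_h3_mut,
                           reads_pol_wt = NULL, reads_pol_mut = NULL,
                           cfg = threshold_config()) {
  len <- genes$end - genes$start
  rec <- data.frame(gene = genes$id, length = len, stringsAsFactors = FALSE)
  c_h3_wt <- count_fragments(reads_h3_wt, genes)
  c_h3_mut <- count_fragments(reads_h3_mut, genes)
  rec$frag_h3_wt <- as.integer(c_h3_wt)
  rec$frag_h3_mut <- as.integer(c_h3_mut)
  rec$fpkm_h3_wt <- fpkm(c_h3_wt, len, nrow(reads_h3_wt))
  rec$fpkm_h3_mut <- fpkm(c_h3_mut, len, nrow(reads_h3_mut))
  rec$fold_change_h3 <- (rec$fpkm_h3_mut + cfg$pseudocount) /
    (rec$fpkm_h3_wt + cfg$pseudocount)
  if (!is.null(reads_pol_wt)) {
    c_pw <- count_fragments(reads_pol_wt, genes)
    rec$frag_pol_wt <- as.integer(c_pw)
    rec$fpkm_pol_wt <- fpkm(c_pw, len, nrow(reads_pol_wt))
    rec$class <- stratify_expression(rec$fpkm_pol_wt)
  }
  if (!is.null(reads_pol_mut)) {
    c_pm <- count_fragments(reads_pol_mut, genes)
    rec$frag_pol_mut <- as.integer(c_pm)
    rec$fpkm_pol_mut <- fpkm(c_pm, len, nrow(reads_pol_mut))
    rec$fold_change_polII <- (rec$fpkm_pol_mut + cfg$pseudocount) /
      (rec$fpkm_pol_wt + cfg$pseudocount)
  }
  classify(rec, cfg)
}

#' Write a gene occupancy table as TSV
#'
#' Fixed header, floats at 6 significant digits, rows in input order.
#'
#' @param records data.frame from [gene_occupancy()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_table <- function(records, path) {
  out <- records
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene occupancy table written by [write_gene_table()]
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
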