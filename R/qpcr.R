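## ChIP-qPCR normalization calculus: per-histone modification levels
## (mark IP efficiency over the H3 C-terminal — or H4 for AcH4 — reference
## at the same amplicon and genotype), then relative reporting against the
## wild type or against a designated control region (act1, gfr2).

#' A single qPCR measurement
#'
#' @param amplicon Amplicon id.
#' @param mark ChIP target (mark, protein, or reference `H3-Cterm`/`H4`).
#' @param genotype Genotype name.
#' @param efficiencies Replicate IP efficiencies (IP/input fractions, > 0;
#'   at least 2 for a dispersion estimate).
#' @return A `qpcr_measurement` object.
#' @export
qpcr_measurement <- function(amplicon, mark, genotype, efficiencies) {
  if (length(efficiencies) < 2) stopf("need >= 2 replicates for dispersion")
  if (any(efficiencies <= 0)) stopf("IP efficiencies must be > 0")
  structure(list(amplicon = amplicon, mark = mark, genotype = genotype,
                 efficiencies = as.numeric(efficiencies)),
            class = "qpcr_measurement")
}

qpcr_result <- function(amplicon, mark, genotype, level, sd, reference) {
  structure(list(amplicon = amplicon, mark = mark, genotype = genotype,
                 level = level, sd = sd, reference = reference),
            class = "qpcr_result")
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat(sprintf("qpcr_result %s/%s [%s]: %.4g +/- %.4g (ref %s)\n",
              x$mark, x$amplicon, x$genotype, x$level, x$sd, x$reference))
  invisible(x)
}

#' Per-histone modification level
#'
#' Normalizes a mark's IP efficiency to that of the histone reference at
#' the same amplicon and genotype — the H3 C-terminus, or histone H4 for
#' AcH4 — to express the modification level per histone molecule.
#' Replicates are paired by index; the level is the mean of the replicate
#' ratios and the s.d. their sample standard deviation.
#'
#' @param mark_meas `qpcr_measurement` of the modification.
#' @param ref_meas `qpcr_measurement` of the reference (`H3-Cterm`, or
#'   `H4` when the mark is `AcH4`).
#' @return A `qpcr_result` with `level`, `sd`, and the reference used.
#' @export
per_histone <- function(mark_meas, ref_meas) {
  stopifnot(inherits(mark_meas, "qpcr_measurement"),
            inherits(ref_meas, "qpcr_measurement"))
  if (mark_meas$amplicon != ref_meas$amplicon ||
      mark_meas$genotype != ref_meas$genotype)
    stopf("per_histone requires the same amplicon and genotype")
  expected_ref <- if (mark_meas$mark == "AcH4") "H4" else "H3-Cterm"
  if (ref_meas$mark != expected_ref)
    stopf("reference error: mark '%s' must be normalized to %s, not %s",
          mark_meas$mark, expected_ref, ref_meas$mark)
  if (length(mark_meas$efficiencies) != length(ref_meas$efficiencies))
    stopf("pairing error: replicate counts differ (%d vs %d)",
          length(mark_meas$efficiencies), length(ref_meas$efficiencies))
  ratios <- mark_meas$efficiencies / ref_meas$efficiencies
  qpcr_result(mark_meas$amplicon, mark_meas$mark, mark_meas$genotype,
              mean(ratios), stats::sd(ratios), expected_ref)
}

#' Level relative to the wild-type control
#'
#' Divides a per-histone level by the wild-type level at the same amplicon
#' and mark; s.d. propagated to first order (relative s.d.s added in
#' quadrature).
#'
#' @param result `qpcr_result` for the genotype of interest.
#' @param wt_result `qpcr_result` for the wild type.
#' @return A `qpcr_result` with reference `"WT"`.
#' @export
relative_to_wt <- function(result, wt_result) {
  stopifnot(inherits(result, "qpcr_result"), inherits(wt_result, "qpcr_result"))
  if (result$amplicon != wt_result$amplicon || result$mark != wt_result$mark)
    stopf("relative_to_wt requires the same amplicon and mark")
  if (wt_result$level == 0) stopf("wild-type level is 0")
  rel <- result$level / wt_result$level
  rel_sd <- abs(rel) * sqrt((result$sd / result$level)^2 +
                            (wt_result$sd / wt_result$level)^2)
  qpcr_result(result$amplicon, result$mark, result$genotype, rel, rel_sd, "WT")
}

#' Level relative to a control region
#'
#' Replicate-wise ratio of raw IP efficiencies at a locus over those at a
#' designated control region (act1 for K9me2/Swi6, gfr2 for H3), within
#' the same mark and genotype. No per-histone step is applied.
#'
#' @param meas `qpcr_measurement` at the locus of interest.
#' @param control_meas `qpcr_measurement` at the control region, same mark
#'   and genotype.
#' @return A `qpcr_result` referencing the control region id.
#' @export
relative_to_region <- function(meas, control_meas) {
  stopifnot(inherits(meas, "qpcr_measurement"),
            inherits(control_meas, "qpcr_measurement"))
  if (meas$mark != control_meas$mark)
    stopf("relative_to_region requires the same mark (%s vs %s)",
          meas$mark, control_meas$mark)
  if (meas$genotype != control_meas$genotype)
    stopf("relative_to_region requires the same genotype")
  if (length(meas$efficiencies) != length(control_meas$efficiencies))
    stopf("pairing error: replicate counts differ")
  ratios <- meas$efficiencies / control_meas$efficiencies
  qpcr_result(meas$amplicon, meas$mark, meas$genotype,
              mean(ratios), stats::sd(ratios), control_meas$amplicon)
}

## pull one measurement out of a long qPCR table
table_measurement <- function(tbl, amplicon, mark, genotype) {
  sel <- tbl$amplicon == amplicon & tbl$mark == mark & tbl$genotype == genotype
  if (!any(sel)) stopf("no qPCR rows for (%s, %s, %s)", amplicon, mark, genotype)
  eff <- tbl$efficiency[sel][order(tbl$replicate[sel])]
  qpcr_measurement(amplicon, mark, genotype, eff)
}

#' Per-histone levels for a whole qPCR table
#'
#' Applies [per_histone()] to every (amplicon, mark, genotype) combination
#' in a long table, using the matching `H3-Cterm` (or `H4` for AcH4)
#' reference rows, and optionally divides by the wild type.
#'
#' @param tbl Long qPCR table (`amplicon`, `mark`, `genotype`, `replicate`,
#'   `efficiency`), e.g. from [emit_qpcr_table()] or [read_qpcr_table()].
#' @param marks Marks to process (default: all per-histone marks present).
#' @param relative_to `"none"` or `"WT"`.
#' @return data.frame with `amplicon`, `mark`, `genotype`, `level`, `sd`,
#'   `reference`.
#' @export
per_histone_table <- function(tbl, marks = NULL,
                              relative_to = c("none", "WT")) {
  relative_to <- match.arg(relative_to)
  marks <- marks %||% setdiff(unique(tbl$mark),
                              c("H3-Cterm", "H4", "PolII", "Swi6"))
  combos <- unique(tbl[tbl$mark %in% marks, c("amplicon", "mark", "genotype")])
  res <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    ref_mark <- if (cb$mark == "AcH4") "H4" else "H3-Cterm"
    r <- per_histone(table_measurement(tbl, cb$amplicon, cb$mark, cb$genotype),
                     table_measurement(tbl, cb$amplicon, ref_mark, cb$genotype))
    if (relative_to == "WT" && cb$genotype != "WT") {
      wt <- per_histone(table_measurement(tbl, cb$amplicon, cb$mark, "WT"),
                        table_measurement(tbl, cb$amplicon, ref_mark, "WT"))
      r <- relative_to_wt(r, wt)
    } else if (relative_to == "WT") {
      r <- relative_to_wt(r, r)
    }
    data.frame(amplicon = r$amplicon, mark = r$mark, genotype = r$genotype,
               level = r$level, sd = r$sd, reference = r$reference,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write a qPCR table as wide TSV
#'
#' Columns `amplicon`, `mark`, `genotype`, `rep1..repN`.
#'
#' @param tbl Long qPCR table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qpcr_table <- function(tbl, path) {
  wide <- stats::reshape(tbl, idvar = c("amplicon", "mark", "genotype"),
                         timevar = "replicate", v.names = "efficiency",
                         direction = "wide")
  names(wide) <- sub("^efficiency\\.", "rep", names(wide))
  rownames(wide) <- NULL
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide qPCR TSV into the long form
#'
#' @param path TSV with columns `amplicon`, `mark`, `genotype`,
#'   `rep1..repN`.
#' @return Long data.frame (`amplicon`, `mark`, `genotype`, `replicate`,
#'   `efficiency`).
#' @export
read_qpcr_table <- function(path) {
  wide <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  repcols <- grep("^rep[0-9]+$", names(wide), value = TRUE)
  if (length(repcols) == 0) stopf("no rep1..repN columns in %s", path)
  long <- do.call(rbind, lapply(repcols, function(rc) {
    data.frame(amplicon = wide$amplicon, mark = wide$mark,
               genotype = wide$genotype,
               replicate = as.integer(sub("^rep", "", rc)),
               efficiency = wide[[rc]], stringsAsFactors = FALSE)
  }))
  long[order(long$amplicon, long$mark, long$genotype, long$replicate), ]
}
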