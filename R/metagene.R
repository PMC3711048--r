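## TSS/TTS-anchored metagene profiles: per-gene oriented windows, then a
## per-offset median across the genes of each expression class. Positions
## falling outside the chromosome are missing, not zero, and offsets to
## which too few genes contribute are masked.

#' Extract an anchored, oriented window from a track
#'
#' Values are read 5' to 3' in gene orientation: for minus-strand genes the
#' window is taken from mirrored coordinates and reversed. Out-of-bounds
#' positions are `NA`.
#'
#' @param track A `coverage_track` (typically per-million).
#' @param gene One-row data.frame (or list) with `chrom`, `start`, `end`,
#'   `strand`.
#' @param anchor `"TSS"` or `"TTS"`.
#' @param upstream,downstream Window extent in bp; offsets run from
#'   `-upstream` to `+downstream` inclusive.
#' @return Numeric vector of length `upstream + downstream + 1`, named by
#'   offset.
#' @export
extract_window <- function(track, gene, anchor = c("TSS", "TTS"),
                           upstream = 500, downstream = 2000) {
  anchor <- match.arg(anchor)
  if (!gene$strand %in% c("+", "-")) stopf("unknown strand for gene window")
  v <- track$values[[gene$chrom]]
  if (is.null(v)) stopf("gene chromosome '%s' not in track", gene$chrom)
  plus <- gene$strand == "+"
  apos <- if (anchor == "TSS") {
    if (plus) gene$start else gene$end - 1L
  } else {
    if (plus) gene$end - 1L else gene$start
  }
  offsets <- seq.int(-upstream, downstream)
  pos <- if (plus) apos + offsets else apos - offsets
  out <- rep(NA_real_, length(offsets))
  ok <- pos >= 0 & pos < length(v)
  out[ok] <- v[pos[ok] + 1L]
  names(out) <- offsets
  out
}

#' Median profile across genes, per class
#'
#' @param windows_by_class Named list (one element per class) of matrices,
#'   genes in rows, offsets in columns (as from [extract_window()]).
#' @param min_coverage Minimum fraction of genes that must contribute a
#'   non-missing value at an offset; sparser offsets are masked `NA`.
#' @return A `metagene_profile`: list with `offsets`, `classes`, `medians`
#'   (class x offset matrix) and `n` (genes per class).
#' @export
aggregate_median <- function(windows_by_class, min_coverage = 0.5) {
  if (length(windows_by_class) == 0 ||
      any(vapply(windows_by_class, nrow, integer(1)) == 0))
    stopf("every class must contain at least one gene")
  offs <- as.integer(colnames(windows_by_class[[1]]))
  med <- t(vapply(windows_by_class, function(m) {
    cover <- colMeans(!is.na(m))
    md <- apply(m, 2, stats::median, na.rm = TRUE)
    md[cover < min_coverage] <- NA_real_
    md[!is.finite(md)] <- NA_real_
    md
  }, numeric(length(offs))))
  structure(list(offsets = offs, classes = names(windows_by_class),
                 medians = med,
                 n = vapply(windows_by_class, nrow, integer(1))),
            class = "metagene_profile")
}

#' Compute a metagene profile from a track and classified genes
#'
#' Extracts anchored windows for every gene, bins them (mean within bins;
#' a bin is missing when more than half its positions are missing), and
#' takes per-class medians.
#'
#' @param track A per-million `coverage_track`.
#' @param genes data.frame with `id`, `chrom`, `start`, `end`, `strand` and
#'   a `class` column of expression classes.
#' @param anchor `"TSS"` or `"TTS"`.
#' @param upstream,downstream Window extent in bp.
#' @param binwidth Bin width in bp of the offset grid.
#' @param min_coverage Masking threshold, as in [aggregate_median()].
#' @return A `metagene_profile` with attribute `anchor`.
#' @export
compute_metagene <- function(track, genes, anchor = c("TSS", "TTS"),
                             upstream = if (match.arg(anchor) == "TSS") 500 else 2000,
                             downstream = if (match.arg(anchor) == "TSS") 2000 else 500,
                             binwidth = 10, min_coverage = 0.5) {
  anchor <- match.arg(anchor)
  if (is.null(genes$class)) stopf("genes must carry a 'class' column")
  wins <- t(vapply(seq_len(nrow(genes)), function(i)
    extract_window(track, genes[i, ], anchor, upstream, downstream),
    numeric(upstream + downstream + 1)))
  ## bin columns
  offs <- seq.int(-upstream, downstream)
  bin <- (offs + upstream) %/% binwidth
  bstart <- -upstream + unique(bin) * binwidth
  binned <- vapply(unique(bin), function(b) {
    cols <- wins[, bin == b, drop = FALSE]
    frac_na <- rowMeans(is.na(cols))
    v <- rowMeans(cols, na.rm = TRUE)
    v[frac_na > 0.5 | !is.finite(v)] <- NA_real_
    v
  }, numeric(nrow(wins)))
  if (is.null(dim(binned))) binned <- matrix(binned, nrow = nrow(wins))
  colnames(binned) <- bstart
  classes <- as.character(genes$class)
  wbc <- lapply(split(seq_len(nrow(genes)), classes),
                function(i) binned[i, , drop = FALSE])
  ## keep canonical class order where applicable
  canon <- c("Very high", "High", "Medium", "Low")
  ord <- c(intersect(canon, names(wbc)), setdiff(names(wbc), canon))
  prof <- aggregate_median(wbc[ord], min_coverage)
  attr(prof, "anchor") <- anchor
  prof
}

#' Write a metagene profile as TSV
#'
#' Columns `anchor`, `class`, `offset`, `median`, `n`, sorted by (anchor,
#' class, offset); masked offsets are serialized as `NA`.
#'
#' @param profile A `metagene_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  anchor <- attr(profile, "anchor") %||% "TSS"
  rows <- do.call(rbind, lapply(seq_along(profile$classes), function(i) {
    data.frame(anchor = anchor, class = profile$classes[i],
               offset = profile$offsets,
               median = signif(profile$medians[i, ], 6),
               n = profile$n[i], stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$anchor, rows$class, rows$offset), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metagene profile TSV
#'
#' @param path TSV written by [write_profile()].
#' @return data.frame with `anchor`, `class`, `offset`, `median`, `n`.
#' @export
read_profile <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
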