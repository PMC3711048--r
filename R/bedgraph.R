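## bedGraph IO: run-length merged 0-based half-open intervals. Zero runs
## are omitted on write and implied on read, so read(write(t)) is the
## identity given the chromosome sizes.

#' Write a track as bedGraph
#'
#' Runs of equal value are merged; zero-valued runs are omitted.
#'
#' @param track A `coverage_track` or `ratio_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (length(v) == 0) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                       format(r$values[keep], digits = 15, trim = TRUE,
                              scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Read a bedGraph file into a per-base track
#'
#' Bases not covered by any interval are 0. Overlapping intervals are a
#' format error.
#'
#' @param path bedGraph file.
#' @param sizes Chromosome sizes (named vector, `genome_model`, or
#'   chrom.sizes data.frame).
#' @param library_size Optional library size to attach.
#' @param units Units to attach (`"raw"` or `"per-million"`).
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, sizes, library_size = NA, units = "raw") {
  sz <- chrom_sizes(sizes)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  vals <- lapply(sz, numeric)
  if (any(keep)) {
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    if (any(lengths(parts) < 4))
      stopf("bedGraph parse error at line %d: expected 4 fields",
            which(keep)[which(lengths(parts) < 4)[1]])
    chrom <- vapply(parts, `[`, "", 1)
    start <- as.numeric(vapply(parts, `[`, "", 2))
    end <- as.numeric(vapply(parts, `[`, "", 3))
    value <- as.numeric(vapply(parts, `[`, "", 4))
    if (anyNA(start) || anyNA(end) || anyNA(value) || any(start < 0 | start >= end))
      stopf("bedGraph parse error: invalid interval or value")
    if (!all(chrom %in% names(sz)))
      stopf("bedGraph chromosome '%s' not in sizes", setdiff(chrom, names(sz))[1])
    if (any(end > sz[chrom])) stopf("bedGraph interval beyond chromosome end")
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      o <- order(start[sel])
      s <- start[sel][o]; e <- end[sel][o]
      if (length(s) > 1 && any(s[-1] < e[-length(e)]))
        stopf("bedGraph format error: overlapping intervals on %s", ch)
      v <- vals[[ch]]
      for (i in seq_along(s)) v[(s[i] + 1):e[i]] <- value[sel][o][i]
      vals[[ch]] <- v
    }
  }
  coverage_track(vals, library_size = library_size, units = units)
}
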