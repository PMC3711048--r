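## Per-base coverage tracks and track arithmetic — the pileup layer on
## which region calling, gene metrics and metagene profiles operate.

#' Construct a coverage track
#'
#' @param values Named list of per-base numeric vectors, one per chromosome.
#' @param library_size Total number of reads the track was built from.
#' @param units `"raw"` or `"per-million"`.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(values, library_size, units = "raw") {
  stopifnot(is.list(values), !is.null(names(values)))
  units <- match.arg(units, c("raw", "per-million"))
  structure(list(values = lapply(values, as.numeric),
                 library_size = library_size, units = units),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track (%s): %d chromosome(s), library_size %s\n",
              x$units, length(x$values), format(x$library_size)))
  invisible(x)
}

#' Pile up reads into a raw per-base coverage track
#'
#' Each read — optionally extended to `extend_to` bp in its strand
#' direction and clipped at the chromosome ends — increments every base it
#' covers by one. `library_size` is set to the number of reads.
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `strand`.
#' @param sizes Chromosome sizes (named vector, `genome_model`, or
#'   chrom.sizes data.frame).
#' @param extend_to Fragment extension length in bp, or `NULL` for none;
#'   must be >= each read length when given.
#' @return A raw `coverage_track`.
#' @export
pileup <- function(reads, sizes, extend_to = NULL) {
  sz <- chrom_sizes(sizes)
  if (!all(reads$chrom %in% names(sz)))
    stopf("read on unknown chromosome '%s'", setdiff(reads$chrom, names(sz))[1])
  if (any(reads$start < 0 | reads$end > sz[reads$chrom]))
    stopf("read beyond chromosome bounds")
  start <- reads$start
  end <- reads$end
  if (!is.null(extend_to)) {
    if (any(extend_to < end - start))
      stopf("extend_to must be >= read length")
    plus <- reads$strand == "+"
    end[plus] <- start[plus] + extend_to
    start[!plus] <- end[!plus] - extend_to
    start <- pmax(0, start)
    end <- pmin(end, sz[reads$chrom])
  }
  vals <- lapply(names(sz), function(ch) {
    sel <- reads$chrom == ch
    if (!any(sel)) return(numeric(sz[[ch]]))
    cov <- IRanges::coverage(IRanges::IRanges(start[sel] + 1L, end[sel]),
                             width = sz[[ch]])
    as.numeric(cov)
  })
  names(vals) <- names(sz)
  coverage_track(vals, library_size = nrow(reads), units = "raw")
}

#' Normalize a raw track to reads per million
#'
#' @param track A raw `coverage_track` with `library_size > 0`.
#' @return A `coverage_track` in per-million units.
#' @export
normalize_fpm <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$units != "raw") stopf("track is already in per-million units")
  if (is.null(track$library_size) || track$library_size <= 0)
    stopf("library_size must be > 0 to normalize")
  track$values <- lapply(track$values, function(v) v * 1e6 / track$library_size)
  track$units <- "per-million"
  track
}

#' log2 ratio track of two per-million tracks
#'
#' Elementwise `log2((treat + c) / (control + c))` with pseudocount
#' `c > 0`, so the ratio is finite everywhere including gene-free regions.
#'
#' @param treat,control `coverage_track`s in per-million units with
#'   identical chromosome lengths.
#' @param pseudocount Pseudocount `c` in per-million units (default 0.5).
#' @return A `ratio_track` object (named list of per-base log2 ratios plus
#'   the pseudocount).
#' @export
log2_ratio <- function(treat, control, pseudocount = 0.5) {
  stopifnot(inherits(treat, "coverage_track"), inherits(control, "coverage_track"))
  if (pseudocount <= 0) stopf("pseudocount must be > 0")
  if (treat$units != "per-million" || control$units != "per-million")
    stopf("log2_ratio expects per-million tracks")
  if (!identical(names(treat$values), names(control$values)) ||
      !identical(lengths(treat$values), lengths(control$values)))
    stopf("treat and control chromosome lengths differ")
  vals <- mapply(function(a, b) log2((a + pseudocount) / (b + pseudocount)),
                 treat$values, control$values, SIMPLIFY = FALSE)
  structure(list(values = vals, pseudocount = pseudocount),
            class = "ratio_track")
}

#' Bin a track
#'
#' 0-based half-open bins of `width` bp; the last partial bin is summarized
#' over its true width.
#'
#' @param track A `coverage_track` or `ratio_track`.
#' @param width Bin width in bp (>= 1).
#' @param stat `"mean"` or `"sum"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
bin_track <- function(track, width, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  if (width < 1) stopf("bin width must be >= 1")
  out <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    n <- length(v)
    starts <- seq(0L, n - 1L, by = width)
    ends <- pmin(starts + width, n)
    idx <- rep(seq_along(starts), times = ends - starts)
    s <- as.numeric(tapply(v, idx, sum))
    val <- if (stat == "mean") s / (ends - starts) else s
    data.frame(chrom = ch, start = starts, end = ends, value = val,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
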