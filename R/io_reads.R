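## Alignment IO at the package boundary. Internal coordinates are 0-based
## half-open everywhere; BED is native, SAM (1-based) is converted here.

#' Read aligned single-end reads from BED6 or SAM
#'
#' BED intervals are taken as-is (0-based half-open). SAM records are
#' converted from 1-based POS; the reference span is computed from the
#' CIGAR (M/D/N/=/X consume reference); records with the unmapped flag
#' (0x4) are skipped and counted; an `@SQ` header is required and
#' coordinates are checked against it.
#'
#' @param path Input file.
#' @param format `"BED"` or `"SAM"` (default guessed from the extension).
#' @param sizes Optional chromosome sizes (named vector, `genome_model`, or
#'   chrom.sizes data.frame) for bounds checking of BED input.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`. The
#'   number of skipped unmapped records is attached as attribute `skipped`
#'   and reported via [message()].
#' @export
read_alignments <- function(path, format = c("auto", "BED", "SAM"), sizes = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sam = "SAM", bed = "BED",
                     stopf("cannot guess format of '%s'; pass format=", path))
  }
  if (format == "BED") read_bed_reads(path, sizes) else read_sam_reads(path)
}

read_bed_reads <- function(path, sizes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  ln <- which(keep)
  if (length(ln) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  parts <- strsplit(lines[ln], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6))
    stopf("BED parse error at line %d: expected >= 6 fields, got %d",
          ln[which(nf < 6)[1]], nf[which(nf < 6)[1]][1])
  m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0)
    stopf("BED parse error at line %d: invalid interval [%s, %s)",
          ln[bad[1]], m[bad[1], 2], m[bad[1], 3])
  bad_strand <- which(!m[, 6] %in% c("+", "-"))
  if (length(bad_strand) > 0)
    stopf("BED parse error at line %d: strand must be '+' or '-'", ln[bad_strand[1]])
  reads <- data.frame(chrom = m[, 1], start = as.integer(start),
                      end = as.integer(end), strand = m[, 6],
                      stringsAsFactors = FALSE)
  if (!is.null(sizes)) {
    sz <- chrom_sizes(sizes)
    if (!all(reads$chrom %in% names(sz)))
      stopf("BED bounds error: unknown chromosome '%s'",
            setdiff(reads$chrom, names(sz))[1])
    over <- which(reads$end > sz[reads$chrom])
    if (length(over) > 0)
      stopf("BED bounds error at line %d: interval beyond chromosome end", ln[over[1]])
  }
  attr(reads, "skipped") <- 0L
  reads
}

cigar_ref_span <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(regmatches(cigar, ops), function(x) {
    n <- as.integer(sub("[A-Z=]$", "", x))
    op <- sub("^\\d+", "", x)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
}

read_sam_reads <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[hdr][grepl("^@SQ", lines[hdr])]
  if (length(sq) == 0) stopf("SAM file '%s' lacks an @SQ header", path)
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  sl <- as.numeric(sub(".*\tLN:([^\t]+).*", "\\1", sq))
  sizes <- stats::setNames(sl, sn)
  body <- which(!hdr & nzchar(lines))
  if (length(body) == 0) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character())
    attr(out, "skipped") <- 0L
    return(out)
  }
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11))
    stopf("SAM parse error at line %d: expected >= 11 fields", body[which(nf < 11)[1]])
  flag <- as.integer(vapply(parts, `[`, "", 2))
  if (anyNA(flag)) stopf("SAM parse error at line %d: non-numeric FLAG",
                         body[which(is.na(flag))[1]])
  unmapped <- bitwAnd(flag, 4L) != 0L
  n_skip <- sum(unmapped)
  if (n_skip > 0) message(sprintf("read_alignments: skipped %d unmapped SAM record(s)", n_skip))
  parts <- parts[!unmapped]
  kept_ln <- body[!unmapped]
  flag <- flag[!unmapped]
  if (length(parts) == 0) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character())
    attr(out, "skipped") <- n_skip
    return(out)
  }
  chrom <- vapply(parts, `[`, "", 3)
  pos <- as.numeric(vapply(parts, `[`, "", 4))
  cigar <- vapply(parts, `[`, "", 6)
  span <- cigar_ref_span(cigar)
  bad <- which(is.na(pos) | pos < 1 | span <= 0)
  if (length(bad) > 0)
    stopf("SAM parse error at line %d: invalid POS/CIGAR", kept_ln[bad[1]])
  if (!all(chrom %in% names(sizes)))
    stopf("SAM bounds error: RNAME '%s' not in @SQ header",
          setdiff(chrom, names(sizes))[1])
  start <- as.integer(pos - 1)
  end <- as.integer(start + span)
  over <- which(end > sizes[chrom])
  if (length(over) > 0)
    stopf("SAM bounds error at line %d: alignment beyond chromosome end", kept_ln[over[1]])
  reads <- data.frame(chrom = chrom, start = start, end = end,
                      strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
                      stringsAsFactors = FALSE)
  attr(reads, "skipped") <- n_skip
  attr(reads, "sizes") <- sizes
  reads
}

#' Write reads as BED6
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reads_bed <- function(reads, path) {
  df <- data.frame(reads$chrom, as.integer(reads$start), as.integer(reads$end),
                   sprintf("r%d", seq_len(nrow(reads))), 0L, reads$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write reads as a minimal SAM file
#'
#' Emits an `@HD`/`@SQ` header followed by one alignment per read with
#' CIGAR `<len>M`, MAPQ 60 and `*` sequence/quality.
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `strand`.
#' @param sizes Chromosome sizes (named vector or `genome_model`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reads_sam <- function(reads, sizes, path) {
  sz <- chrom_sizes(sizes)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sz), as.integer(sz)))
  len <- reads$end - reads$start
  rec <- sprintf("r%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                 seq_len(nrow(reads)),
                 ifelse(reads$strand == "-", 16L, 0L),
                 reads$chrom, as.integer(reads$start + 1), as.integer(len))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write a chromatin state as TSV
#'
#' Columns: domain, index, chrom, dyad, occupancy, marks.
#'
#' @param state A `chromatin_state`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_state_tsv <- function(state, path) {
  utils::write.table(as.data.frame(state)[, c("domain", "index", "chrom",
                                              "dyad", "occupancy", "marks")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
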