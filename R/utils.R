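## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a reproducible child seed from a base seed and a string tag, so
## that independent sampling steps (per genotype, per ChIP target) consume
## independent but fully determined streams. Kept below 2^31.
derive_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

## chromosome sizes as a named numeric vector, from a genome_model or a
## named vector / two-column data.frame
chrom_sizes <- function(x) {
  if (inherits(x, "genome_model")) {
    stats::setNames(x$chromosomes$length, x$chromosomes$name)
  } else if (is.data.frame(x)) {
    stats::setNames(as.numeric(x[[2]]), as.character(x[[1]]))
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stopf("cannot interpret chromosome sizes from class '%s'", class(x)[1])
  }
}

#' Read a chrom.sizes file
#'
#' Two-column TSV of chromosome name and length in bp.
#'
#' @param path Path to a chrom.sizes file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "length"),
                          colClasses = c("character", "numeric"))
  if (any(df$length <= 0)) stopf("non-positive chromosome length in %s", path)
  stats::setNames(df$length, df$name)
}

#' Write a chrom.sizes file
#'
#' @param sizes Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), as.integer(sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
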