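## Sliding-window Poisson region calling with a local background, in the
## style of MACS's local-lambda scheme: per window, the treat fragment
## count is tested against Poisson(lambda_local), where lambda_local is the
## maximum over several control spans (and the genome-wide mean floor) of
## the library-size-scaled control rate.

#' Region caller configuration
#'
#' @param window Window size in bp.
#' @param step Step between window starts in bp (<= window).
#' @param p_threshold Poisson tail probability threshold in (0, 1);
#'   windows are kept at strictly `p < p_threshold`.
#' @param merge_gap Significant windows closer than this are merged.
#' @param min_length Merged regions shorter than this are dropped.
#' @param local_spans Control spans (bp) over which the local background
#'   rate is estimated; the maximum rate (including the genome-wide mean)
#'   is used.
#' @param fragment_scale bp of coverage contributed per fragment, used to
#'   convert per-base coverage sums into fragment counts; `NULL` infers
#'   the mean span from each track (total coverage / library size).
#' @return A `caller_config` object.
#' @export
caller_config <- function(window = 300, step = 100, p_threshold = 1e-5,
                          merge_gap = 300, min_length = 500,
                          local_spans = c(1000, 5000, 10000),
                          fragment_scale = NULL) {
  if (step > window) stopf("step must be <= window")
  if (p_threshold <= 0 || p_threshold >= 1) stopf("p_threshold must lie in (0, 1)")
  structure(list(window = as.integer(window), step = as.integer(step),
                 p_threshold = p_threshold, merge_gap = as.integer(merge_gap),
                 min_length = as.integer(min_length),
                 local_spans = as.integer(local_spans),
                 fragment_scale = fragment_scale),
            class = "caller_config")
}

## mean of v over [max(0, mid-span/2), min(n, mid+span/2)) via cumulative sums
span_mean <- function(cs, mid, span, n) {
  lo <- pmax(0, mid - span %/% 2)
  hi <- pmin(n, mid + span %/% 2)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

#' Call regions of significant occupancy change
#'
#' Slides windows over each chromosome; in each window the treat fragment
#' count is tested against `Poisson(lambda_local)`. For
#' `direction = "increase"` the upper tail P(X >= k) is used; for
#' `"decrease"` the lower tail P(X <= k). Windows with tail probability
#' strictly below `cfg$p_threshold` are merged when separated by at most
#' `cfg$merge_gap` bp and reported when at least `cfg$min_length` bp long.
#'
#' @param treat,control Raw `coverage_track`s with library sizes set.
#' @param cfg A `caller_config`.
#' @param direction `"increase"` or `"decrease"` (of treat relative to
#'   control).
#' @return data.frame of regions: `chrom`, `start`, `end`, `direction`,
#'   `score` (best-window -log10 p), `fold_change` (mean treat count /
#'   mean expected count over the region's windows).
#' @export
call_regions <- function(treat, control, cfg = caller_config(),
                         direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  stopifnot(inherits(treat, "coverage_track"), inherits(control, "coverage_track"))
  if (treat$units != "raw" || control$units != "raw")
    stopf("call_regions expects raw tracks")
  if (is.null(control$library_size) || is.na(control$library_size) ||
      control$library_size <= 0)
    stopf("control library_size must be > 0")
  if (is.null(treat$library_size) || is.na(treat$library_size) ||
      treat$library_size <= 0)
    stopf("treat library_size must be > 0")
  if (!identical(lengths(treat$values), lengths(control$values)))
    stopf("treat and control chromosome lengths differ")

  tot_t <- sum(vapply(treat$values, sum, numeric(1)))
  tot_c <- sum(vapply(control$values, sum, numeric(1)))
  genome <- sum(lengths(treat$values))
  scale_t <- cfg$fragment_scale %||% (tot_t / treat$library_size)
  scale_c <- cfg$fragment_scale %||% (tot_c / control$library_size)
  if (scale_t <= 0 || scale_c <= 0) stopf("cannot infer fragment scale from empty track")
  lib_ratio <- treat$library_size / control$library_size
  gw_rate <- tot_c / genome  # genome-wide control coverage rate (floor)

  regs <- list()
  for (ch in names(treat$values)) {
    tv <- treat$values[[ch]]
    cv <- control$values[[ch]]
    n <- length(tv)
    if (n < cfg$window) next
    cs_t <- c(0, cumsum(tv))
    cs_c <- c(0, cumsum(cv))
    starts <- seq(0L, n - cfg$window, by = cfg$step)
    mids <- starts + cfg$window %/% 2
    k <- round((cs_t[starts + cfg$window + 1] - cs_t[starts + 1]) / scale_t)
    rate <- rep(gw_rate, length(starts))
    for (span in pmax(cfg$local_spans, cfg$window)) {
      rate <- pmax(rate, span_mean(cs_c, mids, span, n))
    }
    lambda <- rate * cfg$window / scale_c * lib_ratio
    log10p <- if (direction == "increase") {
      stats::ppois(k - 1, lambda, lower.tail = FALSE, log.p = TRUE) / log(10)
    } else {
      stats::ppois(k, lambda, lower.tail = TRUE, log.p = TRUE) / log(10)
    }
    sig <- which(log10p < log10(cfg$p_threshold))
    if (length(sig) == 0) next
    ws <- starts[sig]; we <- ws + cfg$window
    ## merge windows with gaps <= merge_gap
    brk <- c(TRUE, ws[-1] - we[-length(we)] > cfg$merge_gap)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      i <- sig[grp == g]
      r_start <- min(starts[i]); r_end <- max(starts[i]) + cfg$window
      if (r_end - r_start < cfg$min_length) next
      regs[[length(regs) + 1L]] <- data.frame(
        chrom = ch, start = r_start, end = r_end, direction = direction,
        score = max(-log10p[match(i, seq_along(starts))]),
        fold_change = sum(k[i]) / sum(lambda[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(regs) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      direction = character(), score = numeric(),
                      fold_change = numeric()))
  out <- do.call(rbind, regs)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write called regions as BED6
#'
#' Name field holds the direction; the BED score is
#' `min(1000, round(100 * score))`; rows sorted by (chrom, start).
#'
#' @param regions data.frame from [call_regions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_regions <- function(regions, path) {
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  if (nrow(regions) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  df <- data.frame(regions$chrom, as.integer(regions$start),
                   as.integer(regions$end), regions$direction,
                   pmin(1000L, as.integer(round(100 * regions$score))),
                   ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read regions written by [write_regions()]
#'
#' @param path BED6 file.
#' @return data.frame with `chrom`, `start`, `end`, `direction`, `bed_score`.
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      direction = character(), bed_score = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1),
             start = as.integer(vapply(parts, `[`, "", 2)),
             end = as.integer(vapply(parts, `[`, "", 3)),
             direction = vapply(parts, `[`, "", 4),
             bed_score = as.integer(vapply(parts, `[`, "", 5)),
             stringsAsFactors = FALSE)
}
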