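## Stochastic transcription-coupled histone turnover.
##
## Each domain starts fully occupied by "old" histones carrying their
## locus-specific marks (K4me2 in genes; K9me2 in heterochromatin when Clr4
## is active). Pol II passages are drawn Poisson per domain; each passage
## evicts each occupied nucleosome with probability p0 * (1 - retention),
## and after each passage every naked position is refilled with probability
## p_fill (p_fill_5prime within the first k_5prime nucleosomes of a gene)
## by a newly synthesized histone carrying K56Ac only. Marks are never
## re-placed cotranscriptionally: the model loses K4me2/K9me2, it cannot
## regain them.

## dyads of a domain, 5' to 3' in domain orientation
domain_dyads <- function(domain, spacing) {
  half <- floor(spacing / 2)
  d <- seq(domain$start + half, domain$end - 1, by = spacing)
  if (identical(domain$strand, "-")) d <- rev(d)
  d
}

#' Initial chromatin state of a genome model
#'
#' All positions occupied by old histones with their locus-specific marks.
#'
#' @param model A `genome_model`.
#' @param genotype A `genotype` (controls K9me2 placement via `clr4_active`).
#' @return A `chromatin_state`: data.frame with columns `domain`, `index`
#'   (1-based from the domain 5' end), `chrom`, `dyad`, `occupancy`
#'   (`OLD`/`NEW`/`NAKED`) and `marks` (comma-separated, `""` when none).
#' @export
initial_state <- function(model, genotype) {
  dom <- model$domains
  rows <- lapply(seq_len(nrow(dom)), function(i) {
    d <- dom[i, ]
    dy <- domain_dyads(d, model$nucleosome_spacing)
    mark <- if (d$kind == "euchromatic-gene") "K4me2"
            else if (genotype$clr4_active) "K9me2" else ""
    data.frame(domain = d$id, index = seq_along(dy), chrom = d$chrom,
               dyad = dy, occupancy = "OLD", marks = mark,
               stringsAsFactors = FALSE)
  })
  st <- do.call(rbind, rows)
  attr(st, "genotype") <- genotype
  class(st) <- c("chromatin_state", "data.frame")
  st
}

#' Simulate transcription-coupled histone turnover
#'
#' Draws a Poisson number of Pol II passages per domain (rate
#' `passage_rate * epochs`, multiplied by the genotype's `het_derepression`
#' in heterochromatin), then applies per-passage Bernoulli eviction with
#' probability `p0 * (1 - retention)` followed by Bernoulli refill of naked
#' positions. Old histones retain their initial marks; refilled positions
#' become new histones carrying K56Ac only; K4me2/K9me2 are never added.
#'
#' @param model A `genome_model`.
#' @param genotype A `genotype`.
#' @param cfg A `sim_config`; `cfg$seed` makes the run reproducible.
#' @param forced_passages Optional integer: use exactly this many passages
#'   in every domain instead of Poisson draws (used for parameter-recovery
#'   experiments with a known passage count).
#' @return A `chromatin_state` (see [initial_state()]), with the genotype,
#'   config and per-domain passage counts attached as attributes.
#' @export
simulate_turnover <- function(model, genotype, cfg = sim_config(),
                              forced_passages = NULL) {
  stopifnot(inherits(model, "genome_model"), inherits(genotype, "genotype"),
            inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "turnover", genotype$name))
  st <- initial_state(model, genotype)
  p_loss <- cfg$p0 * (1 - genotype$retention)
  dom <- model$domains
  dom$passages <- 0L

  for (i in seq_len(nrow(dom))) {
    d <- dom[i, ]
    rate <- d$passage_rate * cfg$epochs *
      if (d$kind == "heterochromatin") genotype$het_derepression else 1
    n_pass <- if (!is.null(forced_passages)) as.integer(forced_passages)
              else stats::rpois(1, rate)
    dom$passages[i] <- n_pass
    sel <- which(st$domain == d$id)
    if (n_pass == 0L || length(sel) == 0L) next
    occ <- st$occupancy[sel]
    p_fill_vec <- rep(cfg$p_fill, length(sel))
    if (d$kind == "euchromatic-gene")
      p_fill_vec[st$index[sel] <= cfg$k_5prime] <- cfg$p_fill_5prime
    for (p in seq_len(n_pass)) {
      occupied <- occ != "NAKED"
      evict <- occupied & stats::runif(length(occ)) < p_loss
      occ[evict] <- "NAKED"
      naked <- occ == "NAKED"
      fill <- naked & stats::runif(length(occ)) < p_fill_vec
      occ[fill] <- "NEW"
    }
    st$occupancy[sel] <- occ
    st$marks[sel][occ == "NAKED"] <- ""
    st$marks[sel][occ == "NEW"] <- "K56Ac"
  }
  attr(st, "genotype") <- genotype
  attr(st, "config") <- cfg
  attr(st, "model") <- model
  attr(st, "passages") <- stats::setNames(dom$passages, dom$id)
  st
}

## per-nucleosome sampling weight for a ChIP target; used by read sampling
## and by the qPCR emitter so both see the same densities.
##
## AcH3/AcH4 are modeled as a fixed baseline on occupied euchromatic (0.5)
## and heterochromatic (0.1) nucleosomes plus a 0.5 increment on new
## histones, so acetylation tracks turnover. Pol II weight is the domain's
## effective passage rate spread evenly over the domain; Swi6 weight follows
## K9me2 (HP1 reads the mark with no independent dynamics).
.chip_targets <- c("H3", "K4me2", "K9me2", "K56Ac", "AcH3", "AcH4",
                   "PolII", "Swi6", "input")

target_weights <- function(state, target, model, genotype) {
  occ <- state$occupancy != "NAKED"
  has <- function(m) vapply(strsplit(state$marks, ",", fixed = TRUE),
                            function(x) m %in% x, logical(1))
  switch(target,
    H3 = as.numeric(occ),
    K4me2 = as.numeric(has("K4me2")),
    K9me2 = as.numeric(has("K9me2")),
    K56Ac = as.numeric(has("K56Ac")),
    AcH3 = ,
    AcH4 = {
      kind <- model$domains$kind[match(state$domain, model$domains$id)]
      base <- ifelse(kind == "euchromatic-gene", 0.5, 0.1)
      ifelse(occ, base + 0.5 * (state$occupancy == "NEW"), 0)
    },
    PolII = {
      i <- match(state$domain, model$domains$id)
      rate <- model$domains$passage_rate[i] *
        ifelse(model$domains$kind[i] == "heterochromatin",
               genotype$het_derepression, 1)
      rate
    },
    Swi6 = as.numeric(has("K9me2")),
    input = rep(1, nrow(state)),
    stopf("unknown ChIP target '%s'", target))
}
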