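---
title: "Modeling transcription-coupled histone turnover and its ChIP read-out"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling transcription-coupled histone turnover and its ChIP read-out}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histurn)
```

## The biological problem

Histone H3 tails store locus-specific epigenetic information: H3K4
dimethylation (K4me2) marks transcribed euchromatin, H3K9 dimethylation
(K9me2) marks heterochromatin and recruits the HP1 protein Swi6. RNA
polymerase II can displace nucleosomes as it transcribes, so a mark written
on a particular histone molecule survives only as long as that molecule
stays put. In fission yeast the Pol II-associated H3–H4 chaperone Spt6
opposes this displacement. When Spt6 is inactivated, transcription evicts
modified histones, and the gaps are refilled — independently of Spt6 — by
newly synthesized histone H3 that carries K56 acetylation (K56Ac, the
standard marker of new deposition) but none of the locus-specific marks.
The net effect is transcription-coupled turnover: occupancy partially
recovers, but the epigenetic information is diluted away. In the
pericentromere, the Clr3 histone deacetylase restrains turnover in
parallel, so an *spt6* point mutation combined with *clr3Δ* turns over
heterochromatic histones more than either single mutant.

`histurn` implements this model as a stochastic simulator plus the
quantitative ChIP analyses used to observe it: coverage tracks and
mutant/wild-type log2 ratios, Poisson local-background region calling,
per-gene FPKM fold-change classification, TSS/TTS metagene profiles, and
the per-histone ChIP-qPCR normalization calculus.

## The turnover model

The genome model is a set of domains — euchromatic genes in four
transcription strata and pericentromeric heterochromatin blocks — tiled
with nucleosomes at fixed spacing (150 bp). Every position starts occupied
by an *old* histone carrying its locus mark (K4me2 in genes; K9me2 in
heterochromatin when Clr4 is active). For each domain a passage count is
drawn,

\[ n_d \sim \mathrm{Poisson}(\lambda_d \cdot \text{epochs} \cdot
   \text{het\_derepression}), \]

where `het_derepression` applies only in heterochromatin. Each passage
evicts each occupied nucleosome with probability

\[ p_\mathrm{loss} = p_0 (1 - r), \]

with \(p_0\) the eviction probability of an unprotected nucleosome and
\(r \in [0,1]\) the Spt6 retention efficiency (one knob per biological
actor: \(p_0\) for Pol II's intrinsic disruptiveness, \(r\) for the
chaperone). After each passage every naked position is refilled with
probability `p_fill` by a *new* histone carrying K56Ac only; within the
first `k_5prime` nucleosomes of a gene the reduced `p_fill_5prime`
applies, which concentrates net occupancy loss over the first few
nucleosomes downstream of the TSS. Marks are never re-placed
cotranscriptionally: the model can only lose K4me2/K9me2, which makes the
mark counts non-increasing in the passage count — the invariant the test
suite checks. After \(n\) passages with no refilling the surviving old
fraction is \((1 - p_\mathrm{loss})^n\), which is what the
parameter-recovery check exploits: regressing \(\log\) mean old fraction
on a forced passage count recovers \(\log(1 - p_\mathrm{loss})\).

### Genotype presets

| genotype | r | het_derepression | clr4_active |
|---|---|---|---|
| WT | 1.0 | 1 | yes |
| spt6-K20 | 0.3 | 4 | yes |
| spt6Δ | 0.0 | 6 | yes |
| clr3Δ | 0.9 | 8 | yes |
| clr4Δ | 1.0 | 10 | no |
| spt6-K20 clr3Δ | 0.3 | 12 | yes |

Two preset choices deserve comment, because the design was genuinely open:

* **clr3Δ retention is 0.9, not 1.** Under
  \(p_\mathrm{loss} = p_0(1-r)\), a genotype with \(r = 1\) can never
  evict a histone no matter how derepressed its heterochromatin, and the
  observed behavior of *clr3Δ* — elevated pericentromeric K56Ac relative
  to wild type — could not emerge. Clr3 itself prevents histone turnover,
  so the preset gives its deletion a mild retention deficit alongside
  strong derepression. Keeping the knob on the shared retention parameter
  avoids introducing a second eviction pathway.
* **The spt6 mutants also derepress heterochromatin.** Cryptic
  pericentromeric transcription rises when Spt6 is impaired, not only in
  *clr3Δ*/*clr4Δ*; the double mutant is the most derepressed, which is how
  the additive K56Ac behavior of the double mutant emerges from combined
  derepression and low retention.

### Defaults and why

* `p0 = 0.2`, `p_fill = 0.3`: with the top stratum seeing ~8 passages,
  spt6Δ occupancy settles near `p_fill / (p_fill + p0)` = 0.6 of wild
  type at the most transcribed genes — a strong but partial loss, i.e.
  compensation that is real but incomplete.
* `p_fill_5prime = 0.05`, `k_5prime = 3`: refilling is rare over the
  first three nucleosomes, concentrating the loss there.
* strata rates `(8, 4, 2, 0.5)` passages per epoch, `epochs = 1`: spread
  wide enough that the four classes separate in every read-out;
  heterochromatin transcribes at a basal 1 passage per epoch.
* reads: single-end 49 bp from 250-bp dyad-centered fragments, 5%
  uniform background, 10^5 reads per sample by default (tests and the
  acceptance script use 3×10^4 on the 40-gene genome, which already
  gives ~150× coverage).
* qPCR: 3 replicates with lognormal noise at CV 0.1 (unit mean, so zero
  noise is the exact density), IP efficiency = mean target density over
  the amplicon's nucleosomes + background.

The desk-scale genome is 40 genes (10 per stratum, assigned cyclically so
stratum is not confounded with position, strands alternating, 10–20
nucleosomes each) plus one 15-kb heterochromatin block. The
heterochromatic `dg` amplicon is 3 kb where gene amplicons are 600 bp: the
simulator follows a single chromatin fiber, and the wider window stands in
for the population averaging inherent in qPCR of repeat elements —
without it the single-fiber read-out is dominated by integer-count
granularity.

## What the generator does and does not emulate

It emulates: transcription-rate-dependent eviction, retention by Spt6,
Spt6-independent K56Ac-marked refilling with a 5′ deficit, genotype-
dependent heterochromatin derepression, ChIP read sampling with
background and fragment-position jitter, and replicate qPCR noise. It
does **not** emulate replication-coupled turnover or the cell cycle,
nucleosome positioning thermodynamics, sequence content (no FASTQ),
mappability, duplicate reads, or the RNAi pathway. Acetylation (AcH3,
AcH4) is a fixed euchromatic baseline plus an increment on new histones,
so it tracks turnover without independent dynamics, and Swi6 density is
proportional to K9me2 density. Passing tests therefore demonstrate the
internal consistency of the analysis chain and the qualitative behavior
of the turnover model — not performance on real libraries, whose noise
structure (PCR duplicates, mappability, copy number) is richer.

K56Ac persists on deposited histones for the whole simulation. Whether it
decays cotranscriptionally is not established for this system; the
simulator treats it as persistent, and since a simulation spans one
steady-state epoch this only matters for long multi-epoch runs. Whether a
hypomorphic *spt6* allele also impairs deposition is likewise open; only
retention varies by default, and both choices are plain config knobs
(`sim_config()`, `genotype()`).

## Numerical and procedural choices

* **Coordinates** are 0-based half-open everywhere inside the package;
  GFF3 and SAM are converted at the boundary.
* **Pileup** uses run-length coverage; tests hold it to exact equality
  with per-base brute-force counting. Per-million normalization refuses
  to run twice (a units flag).
* **Log ratio** uses pseudocount 0.5 per-million so gene-free regions
  stay bounded.
* **Region caller**: windows of 300 bp at step 100; the treat fragment
  count per window (coverage sum divided by mean fragment span) is tested
  against a Poisson rate taken as the maximum over 1/5/10-kb control
  spans and the genome-wide mean, scaled by library-size ratio. Upper
  tail for increases, lower tail for decreases, strict `p < 1e-5`, merge
  gap 300 bp, minimum region 500 bp. Note the two directions are not
  mirror images: the local-background maximum and the genome-wide floor
  are always estimated from the control track, so an "increase" call on
  swapped tracks is similar, not identical, to a "decrease" call.
* **Fold changes** use an FPKM pseudocount of 0.1 so silent genes do not
  divide by zero; flags use strict inequalities, so a gene at exactly
  0.8-fold or exactly 2-fold is not flagged.
* **Stratification** splits genes at the 25/50/75 percentile ranks of
  reference Pol II FPKM with stable tie-breaking by input order. This is
  a stand-in for an externally defined gene set list.
* **Metagene profiles** use the median (robust to the skew of per-gene
  coverage), fixed TSS −500..+2000 and TTS −2000..+500 windows on a
  10-bp grid, no per-gene rescaling; out-of-bounds positions are missing
  (not zero) and offsets with under 50% gene support are masked.
* **qPCR** pairs replicates by index and reports the mean of ratios, so
  the s.d. reflects replicate dispersion; cross-genotype ratios propagate
  s.d. to first order (relative s.d.s in quadrature).
* **Determinism**: every stochastic step seeds R's RNG from the
  configured seed plus a stream tag (genotype, target), so a run is fully
  reproducible and different targets use independent streams.

## A short session

```{r demo, eval = FALSE}
cfg <- run_config(seed = 1, genotypes = c("WT", "spt6d"))
out <- run_demo(cfg, file.path(tempdir(), "histurn-demo"))
read.delim(file.path(out, "summary.tsv"))
```

The summary reports, per expression class, the median mutant/wild-type H3
fold change and the fraction of genes flagged as significant H3 loss
(< 0.8-fold remaining). With the defaults, the "Very high" class loses
the most H3 and the Spearman correlation between wild-type Pol II FPKM
and H3 fold change across genes is strongly negative, while the
pericentromeric K56Ac-per-H3 level orders double mutant > single mutants
> wild type.

## Known limitations

* One fiber, one epoch: no population heterogeneity beyond sampling
  noise, no replication dilution of marks.
* The region caller reports Poisson tail scores without genome-wide FDR
  control; scores are comparable within a run, not across depths.
* Pol II ChIP density is uniform within a domain (proportional to its
  passage rate), so the caller cannot resolve sub-gene Pol II features.
* The four-class stratification is rank-based; with heavily tied FPKM
  values class boundaries follow input order.
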