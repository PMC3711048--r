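Package: histurn
Title: Transcription-Coupled Histone Turnover Simulation and Quantitative ChIP Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying transcription-coupled nucleosome turnover in
    fission yeast chromatin. Provides a stochastic simulator of Pol II
    passage-driven eviction of modified histone H3 opposed by the Spt6
    chaperone, with refilling by newly synthesized K56-acetylated histones;
    generators of aligned ChIP-seq reads and ChIP-qPCR immunoprecipitation
    efficiency tables for wild-type and mutant genotypes; per-base coverage
    tracks with per-million normalization and log2 ratio tracks; a Poisson
    local-background caller for regions of significant occupancy change;
    per-gene FPKM, fold-change classification and expression stratification;
    TSS/TTS-anchored metagene median profiles; and the per-histone ChIP-qPCR
    normalization calculus used for histone modification levels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
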