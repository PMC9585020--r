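Package: rg4cold
Title: RNA G-Quadruplex Folding, Climate Association and mRNA Decay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking transcriptome nucleotide and RNA G-quadruplex
    (RG4) composition to habitat climate, quantifying in vivo RG4 folding from
    SHALiPE-seq reverse-transcription stop counts (Gini index and folding
    score against in vitro K+/Li+ benchmarks), and estimating mRNA decay rates
    and translation efficiency from transcription-arrest time courses under
    cold versus control conditions. Includes motif scanning for two- and
    three-quartet RG4s, per-region nucleotide composition, Pearson correlation
    of species features against quantile profiles of bioclimatic variables
    with Benjamini-Hochberg adjustment, and fully seeded synthetic-data
    generators with planted ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
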