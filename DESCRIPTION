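Package: tierseq
Title: Mapping Endoribonuclease Cleavage Sites from Differential 5' End Coverage
Version: 0.1.0
Authors@R:
    person("tierseq", "authors", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Identifies endoribonuclease (RNase E) cleavage sites and
    mutant-stabilized 5' ends from comparative single-nucleotide 5'-end
    RNA-seq coverage of a wild-type and a temperature-sensitive nuclease
    mutant strain. Computes strand-aware first-base-in-read coverage,
    performs per-position negative-binomial Wald tests with
    Benjamini-Hochberg correction, clusters candidate positions into sites,
    assigns sites to RNA categories with per-kilobase densities and
    codon-relative positional profiles, and summarizes sequence context as
    position frequency and information-content matrices. A synthetic-data
    module generates complete experiments with known ground truth so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
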