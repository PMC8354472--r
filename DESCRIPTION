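Package: iesevo
Title: Evolution of Internal Eliminated Sequences in Ciliate Germline Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for studying the evolutionary
    dynamics of internal eliminated sequences (IESs), the short TA-bounded
    germline-limited segments that ciliates such as Paramecium excise from
    their developing somatic (MAC) genome. The package simulates IES
    gain/loss histories and mobile-element bursts on a species phylogeny,
    reconstructs ancestral IES states with a two-rate presence/absence
    Markov model sampled by MCMC, maps posterior changes onto species-tree
    branches through duplication-aware path enumeration to estimate
    per-branch gain and loss rates, detects floating (ambiguously located)
    IESs, clusters interspersed mobile-IES families with profile scanning,
    and estimates germline genome size from k-mer histograms with a
    correction for contaminating somatic DNA driven by IES retention
    scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    stringi,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
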