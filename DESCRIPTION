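Package: onfhost
Title: Alignment-Free Oligonucleotide Frequency Virus-Host Prediction
Version: 0.1.0
Authors@R:
    person("onfhost", "developers", email = "onfhost@example.org",
           role = c("aut", "cre"))
Description: Predicts the prokaryotic host of viral genomes and metagenomic
    contigs from oligonucleotide frequency (ONF) similarity. Implements eleven
    alignment-free distance/dissimilarity measures between k-mer profiles,
    including the Markov-background-corrected d2* and d2S statistics, with
    per-genome background models of configurable order (selectable by BIC).
    Host calls are made by nearest-host search, top-n consensus voting,
    dissimilarity thresholding and a Wilcoxon rank-sum taxon test, and are
    scored by per-rank accuracy/recall, ROC AUC and an empirical random-guess
    baseline. A Markov-chain simulator generates self-contained virus/host
    benchmarks with tunable compositional amelioration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
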