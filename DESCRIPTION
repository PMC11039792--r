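Package: oralflux
Title: Oral-to-Rectum Microbial Translocation Analysis from Paired Amplicon Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies translocation of tongue bacteria into the rectal
    microbiota from paired 16S rRNA amplicon sequence variant (ASV) tables.
    Provides read filtering and dual-tag demultiplexing for multiplexed
    amplicon libraries, nearest-neighbor species assignment against an
    eHOMD-style reference with negative-control contaminant exclusion,
    per-participant tongue-ASV identification and translocation scoring,
    intra- versus inter-pair sharing comparisons on log-scale Bray-Curtis
    distances, exact nonparametric rank tests (shift-algorithm Wilcoxon
    signed-rank and rank-sum, Kruskal-Wallis with rank eta-squared,
    Steel-Dwass all-pairs comparisons), SparCC compositional correlation
    networks with thresholded cohabiting groups, and a Dirichlet-multinomial
    paired-cohort simulator with known translocation structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vegan,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
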