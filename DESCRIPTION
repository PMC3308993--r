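Package: plastidcomp
Title: Comparative Analysis of Plastid Genome Architecture and Gene Content
Version: 0.1.0
Authors@R:
    person("Plastidcomp", "Developers", email = "plastidcomp@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated plastid
    (chloroplast) genomes: per-genome feature summaries (size, GC, gene
    counts, intron content, coding density), detection of inverted repeats
    and the quadripartite LSC/SSC/IR architecture of circular plastid
    chromosomes, coding-strand switch-point detection, tandem-repeat
    (VNTR) finding, a gene-order conservation statistic based on shared
    adjacent gene pairs, gene-content set partitions across genomes, and a
    classifier for the fate of plastid genes missing relative to an algal
    reference (endosymbiotic transfer to the nucleus versus outright
    loss, using transcriptome presence/absence evidence). A synthetic
    genome generator with full ground truth makes every stage testable
    offline. Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
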