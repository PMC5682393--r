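Package: notophylo
Title: Chloroplast and Nuclear Phylogeography of Notopterygium Herbs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Haplotype-based phylogeographic analysis for aligned chloroplast
    and nuclear ribosomal (ITS) sequence data, built around the alpine herb
    genus Notopterygium. Provides IUPAC ambiguity phasing and haplotype
    collapsing, haplotype and nucleotide diversity, Pons-Petit GST/NST
    differentiation with the permutation U-test, hierarchical AMOVA with
    Phi-statistics, Tajima's D, Fu & Li's F* and Fu's Fs neutrality tests with
    coalescent null distributions, mismatch-distribution sudden-expansion
    fitting with SSD and Harpending's raggedness bootstrap tests and
    expansion-time dating, median-joining haplotype networks, a strict-clock
    net-divergence dating surrogate, and a seeded coalescent simulator
    (island model, clean splits, sudden expansion) used to exercise every
    stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
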