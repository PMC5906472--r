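Package: denovoprom
Title: Mutational Accessibility of Sigma70 Promoters and Avoidance of
    Accidental Intragenic Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying de novo promoter emergence in bacteria.
    Generates GC- and homopolymer-filtered random sequences, scores them
    for sigma70 promoters with a position weight matrix (with spacer-length
    weights and a calibrated threshold) or with the core-motif criterion
    (TTGnnn and TAnnnT with a valid spacer), and computes the mutational
    distance separating a sequence from promoter activity. For coding
    regions, builds synonymous-recoding and codon-shuffle null ensembles,
    scores putative accidental intragenic promoters per gene (sense and
    antisense, per kb), ranks wild-type genes against their null ensembles
    in percentiles and deciles, contrasts gene groups (essential,
    toxin/antitoxin) with Kolmogorov-Smirnov and exact sign tests, and
    profiles six-mer depletion relative to the recoded null. A synthetic
    genome generator with known ground truth supports end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
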