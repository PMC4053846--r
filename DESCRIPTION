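Package: EditScreen
Title: Cross-Species Conservation Screening for A-to-I RNA Editing Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies evolutionarily conserved adenosine-to-inosine (A-to-I)
    RNA editing sites by aligning the 81-nt genomic windows flanking candidate
    edited adenosines between two species and requiring high sequence identity
    together with positional correspondence of the edited base. Includes a
    SNP-based signal-to-noise calibration of the screen, strand-aware editing
    level quantification from samtools mpileup text with base-quality
    filtering, site-by-sample editing matrices, and downstream conservation
    statistics: site accumulation curves, neighbor-preference motif matrices,
    genomic-region and recoding classification, detection of candidate exon
    complementary sequences (ECS), and the genomic G-reversion asymmetry
    analysis. Seeded simulators generate diverged ortholog genome pairs,
    planted site panels, SNP controls and multi-strain pileups with ground
    truth, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
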