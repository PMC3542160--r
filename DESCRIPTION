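Package: mirphas
Title: Small RNA Discovery, Degradome Target Validation and tasiRNA Phasing
Version: 0.1.0
Authors@R:
    person("Plant sRNA", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale re-usable pipeline for plant small-RNA analysis:
    adapter trimming, read collapsing and exact genome mapping with
    reads-per-million normalization; assignment of tags to known miRNA
    families and removal of non-coding RNA look-alikes; de novo miRNA locus
    calling from hairpin secondary structure (maximum base-pair folding,
    duplex mismatch and bulge filters, star-strand detection, read-support
    fractions); degradome (PARE) target validation with complementarity
    scoring, t-plots and category 0-4 classification; 21-nt phased tasiRNA
    register analysis anchored at cleavage sites; and precursor processing
    efficiency statistics (APE/RTA) from band-intensity tables. Includes a
    synthetic-data generator that plants miRNA hairpins, TAS-like loci and
    degradome signals with known ground truth, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
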