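Package: amplikit
Title: Microfluidic Amplicon Demultiplexing, Allele Recovery and Target
    Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for processing highly multiplexed microfluidic PCR
    amplicon sequencing runs built on a four-primer, dual combinatorial
    barcode design. Demultiplexes paired-end reads into sample-by-target
    pools using edit-distance barcode lookup and anchored ("firm end")
    fuzzy primer matching; reduces each pool to strict or IUPAC-ambiguity
    consensus sequences, or recovers individual alleles by absolute and
    relative read-frequency thresholds; aggregates allele counts into
    minimum-ploidy calls; selects variable amplification targets from
    multiple sequence alignments; and simulates complete runs with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
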