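Package: readtiler
Title: Reverse Read-Mapping of Short-Read Libraries by Suffix-Array Tiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Indexes short-read sequencing libraries (FASTA/FASTQ) with a
    suffix array for exact-substring occurrence counting, and queries the
    index by k-mer tiling of an arbitrary reference sequence to produce
    per-position "starts" and "coverage" profiles. Includes a small-RNA
    layer that quantifies miRNA mature and star arms from precursor
    profiles, generates per-library miRNA summary reports, and screens for
    potentially mis-annotated miRNAs by flagging precursors whose
    mature-plus-star tile counts fall below 95% of the precursor total. A
    controlled-vocabulary catalog filters library metadata, and a
    planted-read simulator provides libraries with analytically known
    profiles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    graphics,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
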