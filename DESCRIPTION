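Package: readtrim
Title: Adapter and Quality Trimming of Short Sequencing Reads with
    Insert-Match Overlap Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes adapter sequence and low-quality bases from single-
    and paired-end short sequencing reads. Adapters are located either by
    IUPAC-aware semi-global alignment with an intuitive maximum-error-rate
    acceptance rule, or, for read pairs, by an insert-match algorithm that
    detects the overlap between read 1 and the reverse complement of
    read 2 and infers the adapter start positions from the fragment
    geometry. Companion tools detect unknown adapters de novo by iterative
    k-mer profiling, estimate sequencing error rates from base qualities,
    collect quality-control metrics, simulate adapter-contaminated read
    pairs with ground truth, and score trimming accuracy against that
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    data.table,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
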