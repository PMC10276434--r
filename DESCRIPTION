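Package: wkdict
Title: Weighted k-mer Dictionaries with Run-Length Compressed Abundances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An exact, associative and order-preserving dictionary for k-mers
    and their abundance counts (weights) built over a spectrum-preserving
    string set (SPSS). Weights are compressed as runs: the run values are
    coded against a distinct-value table and the run boundaries are stored as
    an Elias-Fano monotone sequence, so retrieval of a weight is a predecessor
    query. The package also implements an optimal linear-time algorithm that
    reorders and reorients the input strings to minimise the number of runs,
    by computing a minimum-cardinality path cover of the end-point weight
    graph of the collection, together with the constant-time min-key /
    decrease-by-two tracker that drives the even-frequency merging phase.
    Includes readers and writers for weighted FASTA dialects (BCALM2 'ab:Z:'
    headers and plain counts), seeded synthetic generators, and exhaustive
    oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
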