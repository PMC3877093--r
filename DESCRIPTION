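Package: tapir
Title: Identification of Organisms from Raw Sequencing Reads by k-mer
    Index Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A DNA "search engine" for identifying the organism(s) behind a
    set of raw sequencing reads without pre-specifying a reference genome.
    Reference sequences are split into non-overlapping k-mers (k = 16,
    bit-packed two bits per base) and indexed into a presence store (k-mer to
    references), a position store (k-mer and reference to in-phase positions)
    and a reference catalog.  A small random sample of reads is scored by
    overlapping k-mer lookup and positional match clustering, producing a
    ranked hit list of candidate references.  An iterative align-and-subtract
    workflow resolves mixtures: fetch the top candidates, map all unmapped
    reads against each, keep the reference minimizing the unmapped count, and
    recurse on the remainder.  Includes a synthetic read simulator and
    benchmark harness, and a JSON query/retrieval service layer so an index
    can be hosted remotely and queried with low bandwidth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    curl,
    httpuv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
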