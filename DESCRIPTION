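Package: incblast
Title: Incremental Local-Alignment Searches via E-Value Recalibration and
    Result Merging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recalibrates the expect values (e-values) of NCBI BLAST search
    results when the reference database grows over time or is searched in
    disjoint partitions, and merges per-partition results into a single
    result equivalent to a from-scratch search of the combined database.
    Implements Karlin-Altschul length adjustment and e-value recomputation
    for nucleotide programs, ratio rescaling for the finite-size-correction
    (Spouge) statistics used by protein programs, readers and writers for
    BLAST XML (outfmt 5) and tabular (outfmt 6/7) results, a search-record
    store and delta-database logic for incremental searching, a
    residue-balanced query partitioner, and a synthetic-scenario generator
    with brute-force statistical oracles for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
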