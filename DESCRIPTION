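Package: mirtail
Title: Quantification of miRNA Expression and 3' Non-Templated Tailing from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for small RNA deep-sequencing analysis of
    mature microRNA expression and 3' end modification. Reads are adapter
    trimmed and length filtered, multi-hit alignments are reduced to the
    minimum-mismatch stratum per read, tags are assigned to mature miRNAs by
    a strand-aware +/- 3 nt 5' start window, and counts are normalised to
    counts per million (CPM). Tags one nucleotide longer than the annotated
    mature sequence are classified as templated extensions or non-templated
    additions (NTA) per nucleotide, yielding per-miRNA mono-uridylation
    percentages, between-condition changes, and quartile ranks. A synthetic
    data module generates toy genomes, miRBase-style annotations and
    two-condition read sets with known ground truth so that every stage of
    the pipeline is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    data.table,
    jsonlite,
    S4Vectors,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
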