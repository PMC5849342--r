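Package: profdiff
Title: Differential ChIP-Seq Enrichment from Base-Resolution Coverage Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls differentially enriched genomic regions between two ChIP-seq
    conditions from base-resolution coverage profiles. Reads are extended to
    fragment length, depth-normalized per million, input-subtracted, unit-scaled
    and discretized on an overlapping sliding-window grid; replicate-combined
    case and control profiles are subtracted to a signed difference profile,
    noise-filtered at a standard-deviation cutoff, merged into same-sign
    candidate regions and tested with a two-sided two-sample Kolmogorov-Smirnov
    test under Benjamini-Hochberg correction. Also provides strand-aware
    peak-to-gene assignment, position-weight-matrix scanning with exact score
    p-values, reporter-element construction and validation, delta-delta-Ct
    quantification, fold-change list filtering, a one-tailed Fisher overlap
    test, and a spike-in read simulator with ground truth for end-to-end
    verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
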