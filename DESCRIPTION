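Package: rvescore
Title: Evidence Scoring for Regulatory Variants in Rare Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the Regulatory Variant Evidence score (RVE-score) for
    a candidate regulatory variant and its suspected target gene. Evidence
    for 24 clinical and functional criteria is gathered from local
    annotation sources (per-base conservation scores, population allele
    frequencies, deleteriousness scores, transcription-factor binding
    regions and candidate regulatory elements) and from user-supplied
    answers, binarized against rubric thresholds, weighted and summed into
    the clinical C-score, the functional F-score and their total, the
    RVE-score. The score is ranked against a reference distribution of
    curated regulatory variants and emitted as JSON, TSV and markdown
    reports with full per-criterion provenance. Includes a command-line
    interface and a deterministic synthetic-fixture generator so the whole
    pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    optparse,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
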