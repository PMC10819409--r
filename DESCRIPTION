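Package: crisproff
Title: Off-Target Prediction and Whole-Genome Screening of CRISPR-Edited Clones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for assessing unintended genetic variation in CRISPR/Cas-edited
    cell clones from whole-genome sequencing. Provides an ensemble in-silico
    off-target site search (mismatch- and bulge-tolerant, PAM-aware, both strands,
    run under several tool-like sensitivity profiles), screening of clone-versus-parent
    somatic variant calls by filter status, genotype pattern, read depth and allele
    fraction, 200-bp window cross-referencing of screened variants against predicted
    sites, an ungapped guide string-search screen, dual-caller CNV concordance and
    de novo CNV classification, and cohort-level rate comparisons by pooled-variance
    t-test. A deterministic synthetic-data generator plants guide matches, paired
    variant calls and CNV call sets with machine-readable truth so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
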