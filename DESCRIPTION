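Package: vepforest
Title: Transcript-Aware Variant Effect Prediction with Class-Specific
    Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Routes intragenic DNA variants to five prediction classes
    (single amino-acid exchange, complex protein change, 5' UTR, 3' UTR,
    other intragenic) on transcript models built from FASTA and GTF input,
    extracts per-class features (maximum-entropy splice-site score changes
    at canonical donor/acceptor windows, Kozak-context and polyadenylation-
    signal checks, conservation, amino-acid exchange properties), applies
    automatic benign/deleterious labelling rules driven by population
    homozygote counts and clinical assertions, trains per-class Random
    Forest classifiers for balanced accuracy with a smallest-forest grid
    search, and runs a cached single-sample VCF analysis pipeline that
    reports tree votes. Includes a deterministic synthetic-data generator
    emulating genomes, transcripts, resource tables and labelled variant
    sets.
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
    randomForest,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
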