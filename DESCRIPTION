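Package: ibdtrace
Title: Parental Allele Tracing, IBD Segments, and Allele-Effect Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Traces the parental and ancestral origin of every SNP in
    pedigreed inbred lines from raw biallelic marker data, compiles
    identity-by-descent (IBD) segments and recombination breakpoint
    intervals, converts origin labels into per-source allele effect
    estimates (class-mean deviations from the population mean), and uses
    the resulting numeric matrix in place of raw marker codes in
    ridge-regression BLUP genomic prediction.  Includes a pedigreed
    meiosis simulator with ground-truth origins and founder-specific QTL
    so the whole pipeline is testable without external data, and a
    command-line interface wiring the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
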