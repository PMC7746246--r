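Package: captureseq
Title: Targeted RNA-Seq Capture Panel Design and Enrichment Evaluation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for targeted RNA sequencing (CaptureSeq) studies:
    rule-based design of hybridization-capture target panels from gene
    annotation, GWAS linkage-disequilibrium blocks, repeat and EST tracks;
    evaluation of capture enrichment at the library and gene level,
    including segmented linear regression with AICc model selection to
    locate the pre-capture expression level below which enrichment
    estimates become unstable; ERCC-style spike-in sensitivity and
    quantitation QC (CPKM dose-response slope, Spearman correlation,
    detection thresholds); reference-stage expression correlation; and a
    generative simulator of pre- and post-capture libraries with
    low-input dropout for validation without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
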