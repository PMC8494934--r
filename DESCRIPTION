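Package: omicGRN
Title: Temporally Informed Multi-Omic Gene Regulatory Network Inference
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative network inference from time-course transcriptome,
    proteome and phosphoproteome experiments. Provides isobaric-label (TMT)
    sample-loading and internal-reference normalization, per-timepoint
    differential-expression calling with layer-specific thresholds, dynamic
    time warping and independent component analysis clustering of temporal
    profiles, cluster-restricted tree-ensemble inference of transcription
    factor to target regulations from separate regulator and target matrices,
    correlation-based kinase signaling networks built from activation-loop
    phosphosites, network motif scoring (feed-forward, feedback, diamond and
    bi-fan motifs), and a synthetic multi-omic time-course generator with a
    planted kinase to transcription-factor to transcript cascade for
    benchmarking edge recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    cluster,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
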