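Package: genecov
Title: Gene-Centric Transcriptome Coverage Across Sequencing Platforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-centric analysis of transcriptome coverage measured on
    multiple quantification platforms (short-read RNA-Seq in FPKM, nanopore
    direct RNA sequencing in TPM, and qPCR in copies per cell). Builds a
    protein-coding gene universe from a GTF annotation, derives detection
    sets under platform cut-off rules, sweeps cut-offs, tabulates
    per-chromosome coverage with inclusion-exclusion platform unions,
    computes Tanimoto set similarity with interpretation bands, multi-set
    Venn decompositions and an inter-donor variability statistic, and fits
    log-log calibration models converting relative abundance to absolute
    copies per cell. Includes a synthetic multi-donor, multi-platform data
    generator emulating the detection characteristics of each platform.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
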