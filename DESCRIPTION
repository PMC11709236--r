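Package: ThermoTrout
Title: Comparative Transcriptomics of Thermal Tolerance in Rainbow Trout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for contrasting high- and
    low-thermal-tolerance rainbow trout against controls with bulk RNA-seq:
    TPM/RPKM normalization, negative-binomial differential expression with
    filtered FDR correction, cross-strain shared-gene accounting with Venn
    summaries, consolidation of salmonid duplicate genes onto mammalian
    orthologues with strain-mismatch rates, GO-slim overrepresentation by a
    backward-elimination heterogeneity G-test, pathway and upstream-regulator
    filtering rules, and a Functional Effects Group (FE_g) score with a
    two-group proportion test. A seeded negative-binomial simulator with
    planted truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
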