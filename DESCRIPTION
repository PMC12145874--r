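Package: phresp
Title: Growth and Gene-Set Transcriptomic Response Analysis Across pH Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for common-garden experiments comparing microbial
    strains across environmental pH conditions. Estimates exponential growth
    rates from fluorescence time series and contrasts them nonparametrically
    (Kruskal-Wallis with Dunn post-hoc tests and compact letter displays),
    scores genes from differential-expression tables with signed ln(FDR)
    (SLFDR) values, and detects affected gene sets with three complementary
    enrichment methods: functional class scoring against a gene-sampling null,
    chi-square over-representation analysis, and the deterministic
    unidirectional gene-set (UGS) criterion. Composite calls are grouped into
    strain-pH enrichment groups and clustered by square-root-transformed
    Jaccard dissimilarity. A seeded synthetic-data generator emulating the
    experimental design makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    igraph,
    jsonlite,
    yaml,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    fgsea
Config/testthat/edition: 3
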