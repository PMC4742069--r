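Package: riboshift
Title: Ribosome Profiling QC, Expression Thresholding, and Translational
    Efficiency Shift Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for paired ribosome profiling (Ribo-seq) and
    mRNA-Seq experiments in transcript coordinates: sequencing-validity
    diagnostics (replicate correlation, triplet periodicity, metagene
    start-codon density and peak calling), a binomial-partitioning
    minimum-expression threshold that separates counting noise from
    biological inter-replicate variation, translational-efficiency
    computation with a Kolmogorov-Smirnov shift test for TOP-motif genes,
    PCA of expression profiles, and per-group correlation plus
    backward-elimination multiple regression for a small qPCR/western
    expression panel. A seeded synthetic footprint simulator generates
    annotation, aligned reads, count tables, and expression panels with the
    statistical structure the analysis assumes, so the whole chain runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    ggplot2
VignetteBuilder: knitr
Config/testthat/edition: 3
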