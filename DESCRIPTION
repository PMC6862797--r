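Package: popmeth
Title: Population-Scale DNA Methylation Analysis for Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for population epigenomics in fully inbred panels assayed by
    bisulfite sequencing. Summarizes per-cytosine methylation calls into 20-bp
    windows per sequence context (CG, CHG, CHH), calls differentially methylated
    regions (DMRs) across hundreds of genotypes with a two-step pairwise/consensus
    algorithm, classifies context specificity, computes minor epiallele
    frequencies and subgroup-specific DMR tests, estimates genetic and epigenetic
    relationship matrices (with probabilistic PCA for missing data), maps
    methylation QTL with an EMMAX-style mixed linear model, associates DMRs with
    expression and metabolite traits through a two-step residual model, and tests
    causal direction between methylation and expression by Mendelian
    randomization. A synthetic-data generator with planted DMRs, mQTL and causal
    chains makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
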