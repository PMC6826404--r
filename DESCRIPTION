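Package: cernet
Title: Inference of lncRNA-miRNA-mRNA Competing-Endogenous-RNA Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring lncRNA-associated competing-endogenous-RNA
    (ceRNA) networks from two-condition RNA-seq count data, as applied to
    chicken preadipocyte differentiation. Implements FPKM/TPM normalization,
    differential-expression gating, Spearman co-expression filtering of
    predicted miRNA-target interactions, a hypergeometric shared-miRNA test
    for candidate lncRNA-mRNA sponge pairs, tripartite network construction
    with hub and crucial-interaction selection, and gene-set
    over-representation analysis. Includes a seeded negative-binomial
    simulator that plants differentially expressed genes and ceRNA triples
    so the full pipeline can be validated against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
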