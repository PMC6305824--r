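Package: dcgnet
Title: Differential Connectivity Analysis of Two-Condition Gene Networks
Version: 0.1.0
Authors@R:
    person("dcgnet", "maintainers", email = "maintainers@dcgnet.org",
           role = c("aut", "cre"))
Description: Infers condition-specific gene co-regulation networks from
    two-condition log2 expression data using shrinkage Gaussian graphical
    models (analytic Schafer-Strimmer shrinkage of the sample correlation
    matrix toward the identity, partial correlations from the inverted
    shrunk correlation matrix), ranks genes by exact betweenness centrality
    in each network, and extracts differentially connected genes (DCGs) as
    condition-specific hubs: genes in the top betweenness fraction of the
    cancer network but absent from the normal network's top fraction.
    Includes per-dataset differential-expression calling (per-gene Welch t
    test, Benjamini-Hochberg adjustment, fold-change thresholds) with
    multi-dataset intersection into mutual DEGs, hypergeometric gene-set
    over-/under-representation, TF-regulon lookup, a synthetic-data
    generator with planted precision-matrix structure and known hubs for
    ground-truth validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
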