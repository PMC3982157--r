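Package: disptm
Title: Proteome-Wide Correlation of Intrinsic Disorder with
    Post-Translational Modification Sites in Plants
Version: 0.1.0
Authors@R:
    person("disptm", "maintainers", email = "disptm@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the association between intrinsic protein
    disorder and predicted post-translational modification (PTM) sites
    across plant proteomes. Provides FASTA/TSV/YAML input handling,
    dataset construction (length filtering and greedy redundancy
    reduction at a global-identity cutoff), sequence-motif scanners for
    the plant hydroxyproline O-glycosylation consensus and the
    N-glycosylation sequon, disorder summary statistics, the disorder-
    to-order enrichment ratio Rd/o = (Nd/Ld)/(No/Lo), site-count binning
    with bin-level mean disorder, Pearson correlation with one-tailed
    Student-t significance, a synthetic proteome generator with planted
    disorder structure and PTM enrichment for ground-truth validation,
    and a pipeline driver emitting publication-shaped result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
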