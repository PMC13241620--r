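Package: immunorep
Title: Bulk RNA-Seq Immune Repertoire Analysis for Steroid-Phenotype
    Stratified Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Repertoire", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for downstream analysis of adaptive immune receptor
    repertoires (BCR: IGH, IGK, IGL; TCR: TRA, TRB, TRD, TRG) extracted
    from bulk tumor RNA-seq. Reads AIRR Rearrangement TSV tables and the
    TRUST4 simple-report dialect, applies a productive/complete-CDR3
    filter, groups rearrangements into clones by shared V gene, J gene,
    CDR3 length and CDR3 nucleotide identity (single linkage, 90% for BCR
    and 95% for TCR), and computes per-chain repertoire metrics
    (abundance, clones per kiloread, Shannon entropy, clonality).
    Provides phenotype- and stage-stratified nonparametric comparisons
    with Benjamini-Hochberg FDR control, Spearman correlation against
    marker-gene expression and signature scores, Kaplan-Meier/log-rank
    and multivariate Cox survival models with chain-interaction
    covariates, and a fully parameterised synthetic-cohort generator so
    the whole pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
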