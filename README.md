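# immunorep

Downstream analysis of adaptive immune receptor repertoires extracted from
bulk tumor RNA-seq, for cohorts stratified by steroid phenotype (LSP = low
steroid phenotype, HSP = high steroid phenotype). Written for
adrenocortical-carcinoma-style cohorts where hormone excess reshapes the
tumor immune microenvironment, but applicable to any bulk-RNA-seq cohort
with per-sample rearrangement tables and a two-level phenotype label.

Because bulk RNA-seq cannot pair receptor chains, each of the seven loci —
BCR: IGH, IGK, IGL; TCR: TRA, TRB, TRD, TRG — is analysed separately.

## What it computes

* **Ingestion** of AIRR Rearrangement TSVs and the TRUST4 simple-report
  dialect; productivity filter (in-frame, no premature stop codon, complete
  CDR3).
* **Clone identification**: rearrangements sharing V gene, J gene and CDR3
  length are clustered by CDR3 nucleotide identity (single-linkage
  connected components) at ≥ 0.90 identity for BCR and ≥ 0.95 for TCR.
* **Per-chain repertoire metrics** from clone read counts
  \(n_1,\dots,n_R\), \(p_i = n_i/\sum n_j\):
  abundance \(\sum n_i\); CPK = unique clones per thousand total library
  reads; Shannon entropy \(H=-\sum p_i \ln p_i\); clonality
  \(C = 1 - H/\ln R\) (defined for \(R\ge 2\)).
* **Statistics**: two-sided Mann–Whitney U (exact for small tie-free
  samples), Kruskal–Wallis + Dunn post hoc, Benjamini–Hochberg FDR within
  per-panel families, Spearman correlation of chain metrics against marker
  expression and mean-marker signature scores, pooled and per stratum.
* **Survival**: Kaplan–Meier with log-rank on within-stratum
  median-dichotomized metrics (ties to Low), and multivariate Cox
  (Efron ties, HSP reference, ordinal stage, log2(x+1) metric covariates,
  chain-interaction terms IGH:IGK, IGH:IGL, TRA:TRB).
* **Synthetic cohorts**: a generator whose defaults encode a 31 LSP / 47
  HSP cohort with ≈3:1 (BCR) and ≈10:1 (TCR) group read ratios, a flatter
  Zipf clone-size law in LSP, phenotype-coupled marker expression, and
  exponential survival with a protective LSP hazard ratio of ≈ 0.1 — plus a
  phenotype-symmetric `null` preset for calibration studies.

See `vignettes/immunorep-methods.Rmd` for the model, parameter and
numerical-design details.

## Worked example

```r
library(immunorep)

params <- simulation_params(loci = c("IGH", "IGK", "IGL", "TRA", "TRB"),
                            read_scale = 0.5)
co <- simulate_cohort(params, seed = 7)

m <- cohort_metrics(co$repertoires)       # filter -> clones -> metrics
summarize_detection(m)
#> 78 cases: 21 BCR-only, 0 TCR-only, 57 both, 0 neither
#> detectable repertoire: 100.0% (no detection: 0.0%)

labels <- setNames(co$clinical$phenotype, co$clinical$sample_id)
res <- compare_metric_by_group(m, labels, metric = "entropy")
res[res$testable, c("metric", "n_a", "n_b", "median_a", "median_b",
                    "p_raw", "p_adj")]
#>        metric n_a n_b median_a median_b    p_raw    p_adj
#> 1 IGH_entropy  31  47    2.145    0.577 8.33e-08 4.16e-07
#> 2 IGK_entropy  31  46    1.818    0.665 5.23e-05 1.31e-04
#> 3 IGL_entropy  31  46    1.895    0.877 3.81e-04 6.35e-04
#> 4 TRA_entropy  27  14    0.637    0.000 1.29e-02 1.62e-02
#> 5 TRB_entropy  25  21    0.673    0.000 2.52e-02 2.52e-02

cox_multivariate(co$clinical)
#> Cox PH (Efron ties): n = 77, events = 42
#>               covariate    HR ci_lower ci_upper    p_raw    p_adj
#>  phenotype LSP (vs HSP) 0.113   0.0398    0.318 3.83e-05 7.66e-05
#>                   stage 1.945   1.3698    2.762 2.00e-04 2.00e-04
```

Reading the output: LSP repertoires are significantly more diverse than
HSP for every testable chain (TRD was simulated off here and is flagged
not-testable, mirroring its low detection in real cohorts), the group
medians show the direction of the effect, and the Cox fit recovers the
designed protective phenotype effect (true HR 0.1, fitted 0.11 with CI
0.04–0.32) together with the adverse ordinal stage effect.

The `n_a`/`n_b` columns shrink where a chain was undetected in some
samples: undefined metrics propagate as missing values, never as zeros.

## Files and pipeline

A cohort on disk is one AIRR TSV per sample plus `samples.tsv`
(sample_id, library_reads, path), `clinical.tsv` (sample_id, phenotype,
stage, vital_status/event, os_days) and optionally `expression.tsv` and a
gene-set file (`name TAB gene,gene,...`). `run_pipeline()` (or the CLI,
`inst/cli/immunorep.R`, with subcommands `simulate` and `run-all`) chains
all stages and writes `clones.tsv`, `metrics.tsv`, `comparisons.tsv`,
`correlations.tsv`, `survival.json` and a `manifest.json` with MD5 hashes
and every resolved setting, so two runs can be diffed on provenance alone.

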