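---
title: "Methods: clone identification, repertoire metrics and survival modelling in immunorep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone identification, repertoire metrics and survival modelling in immunorep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunorep)
```

## Scope and model

`immunorep` analyses adaptive immune receptor repertoires extracted from
bulk tumor RNA-seq (e.g. by TRUST4) for cohorts stratified by a steroid
phenotype label (LSP = low steroid phenotype, HSP = high). Bulk RNA-seq
cannot pair heavy/light or alpha/beta chains, so each of the seven loci
(IGH, IGK, IGL; TRA, TRB, TRD, TRG) is analysed separately throughout.

The pipeline is: AIRR-format ingestion → productivity filter → clone
identification → per-chain metrics → phenotype/stage statistics → survival
models. A synthetic-cohort generator reproduces the statistical structure
of the cohort the analysis targets, so every stage is testable without the
controlled-access source data.

## Clone definition

A clone is an equivalence class of rearrangements sharing:

1. locus, V gene and J gene (gene level by default; RNA-seq allele calls
   are noisy, so the `*01` suffix is stripped before matching — switchable
   to allele level),
2. CDR3 nucleotide length, and
3. CDR3 nucleotide identity at or above a chain-class threshold: 0.90 for
   BCR loci, 0.95 for TCR loci.

"At least X% identity" does not by itself define a partition. We use
single-linkage connected components of the thresholded identity graph: the
most common clonotype-grouping convention, with clean graph semantics and a
natural monotonicity (raising the threshold can only split clones, never
merge them — a property the tests check). The threshold is inclusive
(`>=`), matching "at least". Because grouping by equal CDR3 length precedes
clustering, identity reduces to Hamming identity; indels cannot occur
inside a group. `N` bases never count as matches, and records whose CDR3
exceeds 10% `N` are dropped at load with a warning, since their identity is
not meaningfully defined. Output order is canonicalised (components and
members sorted lexicographically), so the partition and the deterministic
clone ids are invariant to input order.

## Productivity filter

A record survives `filter_productive()` iff it has a non-empty CDR3, its
nucleotide length is divisible by 3, its frame-0 translation is consistent
with the reported amino-acid junction (positions where either side is
ambiguous `X`/`_` are not disagreements), the junction contains no stop
codon `*`, and the CDR3 is completely assembled. Completeness trusts an
`is_complete`/`complete_vdj` flag when present and otherwise falls back to
the canonical anchors (cysteine start, phenylalanine/tryptophan end), the
TRUST4 convention. The filter is idempotent and order-preserving.

## Repertoire metrics

For each (sample, chain), with clone read counts \(n_1,\dots,n_R\),
\(p_i = n_i / \sum_j n_j\):

* **abundance** \(= \sum_i n_i\): total receptor reads;
* **CPK**: unique clones per *thousand total library reads* (primary mode,
  matching the "clones per kiloread" name); a per-million mode implements
  the alternative reads-per-million wording. The two normalisations differ
  only by a factor of 1000, and the mode in force is recorded in output
  attributes and the pipeline manifest because the source material is
  ambiguous between them;
* **Shannon entropy** \(H = -\sum_i p_i \ln p_i\) in nats. The log base is
  a config toggle (base 2 available); orderings, and therefore every rank
  test downstream, are base-invariant;
* **clonality** \(C = 1 - H/\ln R\), defined only for \(R \ge 2\).

Frequencies are read-count weighted (clonality quantifies unevenness of
clonotype *abundance*), not one-per-unique-sequence. Chains without
detections are reported as explicit rows with abundance 0 and `NA`
entropy/clonality — undefined is never coerced to 0, and downstream tests
receive the detection structure (e.g. TRD is typically too rarely detected
to compare, and is flagged not-testable rather than dropped).

## Statistics

Two-group comparisons use the two-sided Mann–Whitney U test: exact when the
combined n is at most 20 without ties, otherwise the tie-corrected normal
approximation with continuity correction (standard practice; the choice is
recorded in the result row). Groups below `min_samples = 3` non-missing
values give a flagged not-testable row with a reason code. Three or more
groups use Kruskal–Wallis followed by Dunn's pairwise z-tests on pooled
midranks with tie-corrected variance.

FDR control is Benjamini–Hochberg, implemented as the textbook step-up and
verified against an independent oracle. Families follow the per-panel
convention: one family per (metric × test battery), e.g. all chains'
entropy LSP-vs-HSP is one family; Dunn pairs form one family per omnibus
test; correlations one family per (stratum × metric). Family composition is
emitted with the results; raw and adjusted p-values are always both
reported, since the source material mixes nominal and adjusted conventions.

Correlations are Spearman's rho, pooled and per stratum, with pairwise
deletion of missing metric values and the effective n reported; pairs with
n < 3 or zero variance are flagged. Signature scores are per-sample means
of log2(TPM+1) marker expression over a gene set (a deliberate, transparent
stand-in for deconvolution scores, used only as correlation covariates);
the fraction of genes found is recorded.

Display/modelling transform: `log2p1(x) = log2(x + 1)` for counts and
entropy.

## Survival

Kaplan–Meier product-limit curves with the standard log-rank test compare
strata; metric-based strata come from median dichotomization computed
within the stratum being plotted, with values equal to the median assigned
to Low (a deterministic rule; the convention is recorded in the manifest)
and all-constant vectors flagged not-dichotomizable.

The multivariate Cox model uses Efron's tie handling (the default of the
standard survival implementation), Wald 95% intervals, HSP as the phenotype
reference (so the protective LSP effect appears as HR < 1), ordinal stage
coding I=1..IV=4 by default (categorical optional), metric covariates on
the log2(x+1) scale, and interaction covariates as element-wise products of
the two named transformed columns (IGH:IGK, IGH:IGL, TRA:TRB in the
standard battery). P-values are BH-adjusted across the reported covariate
battery. A covariate with zero variance is reported as HR 1 with an
uninformative CI rather than passed to a singular fit. Survival time is
consumed in days.

## Synthetic cohorts: what they emulate

`simulation_params()` defaults are a stated world fixed once from the
published cohort description, not tuning knobs:

* 31 LSP and 47 HSP cases; stage mix 9/37/16/14 (I–IV) with a ~2.6%
  missing-stage fraction.
* Per-sample, per-chain receptor reads are negative binomial (size 0.8)
  with means calibrated so group read totals reproduce the published ones:
  116,426 vs 39,666 BCR reads and 1,336 vs 115 TCR reads (LSP vs HSP),
  i.e. ≈3:1 and ≈10:1 group ratios. TCR reads split TRA/TRB/TRG/TRD =
  0.35/0.45/0.15/0.05, making TRD rare, as observed.
* Unique clones arise by Poisson thinning at the published clones-per-read
  rates (BCR ≈ 0.021 LSP / 0.028 HSP; TCR ≈ 0.36 / 0.63); clone sizes
  follow a Zipf law with exponent 0.8 (LSP) vs 1.6 (HSP), so LSP
  repertoires are richer *and* more even — the entropy shift δ is an
  emergent consequence of these two levers, not a separate dial.
* CDR3s are random in-frame sequences (21–60 nt, C...F/W anchors, no stop
  codons). Within-clone variants mutate at most half the threshold slack,
  so all members stay at or above the clonotyping threshold; bases of
  distinct clones sharing a (V, J, length) key are kept far enough apart
  that single linkage cannot bridge them — designed clone counts are
  exactly recoverable, which the tests exploit.
* Marker expression = baseline + coupling × standardised log2(x+1) class
  abundance + Gaussian noise, with coupling 1.2 (LSP) vs 0.4 (HSP),
  emulating the attenuated marker correlations in HSP.
* Survival is exponential with baseline hazard 1/3000 per day (HSP, stage
  I), phenotype log-HR ln(0.1), stage log-HR ln(1.6) per step, and
  independent uniform administrative censoring on 1000–3000 days. These
  produce death fractions of the observed order (≈half of HSP, few LSP).
* Library sizes are lognormal (median 4×10⁷) and independent of phenotype,
  so CPK and abundance remain statistically distinguishable.
* `preset = "null"` pools all phenotype-dependent parameters and zeroes the
  phenotype log-hazard; it is the basis of the type-I calibration test.

What the generator does *not* emulate: real V(D)J recombination biology
(junctional insertions, gene-usage bias beyond uniform), somatic
hypermutation lineages, shared/public clonotypes across samples, batch
effects, or any dependence between library size and phenotype. A green
test therefore establishes correctness of the pipeline's algorithms and
calibration of its tests under the designed statistical structure — not
biological realism of any particular clone.

## Numerical and compute choices

* Identity is computed on character matrices per (V, J, length) group;
  groups are small by construction, so the all-pairs cost is negligible.
* The calibration study (1000 null cohorts) and power study (200
  paper-like cohorts) restrict simulation to the IGH chain at a 0.25 read
  scale purely to bound compute on one CPU. The null world is
  phenotype-symmetric at any scale, so the nominal level is unaffected;
  IGH is the chain with the clearest reported entropy separation, making
  it the natural single-chain power target. Repetition counts are as
  specified.
* The Cox recovery study uses a 4000–8000-day censoring window to realise
  the stated ≥60% event condition at n = 500.
* Cohort generation is a deterministic function of (params, seed) via R's
  default RNG; derived seeds stay below 2^31.
* CDR3 translation uses the standard genetic code table directly (N-codons
  → `X`); this is numerically identical to, but ~100× faster than, the
  general fuzzy-codon translation path of the underlying library.

## Known limitations

* Cross-sample (public) clonotype analysis, rarefaction/Hill diversity,
  somatic-hypermutation lineage trees and repertoire-overlap indices are
  out of scope.
* The Cox battery makes no attempt to reproduce published hazard-ratio
  magnitudes for chain covariates — the covariate scale behind those
  numbers is not recoverable; only the qualitative structure (dominant
  protective phenotype effect, HR ≈ 0.1) is designed and recovered.
* Efron tie handling makes subject-duplication invariance approximate
  (exact under Breslow); see the survival tests.
* The detection summary classifies on raw read presence; it does not model
  assay sensitivity.
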