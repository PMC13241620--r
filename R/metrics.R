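# Per-(sample, chain) repertoire summary metrics: abundance (total receptor
# reads), unique clone count, CPK (normalised richness), Shannon entropy and
# clonality. Clone frequencies are weighted by read counts, so a clone seen
# in many reads dominates the entropy.

#' Shannon entropy of a clone-size distribution
#'
#' \eqn{H = -\sum_i p_i \log p_i} with \eqn{p_i} the read-count frequency of
#' clone \eqn{i}. Natural log by default; `base = 2` gives bits. An empty
#' vector yields `NA` (undefined, not zero): a repertoire with no clones has
#' no diversity to measure.
#'
#' @param clone_read_counts positive counts, one per clone.
#' @param base logarithm base; default `exp(1)` (nats).
#' @return entropy in `[0, log(R)]`, or `NA_real_` for an empty input.
#' @export
shannon_entropy <- function(clone_read_counts, base = exp(1)) {
  if (length(clone_read_counts) == 0) return(NA_real_)
  if (any(is.na(clone_read_counts)) || any(clone_read_counts <= 0)) {
    stop("clone read counts must be positive")
  }
  p <- clone_read_counts / sum(clone_read_counts)
  -sum(p * log(p, base = base))
}

#' Clonality of a clone-size distribution
#'
#' \eqn{C = 1 - H / \log(R)} for \eqn{R \ge 2} clones: 0 for a perfectly
#' even repertoire, approaching 1 when a single clone dominates. Undefined
#' (`NA`) for fewer than two clones, where \eqn{\log R = 0}. The value does
#' not depend on the entropy base.
#'
#' @inheritParams shannon_entropy
#' @return clonality in `[0, 1]`, or `NA_real_` when fewer than two clones.
#' @export
clonality <- function(clone_read_counts) {
  R <- length(clone_read_counts)
  if (R == 0) return(NA_real_)
  if (any(is.na(clone_read_counts)) || any(clone_read_counts <= 0)) {
    stop("clone read counts must be positive")
  }
  if (R < 2) return(NA_real_)
  1 - shannon_entropy(clone_read_counts) / log(R)
}

#' Clones per kiloread (CPK)
#'
#' Unique clone count normalised by the total sequencing depth of the RNA-seq
#' library. The primary mode is clones per thousand library reads (matching
#' the CPK acronym); `mode = "per_million"` instead reports clones per
#' million library reads.
#'
#' @param n_clones non-negative unique clone count.
#' @param library_reads positive total library read count.
#' @param mode `"per_kiloread"` (default) or `"per_million"`.
#' @return non-negative normalised richness.
#' @export
cpk <- function(n_clones, library_reads, mode = c("per_kiloread",
                                                  "per_million")) {
  mode <- match.arg(mode)
  if (!is.numeric(library_reads) || any(library_reads <= 0)) {
    stop("`library_reads` must be positive")
  }
  if (any(n_clones < 0)) stop("`n_clones` must be non-negative")
  scale <- if (mode == "per_kiloread") 1e3 else 1e6
  scale * n_clones / library_reads
}

#' Per-chain repertoire metrics for one sample
#'
#' Aggregates a clone set into one row per receptor locus. All seven loci
#' are always reported: chains with no detected clones get abundance 0,
#' `n_clones` 0, CPK 0 and `NA` entropy/clonality, so downstream group tests
#' can see the detection structure rather than silently losing chains.
#'
#' @param clones a `clone_set` from [assign_clones()].
#' @param library_reads total library reads; defaults to the value stored in
#'   the clone set.
#' @param cpk_mode passed to [cpk()].
#' @param entropy_base passed to [shannon_entropy()].
#' @return data.frame with columns `sample_id, locus, abundance, n_clones,
#'   cpk, entropy, clonality`.
#' @export
repertoire_metrics <- function(clones, library_reads = clones$library_reads,
                               cpk_mode = c("per_kiloread", "per_million"),
                               entropy_base = exp(1)) {
  if (!inherits(clones, "clone_set")) stop("`clones` must be a clone_set")
  cpk_mode <- match.arg(cpk_mode)
  out <- list2DF(list(
    sample_id = rep.int(clones$sample_id, length(ALL_LOCI)),
    locus = ALL_LOCI,
    abundance = rep.int(0L, length(ALL_LOCI)),
    n_clones = rep.int(0L, length(ALL_LOCI)),
    cpk = rep.int(0, length(ALL_LOCI)),
    entropy = rep.int(NA_real_, length(ALL_LOCI)),
    clonality = rep.int(NA_real_, length(ALL_LOCI))
  ))
  df <- clones$clones
  for (i in seq_along(ALL_LOCI)) {
    sizes <- df$total_reads[df$locus == ALL_LOCI[i]]
    if (length(sizes) == 0) next
    out$abundance[i] <- sum(sizes)
    out$n_clones[i] <- length(sizes)
    out$entropy[i] <- shannon_entropy(sizes, base = entropy_base)
    out$clonality[i] <- clonality(sizes)
  }
  out$cpk <- cpk(out$n_clones, library_reads, mode = cpk_mode)
  attr(out, "cpk_mode") <- cpk_mode
  attr(out, "entropy_base") <- entropy_base
  out
}

#' Repertoire metrics for a whole cohort
#'
#' Convenience wrapper: productive-filters each repertoire, assigns clones
#' and stacks the per-sample metric tables.
#'
#' @param repertoires list of [sample_repertoire()] objects.
#' @param cfg a [clonotyping_config()].
#' @inheritParams repertoire_metrics
#' @return data.frame, 7 rows (loci) per sample.
#' @export
cohort_metrics <- function(repertoires, cfg = clonotyping_config(),
                           cpk_mode = c("per_kiloread", "per_million"),
                           entropy_base = exp(1)) {
  cpk_mode <- match.arg(cpk_mode)
  res <- lapply(repertoires, function(r) {
    cs <- assign_clones(filter_productive(r), cfg)
    repertoire_metrics(cs, cpk_mode = cpk_mode, entropy_base = entropy_base)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "cpk_mode") <- cpk_mode
  attr(out, "entropy_base") <- entropy_base
  out
}
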