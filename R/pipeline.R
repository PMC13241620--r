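# End-to-end orchestration: detection summary, config validation, and the
# run that chains read -> filter -> clonotype -> metrics -> comparisons ->
# correlations -> survival, writing a hashed artifact manifest.

#' Cohort detection summary
#'
#' Classifies every case by whether any BCR-locus reads and/or any TCR-locus
#' reads were detected, partitioning the cohort into BCR-only, TCR-only,
#' both and neither. Percentages are reported to one decimal.
#'
#' @param metrics cohort metrics table ([cohort_metrics()] output, or any
#'   data.frame with `sample_id`, `locus`, `abundance`).
#' @return list of class `cohort_summary`: `n_cases`, `n_with_bcr_only`,
#'   `n_with_tcr_only`, `n_with_both`, `n_with_neither`, `pct_detectable`,
#'   `pct_undetectable`, and per-group read/clone totals.
#' @export
summarize_detection <- function(metrics) {
  stopifnot(all(c("sample_id", "locus", "abundance") %in% names(metrics)))
  ids <- unique(metrics$sample_id)
  has_bcr <- vapply(ids, function(s) {
    sum(metrics$abundance[metrics$sample_id == s &
                            metrics$locus %in% BCR_LOCI]) > 0
  }, logical(1))
  has_tcr <- vapply(ids, function(s) {
    sum(metrics$abundance[metrics$sample_id == s &
                            metrics$locus %in% TCR_LOCI]) > 0
  }, logical(1))
  n <- length(ids)
  n_both <- sum(has_bcr & has_tcr)
  n_bcr <- sum(has_bcr & !has_tcr)
  n_tcr <- sum(!has_bcr & has_tcr)
  n_neither <- n - n_both - n_bcr - n_tcr
  reads <- list(
    bcr = sum(metrics$abundance[metrics$locus %in% BCR_LOCI]),
    tcr = sum(metrics$abundance[metrics$locus %in% TCR_LOCI])
  )
  clones <- if ("n_clones" %in% names(metrics)) list(
    bcr = sum(metrics$n_clones[metrics$locus %in% BCR_LOCI]),
    tcr = sum(metrics$n_clones[metrics$locus %in% TCR_LOCI])
  ) else list(bcr = NA_integer_, tcr = NA_integer_)
  structure(list(
    n_cases = n,
    n_with_bcr_only = n_bcr, n_with_tcr_only = n_tcr,
    n_with_both = n_both, n_with_neither = n_neither,
    pct_detectable = round(100 * (n - n_neither) / n, 1),
    pct_undetectable = round(100 * n_neither / n, 1),
    total_reads = reads, total_clones = clones
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "%d cases: %d BCR-only, %d TCR-only, %d both, %d neither\n",
    "detectable repertoire: %.1f%% (no detection: %.1f%%)\n"),
    x$n_cases, x$n_with_bcr_only, x$n_with_tcr_only, x$n_with_both,
    x$n_with_neither, x$pct_detectable, x$pct_undetectable))
  invisible(x)
}

#' Pipeline configuration
#'
#' Validates paths and analysis settings before any stage runs. The config
#' can also be stored as / loaded from JSON ([read_pipeline_config()]).
#'
#' @param repertoire_dir directory of per-sample AIRR TSVs.
#' @param samples_tsv TSV with `sample_id, library_reads, path` (paths
#'   relative to `repertoire_dir`'s parent or absolute).
#' @param clinical_tsv clinical metadata TSV.
#' @param expression_tsv optional gene-by-sample expression TSV (first
#'   column `gene`).
#' @param gene_sets optional plain-text gene-set file
#'   (`name TAB gene,gene,...`).
#' @param out_dir output directory.
#' @param bcr_identity_threshold,tcr_identity_threshold,gene_match_level
#'   clonotyping settings, see [clonotyping_config()].
#' @param cpk_mode,entropy_base metric settings, see [repertoire_metrics()].
#' @param min_samples smallest per-group n considered testable.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(repertoire_dir, samples_tsv, clinical_tsv,
                            expression_tsv = NULL, gene_sets = NULL,
                            out_dir = "immunorep_out",
                            bcr_identity_threshold = 0.90,
                            tcr_identity_threshold = 0.95,
                            gene_match_level = "gene",
                            cpk_mode = "per_kiloread",
                            entropy_base = exp(1),
                            min_samples = 3, seed = 1) {
  for (p in c(repertoire_dir, samples_tsv, clinical_tsv, expression_tsv,
              gene_sets)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("config validation: path does not exist: ", p)
    }
  }
  cfg <- clonotyping_config(bcr_identity_threshold, tcr_identity_threshold,
                            gene_match_level)
  structure(list(
    repertoire_dir = repertoire_dir, samples_tsv = samples_tsv,
    clinical_tsv = clinical_tsv, expression_tsv = expression_tsv,
    gene_sets = gene_sets, out_dir = out_dir, clonotyping = cfg,
    cpk_mode = cpk_mode, entropy_base = entropy_base,
    min_samples = min_samples, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose keys match the [pipeline_config()] arguments.
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Reads every repertoire listed in the samples manifest, productive-filters
#' it, assigns clones, computes per-chain metrics, runs the LSP-vs-HSP
#' comparisons (abundance, CPK, entropy, clonality on the log2(x+1) scale),
#' correlates chain abundance/entropy with marker expression and signature
#' scores when expression data are supplied, and fits Kaplan-Meier and
#' multivariate Cox survival models. Every output file is recorded in a
#' manifest with its MD5 hash, together with the fully resolved settings, so
#' two runs can be diffed on provenance alone.
#'
#' @param config a [pipeline_config()] or path to its JSON form.
#' @return the manifest (list), invisibly; written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "read"
  manifest <- list(settings = resolve_settings(config), outputs = list())
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    data.table::fwrite(df, p, sep = "\t", quote = FALSE, na = "NA")
    manifest$outputs[[name]] <<- unname(tools::md5sum(p))
    p
  }
  result <- tryCatch({
    samples <- as.data.frame(data.table::fread(config$samples_tsv,
                                               data.table = FALSE))
    base_dir <- dirname(config$repertoire_dir)
    reps <- lapply(seq_len(nrow(samples)), function(i) {
      p <- samples$path[i]
      if (!file.exists(p)) p <- file.path(base_dir, samples$path[i])
      read_airr_table(p, samples$sample_id[i], samples$library_reads[i])
    })
    names(reps) <- samples$sample_id
    clinical <- read_clinical_table(config$clinical_tsv)

    stage <- "clonotype"
    clone_sets <- lapply(reps, function(r)
      assign_clones(filter_productive(r), config$clonotyping))
    clone_tab <- do.call(rbind, lapply(clone_sets, function(cs)
      cbind(sample_id = cs$sample_id, cs$clones)))
    emit(clone_tab, "clones.tsv")

    stage <- "metrics"
    metrics <- do.call(rbind, lapply(clone_sets, repertoire_metrics,
                                     cpk_mode = config$cpk_mode,
                                     entropy_base = config$entropy_base))
    rownames(metrics) <- NULL
    emit(metrics, "metrics.tsv")
    detection <- summarize_detection(metrics)

    stage <- "compare"
    labels <- stats::setNames(clinical$phenotype, clinical$sample_id)
    comparisons <- do.call(rbind, lapply(
      c("abundance", "cpk", "entropy", "clonality"),
      function(m) compare_metric_by_group(
        metrics, labels, metric = m, min_samples = config$min_samples,
        transform = if (m %in% c("abundance", "cpk")) log2p1 else identity)
    ))
    emit(comparisons, "comparisons.tsv")

    stage <- "correlate"
    correlations <- NULL
    if (!is.null(config$expression_tsv)) {
      expr_df <- as.data.frame(data.table::fread(config$expression_tsv,
                                                 data.table = FALSE))
      expr <- as.matrix(expr_df[, -1, drop = FALSE])
      rownames(expr) <- expr_df[[1]]
      x <- metrics_wide(metrics, c("abundance", "entropy"))
      y <- as.data.frame(t(expr))
      if (!is.null(config$gene_sets)) {
        sets <- read_gene_sets(config$gene_sets)
        for (nm in names(sets)) {
          sc <- signature_score(expr, sets[[nm]], name = nm)
          y[[nm]] <- sc$score[match(rownames(y), sc$sample_id)]
        }
      }
      correlations <- spearman_matrix(x, y, strata = labels)
      emit(correlations, "correlations.tsv")
    }

    stage <- "survival"
    surv_out <- survival_battery(metrics, clinical)
    jsonlite::write_json(surv_out, file.path(out_dir, "survival.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         na = "null")
    manifest$outputs[["survival.json"]] <-
      unname(tools::md5sum(file.path(out_dir, "survival.json")))

    manifest$detection <- unclass(detection)
    manifest$stages <- c("read", "clonotype", "metrics", "compare",
                         "correlate", "survival")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    manifest
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

# wide sample x (locus_metric) table used for correlations and Cox models
metrics_wide <- function(metrics, which = c("abundance", "entropy")) {
  ids <- unique(metrics$sample_id)
  out <- data.frame(row.names = ids)
  for (m in which) {
    for (lo in ALL_LOCI) {
      sub <- metrics[metrics$locus == lo, ]
      out[[paste(lo, m, sep = "_")]] <- sub[[m]][match(ids, sub$sample_id)]
    }
  }
  out
}

# The standard survival battery: phenotype KM + log-rank, per-chain
# median-dichotomized KM within phenotype strata for abundance and entropy,
# and Cox models (phenotype + stage + chain metric with the interaction
# pairs IGH:IGK, IGH:IGL, TRA:TRB).
survival_battery <- function(metrics, clinical) {
  labels <- clinical$phenotype
  km_pheno <- km_logrank(clinical, labels)
  wide <- metrics_wide(metrics, c("abundance", "entropy"))
  wide <- wide[clinical$sample_id, , drop = FALSE]
  km_metric <- list()
  for (m in c("abundance", "entropy")) {
    for (lo in ALL_LOCI) {
      col <- paste(lo, m, sep = "_")
      for (ph in c("LSP", "HSP")) {
        idx <- clinical$phenotype == ph
        v <- wide[[col]][idx]
        if (sum(!is.na(v)) < 2 || all(v[!is.na(v)] == v[!is.na(v)][1])) next
        lab <- dichotomize_by_median(v)
        if (isTRUE(attr(lab, "not_dichotomizable"))) next
        if (nlevels(droplevels(lab)) < 2) next
        km <- km_logrank(clinical[idx, ], lab)
        km_metric[[paste(col, ph, sep = ":")]] <-
          list(chisq = km$chisq, p = km$p, n = km$n)
      }
    }
  }
  cox <- list()
  for (m in c("abundance", "entropy")) {
    cols <- paste(c("IGH", "IGK", "IGL", "TRA", "TRB"), m, sep = "_")
    cov <- wide[, cols, drop = FALSE]
    names(cov) <- c("IGH", "IGK", "IGL", "TRA", "TRB")
    cov[is.na(cov)] <- 0  # undetected chain = zero signal on log2(x+1) scale
    fit <- tryCatch(
      cox_multivariate(clinical, cov,
                       interactions = list(c("IGH", "IGK"), c("IGH", "IGL"),
                                           c("TRA", "TRB"))),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      cox[[m]] <- list(table = as.data.frame(fit),
                       n = attr(fit, "n"), n_events = attr(fit, "n_events"),
                       metadata = attr(fit, "metadata"))
    }
  }
  list(
    km_phenotype = list(chisq = km_pheno$chisq, p = km_pheno$p,
                        n = km_pheno$n),
    km_dichotomized = km_metric,
    cox = cox
  )
}

resolve_settings <- function(config) {
  list(
    repertoire_dir = config$repertoire_dir,
    samples_tsv = config$samples_tsv,
    clinical_tsv = config$clinical_tsv,
    expression_tsv = config$expression_tsv,
    gene_sets = config$gene_sets,
    out_dir = config$out_dir,
    bcr_identity_threshold = config$clonotyping$bcr_identity_threshold,
    tcr_identity_threshold = config$clonotyping$tcr_identity_threshold,
    gene_match_level = config$clonotyping$gene_match_level,
    linkage = config$clonotyping$linkage,
    cpk_mode = config$cpk_mode,
    entropy_base = config$entropy_base,
    min_samples = config$min_samples,
    ties_method = "efron",
    stage_coding = "ordinal",
    median_tie_rule = "Low",
    seed = config$seed
  )
}
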