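# Nonparametric group comparisons (Mann-Whitney, Kruskal-Wallis + Dunn),
# Benjamini-Hochberg FDR control and Spearman correlation of repertoire
# metrics against marker-gene expression / signature scores.

#' log2(value + 1) transform
#'
#' The display/modelling scale used for read counts and entropy throughout
#' the package.
#'
#' @param values non-negative numeric vector (`NA` passes through).
#' @return `log2(values + 1)`.
#' @export
log2p1 <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stop("log2p1 requires non-negative values")
  log2(values + 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: sort p-values increasingly, multiply by `m/i`, take
#' the running minimum from the largest down, cap at 1 and restore the input
#' order. `NA` entries are ignored (and returned as `NA`) without counting
#' towards `m`.
#'
#' @param p_values numeric vector in `(0, 1]` (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(p_values))
  if (m > 0) {
    o <- order(p)
    adj <- pmin(1, cummin((p[o] * m / seq_len(m))[m:1])[m:1])
    res <- numeric(m)
    res[o] <- adj
    out[ok] <- res
  }
  out
}

# p-values live in (0, 1]; degenerate statistics (perfect correlations,
# huge z) can underflow to exactly 0, which the BH contract rejects
clamp_p <- function(p) pmin(1, pmax(p, .Machine$double.xmin))

not_testable <- function(metric, grouping, test, reason) {
  data.frame(metric = metric, grouping = grouping, test = test,
             statistic = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
             n_a = NA_integer_, n_b = NA_integer_,
             median_a = NA_real_, median_b = NA_real_,
             testable = FALSE, reason = reason,
             stringsAsFactors = FALSE)
}

#' Two-sided Mann-Whitney U comparison
#'
#' Exact p-value when the combined sample size is at most 20 and there are
#' no ties, otherwise the normal approximation with tie correction and
#' continuity correction. Groups below `min_samples` non-missing values are
#' reported as not testable (mirroring chains excluded for low detection)
#' rather than dropped.
#'
#' @param group_a,group_b numeric vectors (NA ignored).
#' @param min_samples minimum non-missing values per group; default 3.
#' @param metric,grouping labels copied into the result row.
#' @return one-row data.frame: `metric, grouping, test, statistic, p_raw,
#'   p_adj, n_a, n_b, median_a, median_b, testable, reason`.
#' @export
mann_whitney <- function(group_a, group_b, min_samples = 3,
                         metric = "value", grouping = "A-vs-B") {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < min_samples || length(b) < min_samples) {
    return(not_testable(metric, grouping, "mann-whitney",
                        sprintf("group below min_samples=%d (n=%d, %d)",
                                min_samples, length(a), length(b))))
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 20 && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = !exact)
  )
  data.frame(metric = metric, grouping = grouping, test = "mann-whitney",
             statistic = unname(wt$statistic),
             p_raw = clamp_p(wt$p.value), p_adj = NA_real_,
             n_a = length(a), n_b = length(b),
             median_a = stats::median(a), median_b = stats::median(b),
             testable = TRUE, reason = "",
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis omnibus test with Dunn post hoc pairs
#'
#' Omnibus rank test over three or more groups followed by Dunn z-tests for
#' every pair, with tie-corrected pooled rank variance. Pairwise p-values
#' are BH-adjusted within the family of pairs.
#'
#' @param groups named list of numeric vectors (three or more).
#' @param min_samples minimum non-missing values per group.
#' @param metric label copied into result rows.
#' @return list with `omnibus` (one-row data.frame: statistic = KW H, df,
#'   p_raw) and `pairs` (data.frame of Dunn comparisons with `p_adj`).
#' @export
kruskal_dunn <- function(groups, min_samples = 3, metric = "value") {
  stopifnot(is.list(groups))
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  groups <- lapply(groups, function(v) v[!is.na(v)])
  eligible <- vapply(groups, length, integer(1)) >= min_samples
  if (sum(eligible) < 3) {
    stop("kruskal_dunn needs >= 3 groups meeting min_samples; ",
         "use mann_whitney for two groups")
  }
  groups <- groups[eligible]
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  kw <- stats::kruskal.test(x, g)
  omnibus <- data.frame(metric = metric, test = "kruskal-wallis",
                        statistic = unname(kw$statistic),
                        df = unname(kw$parameter),
                        p_raw = kw$p.value, stringsAsFactors = FALSE)
  # Dunn's z statistics on the pooled midranks
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  combs <- utils::combn(names(groups), 2)
  pair_rows <- lapply(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    sigma <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z <- if (sigma > 0) (rbar[[i]] - rbar[[j]]) / sigma else 0
    data.frame(metric = metric, grouping = paste(i, j, sep = "-vs-"),
               test = "dunn", statistic = z,
               p_raw = clamp_p(2 * stats::pnorm(-abs(z))),
               n_a = n[[i]], n_b = n[[j]],
               median_a = stats::median(groups[[i]]),
               median_b = stats::median(groups[[j]]),
               testable = TRUE, reason = "", stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pair_rows)
  pairs$p_adj <- bh_adjust(pairs$p_raw)
  rownames(pairs) <- NULL
  list(omnibus = omnibus, pairs = pairs)
}

#' Group comparison of a metric table across a label
#'
#' Runs the LSP-vs-HSP style comparison for one metric column of a cohort
#' metrics table, chain by chain, and BH-adjusts across the family of chains
#' (one family per metric, matching a per-panel adjustment policy).
#'
#' @param metrics cohort metrics table from [cohort_metrics()].
#' @param labels named character vector mapping `sample_id` to group label
#'   (two levels).
#' @param metric metric column to compare (e.g. `"entropy"`).
#' @param min_samples per-group minimum; default 3.
#' @param transform optional transform applied to the metric first (the
#'   log2(x+1) convention); default identity.
#' @return data.frame, one row per locus, with `p_adj` filled across the
#'   testable rows.
#' @export
compare_metric_by_group <- function(metrics, labels, metric = "entropy",
                                    min_samples = 3, transform = identity) {
  stopifnot(metric %in% names(metrics))
  lv <- unique(labels[!is.na(labels)])
  if (length(lv) != 2) stop("compare_metric_by_group needs exactly 2 groups")
  rows <- lapply(ALL_LOCI, function(lo) {
    sub <- metrics[metrics$locus == lo, ]
    val <- transform(sub[[metric]])
    grp <- labels[sub$sample_id]
    mann_whitney(val[grp == lv[1]], val[grp == lv[2]],
                 min_samples = min_samples,
                 metric = paste(lo, metric, sep = "_"),
                 grouping = paste(lv[1], lv[2], sep = "-vs-"))
  })
  out <- do.call(rbind, rows)
  out$p_adj[out$testable] <- bh_adjust(out$p_raw[out$testable])
  out$family <- paste0(metric, ":", paste(lv, collapse = "-vs-"))
  rownames(out) <- NULL
  out
}

#' Signature score: mean marker expression per sample
#'
#' Stand-in for deconvolution scores: the per-sample mean of log2(TPM+1)
#' expression over the marker genes of a set. The fraction of requested
#' genes found in the matrix is recorded in attribute `coverage`.
#'
#' @param expr gene-by-sample numeric matrix (rownames = genes).
#' @param gene_set character vector of gene symbols.
#' @param name signature name.
#' @return data.frame `signature, sample_id, score` with attribute
#'   `coverage`.
#' @export
signature_score <- function(expr, gene_set, name = "signature") {
  stopifnot(is.matrix(expr) || is.data.frame(expr))
  expr <- as.matrix(expr)
  present <- intersect(gene_set, rownames(expr))
  if (length(present) == 0) {
    stop("no genes of the set found in the expression matrix: ",
         paste(gene_set, collapse = ", "))
  }
  sc <- colMeans(expr[present, , drop = FALSE])
  out <- data.frame(signature = name, sample_id = names(sc), score = unname(sc),
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- length(present) / length(gene_set)
  rownames(out) <- NULL
  out
}

#' Read a plain-text gene-set file
#'
#' One set per line: `name TAB gene,gene,...`.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(
    lapply(parts, function(p) trimws(strsplit(p[2], ",", fixed = TRUE)[[1]])),
    vapply(parts, `[[`, character(1), 1)
  )
}

#' Spearman correlations between chain metrics and covariates
#'
#' Correlates each metric column against each covariate column, pooled and
#' within each stratum. Pairs with fewer than 3 complete observations or
#' zero variance on either side are flagged not testable. BH adjustment is
#' applied within each (stratum, metric) family.
#'
#' @param x data.frame of metric values, rownames = sample ids (e.g. one
#'   column per chain-metric such as `IGH_abundance`).
#' @param y data.frame of covariates (marker expression, signature scores),
#'   rownames = sample ids.
#' @param strata named character vector mapping sample id to stratum label;
#'   `NULL` for pooled-only.
#' @return data.frame of `x_name, y_name, stratum, rho, p_raw, p_adj, n,
#'   testable, reason` rows.
#' @export
spearman_matrix <- function(x, y, strata = NULL) {
  common <- intersect(rownames(x), rownames(y))
  if (length(common) == 0) stop("no overlapping samples between x and y")
  x <- x[common, , drop = FALSE]
  y <- y[common, , drop = FALSE]
  strata_levels <- "all"
  if (!is.null(strata)) {
    strata <- strata[common]
    strata_levels <- c("all", sort(unique(strata[!is.na(strata)])))
  }
  rows <- list()
  for (st in strata_levels) {
    keep <- if (st == "all") rep(TRUE, length(common)) else
      !is.na(strata) & strata == st
    for (xn in colnames(x)) {
      fam <- list()
      for (yn in colnames(y)) {
        xv <- x[keep, xn]
        yv <- y[keep, yn]
        cc <- stats::complete.cases(xv, yv)
        n <- sum(cc)
        if (n < 3 || stats::sd(xv[cc]) == 0 || stats::sd(yv[cc]) == 0) {
          fam[[yn]] <- data.frame(x_name = xn, y_name = yn, stratum = st,
                                  rho = NA_real_, p_raw = NA_real_,
                                  p_adj = NA_real_, n = n, testable = FALSE,
                                  reason = if (n < 3) "n < 3" else
                                    "zero variance",
                                  stringsAsFactors = FALSE)
          next
        }
        ct <- suppressWarnings(
          stats::cor.test(xv[cc], yv[cc], method = "spearman",
                          alternative = "two.sided", exact = FALSE)
        )
        fam[[yn]] <- data.frame(x_name = xn, y_name = yn, stratum = st,
                                rho = unname(ct$estimate),
                                p_raw = clamp_p(ct$p.value), p_adj = NA_real_,
                                n = n, testable = TRUE, reason = "",
                                stringsAsFactors = FALSE)
      }
      fam <- do.call(rbind, fam)
      fam$p_adj[fam$testable] <- bh_adjust(fam$p_raw[fam$testable])
      rows[[paste(st, xn)]] <- fam
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
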