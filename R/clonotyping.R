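# Clone identification: rearrangements sharing V gene, J gene and CDR3
# length are clustered by CDR3 nucleotide identity using single-linkage
# connected components, at 90% identity for BCR loci and 95% for TCR loci.

#' Clonotyping configuration
#'
#' @param bcr_identity_threshold minimum CDR3 nucleotide identity joining two
#'   BCR (IGH/IGK/IGL) rearrangements into one clone; inclusive. Default 0.90.
#' @param tcr_identity_threshold as above for TCR loci (TRA/TRB/TRD/TRG);
#'   default 0.95.
#' @param gene_match_level `"gene"` (allele suffix after `*` stripped before
#'   matching; default, since RNA-seq allele calls are unreliable) or
#'   `"allele"`.
#' @return object of class `clonotyping_config`.
#' @export
clonotyping_config <- function(bcr_identity_threshold = 0.90,
                               tcr_identity_threshold = 0.95,
                               gene_match_level = c("gene", "allele")) {
  gene_match_level <- match.arg(gene_match_level)
  for (thr in c(bcr_identity_threshold, tcr_identity_threshold)) {
    if (!is.numeric(thr) || length(thr) != 1L || thr <= 0 || thr > 1) {
      stop("identity thresholds must lie in (0, 1]")
    }
  }
  structure(
    list(bcr_identity_threshold = bcr_identity_threshold,
         tcr_identity_threshold = tcr_identity_threshold,
         gene_match_level = gene_match_level,
         linkage = "single"),
    class = "clonotyping_config"
  )
}

#' Pairwise CDR3 nucleotide identity
#'
#' Fraction of positions at which two equal-length CDR3 nucleotide sequences
#' carry the same unambiguous base. `N` never counts as a match (conservative
#' identity), but the denominator is always the full CDR3 length.
#'
#' @param a,b nucleotide strings of equal, positive length.
#' @return identity fraction in `[0, 1]`.
#' @export
cdr3_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || nchar(a) != nchar(b)) {
    stop("cdr3_identity requires equal, positive lengths (got ",
         nchar(a), " and ", nchar(b), ")")
  }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av == bv & av != "N" & bv != "N") / length(av)
}

# All-pairs identity for a character vector of equal-length sequences,
# computed column-wise on the position matrix.
identity_matrix <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  len <- ncol(m)
  idm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    eq <- sweep(m, 2, m[i, ], FUN = "==") &
      m != "N" & matrix(m[i, ] != "N", n, len, byrow = TRUE)
    idm[i, ] <- rowSums(eq) / len
  }
  diag(idm) <- 1
  idm
}

# Union-find over 1..n
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cluster one (locus, V, J, CDR3-length) group into clones
#'
#' Builds the graph whose vertices are the records and whose edges join pairs
#' with CDR3 identity greater than or equal to `threshold` ("at least":
#' inclusive), and returns its connected components (single linkage). The
#' result is deterministic and independent of input order: records are
#' canonically sorted by (CDR3, sequence_id) before clustering and components
#' are ordered by their lexicographically smallest CDR3.
#'
#' @param records data.frame of rearrangement records sharing locus, V gene,
#'   J gene and CDR3 length.
#' @param threshold identity threshold in (0, 1].
#' @return list of integer vectors, each holding the row indices (into the
#'   canonical ordering, returned as attribute `order`) of one clone.
#' @export
partition_group <- function(records, threshold) {
  n <- nrow(records)
  lens <- nchar(records$cdr3_nt)
  if (length(unique(lens)) > 1L ||
      length(unique(records$locus)) > 1L) {
    bad <- records$sequence_id[1]
    stop("partition_group precondition violated (mixed locus or CDR3 length); ",
         "first offending record: ", bad)
  }
  ord <- order(records$cdr3_nt, records$sequence_id)
  comps <- single_linkage_components(records$cdr3_nt[ord], threshold)
  attr(comps, "order") <- ord
  comps
}

# Connected components of the >= threshold identity graph over sequences
# already in canonical order; components ordered by smallest member index.
single_linkage_components <- function(seqs, threshold) {
  n <- length(seqs)
  if (n == 1L) return(list(1L))
  idm <- identity_matrix(seqs)
  pairs <- which(upper.tri(idm) & idm >= threshold, arr.ind = TRUE)
  comp_id <- uf_components(n, pairs)
  comps <- split(seq_len(n), comp_id)
  comps <- comps[order(vapply(comps, min, integer(1)))]
  lapply(unname(comps), sort)
}

strip_allele <- function(call) sub("\\*.*$", "", call)

#' Group a productive repertoire into clones
#'
#' Applies the clone definition: records are first grouped by locus, V gene,
#' J gene (at `gene_match_level`) and CDR3 nucleotide length, then each group
#' is single-linkage clustered by CDR3 identity at the BCR threshold for
#' IGH/IGK/IGL and the TCR threshold for TRA/TRB/TRD/TRG. Records lacking a
#' V or J call (or a locus) are excluded and counted in the `unassigned`
#' attribute of the result.
#'
#' @param rep a productive-filtered [sample_repertoire()].
#' @param cfg a [clonotyping_config()].
#' @return object of class `clone_set`: list with `sample_id`, `clones`
#'   (data.frame: clone_id, locus, v_gene, j_gene, cdr3_length,
#'   representative_cdr3, n_members, total_reads), `membership` (data.frame:
#'   sequence_id, clone_id), `n_unique`, `n_reads`.
#' @export
assign_clones <- function(rep, cfg = clonotyping_config()) {
  if (!inherits(rep, "sample_repertoire")) {
    stop("`rep` must be a sample_repertoire")
  }
  if (!inherits(cfg, "clonotyping_config")) {
    stop("`cfg` must be a clonotyping_config")
  }
  rec <- rep$records
  no_cdr3 <- is.na(rec$cdr3_nt) | !nzchar(rec$cdr3_nt)
  unassigned <- rec[is.na(rec$v_call) | is.na(rec$j_call) |
                      is.na(rec$locus) | no_cdr3, , drop = FALSE]
  rec <- rec[setdiff(rownames(rec), rownames(unassigned)), , drop = FALSE]
  # accumulate plain vectors; building one data.frame per clone is far too
  # slow for cohort-scale simulation studies
  acc <- list(clone_id = character(0), locus = character(0),
              v_gene = character(0), j_gene = character(0),
              cdr3_length = integer(0), representative_cdr3 = character(0),
              n_members = integer(0), total_reads = integer(0))
  mem_seq <- character(0)
  mem_clone <- character(0)
  if (nrow(rec) > 0) {
    if (cfg$gene_match_level == "gene") {
      v_gene <- strip_allele(rec$v_call)
      j_gene <- strip_allele(rec$j_call)
    } else {
      v_gene <- rec$v_call
      j_gene <- rec$j_call
    }
    seq_id <- rec$sequence_id
    cdr3 <- rec$cdr3_nt
    counts <- rec$read_count
    locus <- rec$locus
    key <- paste(locus, v_gene, j_gene, nchar(cdr3), sep = "|")
    groups <- split(seq_along(key), key)  # split() sorts keys: deterministic
    res <- lapply(groups, function(ix) {
      thr <- if (locus_class(locus[ix[1]]) == "BCR")
        cfg$bcr_identity_threshold else cfg$tcr_identity_threshold
      ord <- ix[order(cdr3[ix], seq_id[ix])]
      comps <- single_linkage_components(cdr3[ord], thr)
      n_comp <- length(comps)
      cid <- sprintf("%s|%s|%s|%s|%d|c%02d", rep$sample_id, locus[ix[1]],
                     v_gene[ix[1]], j_gene[ix[1]], nchar(cdr3[ix[1]]),
                     seq_len(n_comp))
      list(
        clone_id = cid,
        locus = rep.int(locus[ix[1]], n_comp),
        v_gene = rep.int(v_gene[ix[1]], n_comp),
        j_gene = rep.int(j_gene[ix[1]], n_comp),
        cdr3_length = rep.int(nchar(cdr3[ix[1]]), n_comp),
        representative_cdr3 = vapply(comps, function(ii)
          min(cdr3[ord[ii]]), character(1)),
        n_members = lengths(comps),
        total_reads = vapply(comps, function(ii)
          sum(counts[ord[ii]]), numeric(1)),
        mem_seq = seq_id[ord[unlist(comps)]],
        mem_clone = rep.int(cid, lengths(comps))
      )
    })
    for (f in names(acc)) acc[[f]] <- unlist(lapply(res, `[[`, f),
                                             use.names = FALSE)
    mem_seq <- unlist(lapply(res, `[[`, "mem_seq"), use.names = FALSE)
    mem_clone <- unlist(lapply(res, `[[`, "mem_clone"), use.names = FALSE)
  }
  clones <- list2DF(acc)
  membership <- list2DF(list(sequence_id = mem_seq, clone_id = mem_clone))
  rownames(clones) <- rownames(membership) <- NULL
  structure(
    list(sample_id = rep$sample_id, clones = clones, membership = membership,
         n_unique = nrow(clones), n_reads = sum(clones$total_reads),
         library_reads = rep$library_reads),
    class = "clone_set",
    unassigned = nrow(unassigned),
    config = cfg
  )
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf("clone_set '%s': %d clones, %d reads (%d unassigned record(s))\n",
              x$sample_id, x$n_unique, x$n_reads,
              attr(x, "unassigned")))
  invisible(x)
}

#' Write a clone table TSV
#'
#' One row per clone: `sample_id, locus, clone_id, v_gene, j_gene,
#' cdr3_length, representative_cdr3, n_members, total_reads`.
#'
#' @param clones a `clone_set` from [assign_clones()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(clones, path) {
  stopifnot(inherits(clones, "clone_set"))
  df <- cbind(sample_id = clones$sample_id,
              clones$clones[, c("locus", "clone_id", "v_gene", "j_gene",
                                "cdr3_length", "representative_cdr3",
                                "n_members", "total_reads")])
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
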