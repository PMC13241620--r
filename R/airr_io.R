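# Ingestion of rearrangement tables: the AIRR Rearrangement TSV standard and
# the TRUST4 simple-report dialect, plus the productive/complete-CDR3 filter
# applied before clone identification.

# Canonical record columns kept for every rearrangement.
RECORD_COLS <- c("sequence_id", "v_call", "d_call", "j_call", "locus",
                 "cdr3_nt", "cdr3_aa", "read_count", "is_complete",
                 "out_of_frame")

#' Construct a sample repertoire
#'
#' A `sample_repertoire` bundles the rearrangement records observed in one
#' RNA-seq sample with the total library read count used for clones-per-
#' kiloread (CPK) normalisation.
#'
#' @param sample_id sample identifier.
#' @param records data.frame with columns `sequence_id, v_call, d_call,
#'   j_call, locus, cdr3_nt, cdr3_aa, read_count, is_complete, out_of_frame`.
#' @param library_reads positive scalar: total reads in the RNA-seq library.
#'   Must be at least the summed read support of the records.
#' @return object of class `sample_repertoire`.
#' @export
sample_repertoire <- function(sample_id, records, library_reads) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!is.numeric(library_reads) || length(library_reads) != 1L ||
      library_reads <= 0) {
    stop("`library_reads` must be a positive scalar")
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(RECORD_COLS, names(records))
  for (mc in missing_cols) {
    records[[mc]] <- switch(mc,
      d_call = rep(NA_character_, nrow(records)),
      read_count = rep(1L, nrow(records)),
      is_complete = rep(TRUE, nrow(records)),
      out_of_frame = rep(FALSE, nrow(records)),
      rep(NA_character_, nrow(records))
    )
  }
  records <- records[, RECORD_COLS]
  if (nrow(records) > 0) {
    bad <- !is.na(records$locus) & !(records$locus %in% ALL_LOCI)
    if (any(bad)) {
      stop("unknown locus value(s): ",
           paste(unique(records$locus[bad]), collapse = ", "))
    }
    if (any(records$read_count < 0, na.rm = TRUE)) {
      stop("read_count must be non-negative")
    }
    if (sum(records$read_count) > library_reads) {
      stop("`library_reads` must be >= total receptor read support")
    }
  }
  structure(
    list(sample_id = sample_id, records = records,
         library_reads = as.numeric(library_reads)),
    class = "sample_repertoire"
  )
}

#' @export
print.sample_repertoire <- function(x, ...) {
  cat(sprintf("sample_repertoire '%s': %d records, library %s reads\n",
              x$sample_id, nrow(x$records),
              format(x$library_reads, big.mark = ",")))
  if (nrow(x$records) > 0) {
    print(table(x$records$locus))
  }
  invisible(x)
}

# Infer the chain locus from the leading gene symbol of a V/J call,
# e.g. "TRBV7-2*01" -> "TRB".
infer_locus <- function(call) {
  pre <- toupper(substr(call, 1L, 3L))
  pre[!(pre %in% ALL_LOCI)] <- NA_character_
  pre
}

# Fraction of ambiguous bases above which a record is unusable for
# identity-based clustering.
MAX_N_FRACTION <- 0.10

drop_high_n <- function(records, sample_id) {
  if (nrow(records) == 0) return(records)
  n_frac <- ifelse(nchar(records$cdr3_nt) > 0,
                   nchar(gsub("[^N]", "", records$cdr3_nt)) /
                     nchar(records$cdr3_nt), 0)
  n_frac[is.na(n_frac)] <- 0
  bad <- n_frac > MAX_N_FRACTION
  if (any(bad)) {
    warning(sprintf("%s: dropped %d record(s) with > %d%% ambiguous CDR3 bases",
                    sample_id, sum(bad), round(100 * MAX_N_FRACTION)))
    records <- records[!bad, , drop = FALSE]
  }
  records
}

first_present <- function(df, candidates) {
  hit <- candidates[candidates %in% names(df)]
  if (length(hit)) hit[[1L]] else NULL
}

#' Read an AIRR Rearrangement TSV
#'
#' Parses a tab-separated rearrangement table following the AIRR/MiAIRR
#' column conventions (`v_call`, `j_call`, `junction`/`cdr3`,
#' `junction_aa`/`cdr3_aa`, optional `locus`, `productive`, `complete_vdj`
#' and count columns). When no locus column is present the locus is inferred
#' from the `v_call` prefix. Count precedence is `consensus_count` over
#' `duplicate_count` over `count`; with none present every row counts 1.
#' Records whose CDR3 is more than 10% ambiguous bases are dropped with a
#' warning.
#'
#' @param path TSV file path.
#' @param sample_id sample identifier attached to every record.
#' @param library_reads total RNA-seq library reads for the sample.
#' @return a [sample_repertoire()].
#' @export
read_airr_table <- function(path, sample_id, library_reads) {
  if (file.exists(path) && file.size(path) == 0) {
    return(sample_repertoire(sample_id,
                             data.frame(sequence_id = character(0)),
                             library_reads))
  }
  df <- as.data.frame(data.table::fread(path, sep = "\t",
                                        data.table = FALSE,
                                        showProgress = FALSE))
  nt_col <- first_present(df, c("junction", "cdr3"))
  aa_col <- first_present(df, c("junction_aa", "cdr3_aa"))
  if (nrow(df) == 0 && ncol(df) <= 1) {
    # header-only files can be read with no columns by fread; re-read header
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    df <- as.data.frame(setNames(rep(list(character(0)), length(hdr)), hdr))
    nt_col <- first_present(df, c("junction", "cdr3"))
    aa_col <- first_present(df, c("junction_aa", "cdr3_aa"))
  }
  for (needed in c("v_call", "j_call")) {
    if (!needed %in% names(df)) {
      stop(sprintf("AIRR table '%s' is missing mandatory column '%s'",
                   path, needed))
    }
  }
  if (is.null(nt_col)) {
    stop(sprintf("AIRR table '%s' is missing mandatory column 'junction'/'cdr3'",
                 path))
  }
  n <- nrow(df)
  blank_to_na <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & !nzchar(x)] <- NA_character_
    x
  }
  df$v_call <- blank_to_na(df$v_call)
  df$j_call <- blank_to_na(df$j_call)
  if ("d_call" %in% names(df)) df$d_call <- blank_to_na(df$d_call)
  count_col <- first_present(df, c("consensus_count", "duplicate_count",
                                   "count"))
  read_count <- if (is.null(count_col)) rep(1L, n) else {
    rc <- suppressWarnings(as.integer(df[[count_col]]))
    rc[is.na(rc)] <- 1L
    rc
  }
  locus <- if ("locus" %in% names(df) && n > 0) {
    lo <- as.character(df$locus)
    miss <- is.na(lo) | !nzchar(lo)
    lo[miss] <- infer_locus(df$v_call[miss])
    lo
  } else {
    infer_locus(df$v_call)
  }
  cdr3_nt <- toupper(as.character(df[[nt_col]]))
  cdr3_nt[is.na(cdr3_nt)] <- ""
  cdr3_aa <- if (is.null(aa_col)) translate_cdr3(cdr3_nt) else {
    aa <- as.character(df[[aa_col]])
    aa[is.na(aa)] <- ""
    aa
  }
  cdr3_aa[is.na(cdr3_aa)] <- ""
  complete_col <- first_present(df, c("is_complete", "complete_vdj"))
  is_complete <- if (!is.null(complete_col)) {
    as_airr_logical(df[[complete_col]])
  } else {
    # canonical junction anchors: cysteine start, phenylalanine or
    # tryptophan end (TRUST4 convention for fully assembled CDR3s)
    grepl("^C.*[FW]$", cdr3_aa)
  }
  out_of_frame <- nchar(cdr3_nt) %% 3L != 0L & nzchar(cdr3_nt)
  records <- data.frame(
    sequence_id = if ("sequence_id" %in% names(df) && n > 0)
      as.character(df$sequence_id) else sprintf("%s_seq%04d", sample_id,
                                                seq_len(n)),
    v_call = as.character(df$v_call),
    d_call = if ("d_call" %in% names(df)) as.character(df$d_call)
             else rep(NA_character_, n),
    j_call = as.character(df$j_call),
    locus = locus,
    cdr3_nt = cdr3_nt,
    cdr3_aa = cdr3_aa,
    read_count = read_count,
    is_complete = is_complete,
    out_of_frame = out_of_frame,
    stringsAsFactors = FALSE
  )
  records <- drop_high_n(records, sample_id)
  sample_repertoire(sample_id, records, library_reads)
}

as_airr_logical <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("t", "true", "1", "yes")
}

TRUST4_COLS <- c("count", "frequency", "CDR3nt", "CDR3aa", "V", "D", "J", "C")

#' Read a TRUST4 simple report
#'
#' Parses the TRUST4 `report.tsv` dialect (columns `count, frequency, CDR3nt,
#' CDR3aa, V, D, J, C`, first header field possibly prefixed with `#`). Rows
#' whose `CDR3aa` equals `out_of_frame` are loaded with the out-of-frame flag
#' set so the productivity filter can remove them explicitly.
#'
#' @inheritParams read_airr_table
#' @return a [sample_repertoire()].
#' @export
read_trust4_report <- function(path, sample_id, library_reads) {
  hdr_line <- readLines(path, n = 1L)
  hdr <- sub("^#", "", strsplit(hdr_line, "\t", fixed = TRUE)[[1]])
  if (!all(TRUST4_COLS %in% hdr)) {
    stop(sprintf("'%s' does not look like a TRUST4 simple report (expected columns: %s)",
                 path, paste(TRUST4_COLS, collapse = ", ")))
  }
  n_lines <- length(readLines(path))
  if (n_lines < 2) {
    return(sample_repertoire(sample_id, EMPTY_RECORDS, library_reads))
  }
  df <- as.data.frame(data.table::fread(path, sep = "\t", skip = 1L,
                                        header = FALSE, data.table = FALSE,
                                        showProgress = FALSE))
  names(df) <- hdr[seq_len(ncol(df))]
  oof <- tolower(as.character(df$CDR3aa)) == "out_of_frame"
  cdr3_nt <- toupper(as.character(df$CDR3nt))
  cdr3_aa <- as.character(df$CDR3aa)
  cdr3_aa[oof] <- ""
  v_call <- as.character(df$V)
  v_call[v_call == "."] <- NA_character_
  j_call <- as.character(df$J)
  j_call[j_call == "."] <- NA_character_
  d_call <- as.character(df$D)
  d_call[d_call == "."] <- NA_character_
  locus <- infer_locus(ifelse(is.na(v_call), j_call, v_call))
  records <- data.frame(
    sequence_id = sprintf("%s_trust4_%04d", sample_id, seq_len(nrow(df))),
    v_call = v_call, d_call = d_call, j_call = j_call,
    locus = locus, cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
    read_count = as.integer(df$count),
    is_complete = grepl("^C.*[FW]$", cdr3_aa),
    out_of_frame = oof | (nzchar(cdr3_nt) & nchar(cdr3_nt) %% 3L != 0L),
    stringsAsFactors = FALSE
  )
  records <- drop_high_n(records, sample_id)
  sample_repertoire(sample_id, records, library_reads)
}

#' Keep only productive rearrangements with a complete CDR3
#'
#' Retains records that are (a) non-empty in CDR3 nucleotides, (b) in frame
#' (length divisible by 3, not flagged out-of-frame, and consistent with the
#' reported amino-acid junction), (c) free of premature stop codons (`*`),
#' and (d) flagged as having a completely assembled CDR3. Record order is
#' preserved; the operation is idempotent.
#'
#' @param rep a [sample_repertoire()].
#' @return filtered [sample_repertoire()].
#' @export
filter_productive <- function(rep) {
  stopifnot(inherits(rep, "sample_repertoire"))
  rec <- rep$records
  if (nrow(rec) == 0) return(rep)
  nt <- rec$cdr3_nt
  nt[is.na(nt)] <- ""
  aa <- rec$cdr3_aa
  aa[is.na(aa)] <- ""
  keep <- nzchar(nt) & nchar(nt) %% 3L == 0L & !rec$out_of_frame
  # translational consistency: frame-0 translation must agree with the
  # reported junction amino acids wherever neither side is ambiguous
  if (any(keep)) {
    tr <- translate_cdr3(nt)
    consistent <- !logical(nrow(rec))
    has_aa <- nzchar(aa) & !is.na(tr)
    idx <- which(keep & has_aa & tr != aa)  # exact matches need no char scan
    if (length(idx)) {
      consistent[idx] <- mapply(aa_consistent, tr[idx], aa[idx])
    }
    # no reported junction: adopt the translation for the stop-codon test
    idx2 <- which(keep & !nzchar(aa) & !is.na(tr))
    aa[idx2] <- tr[idx2]
    keep <- keep & consistent
  }
  keep <- keep & !grepl("*", aa, fixed = TRUE) & nzchar(aa)
  keep <- keep & rec$is_complete
  out <- rep
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

# Positions where either side is ambiguous ('X' from N-containing codons,
# '_' partial markers) do not count as disagreement.
aa_consistent <- function(translated, reported) {
  if (nchar(translated) != nchar(reported)) return(FALSE)
  a <- strsplit(translated, "")[[1]]
  b <- strsplit(reported, "")[[1]]
  amb <- a %in% c("X", "_") | b %in% c("X", "_")
  all(a[amb == FALSE] == b[amb == FALSE])
}

#' Write a repertoire as an AIRR Rearrangement TSV
#'
#' Emits the MiAIRR column set (`sequence_id, v_call, d_call, j_call,
#' junction, junction_aa, productive, consensus_count, locus, complete_vdj`)
#' so that [read_airr_table()] round-trips every stored field.
#'
#' @param rep a [sample_repertoire()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(rep, path) {
  stopifnot(inherits(rep, "sample_repertoire"))
  rec <- rep$records
  out <- data.frame(
    sequence_id = if (nrow(rec)) rec$sequence_id else character(0),
    v_call = rec$v_call,
    d_call = rec$d_call,
    j_call = rec$j_call,
    junction = rec$cdr3_nt,
    junction_aa = rec$cdr3_aa,
    productive = !rec$out_of_frame & !grepl("*", rec$cdr3_aa, fixed = TRUE),
    consensus_count = rec$read_count,
    locus = rec$locus,
    complete_vdj = rec$is_complete,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write rearrangement table to '", path,
                        "': ", conditionMessage(ok))
  invisible(path)
}
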