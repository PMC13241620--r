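# Independent oracles and fixture builders shared across the suite.
# The oracles deliberately use naive algorithms (double loops, DFS) so they
# share no code path with the package implementation they check.

# --- record / repertoire fixtures -----------------------------------------

make_records <- function(cdr3_nt, v_call = "TRBV7-2*01",
                         j_call = "TRBJ2-1*01", locus = NULL,
                         read_count = 1L, cdr3_aa = NULL,
                         is_complete = TRUE, out_of_frame = FALSE,
                         sequence_id = NULL) {
  n <- length(cdr3_nt)
  if (is.null(sequence_id)) sequence_id <- sprintf("seq%03d", seq_len(n))
  if (is.null(locus)) locus <- substr(rep_len(v_call, n), 1, 3)
  if (is.null(cdr3_aa)) cdr3_aa <- translate_cdr3(cdr3_nt)
  data.frame(
    sequence_id = sequence_id,
    v_call = rep_len(v_call, n), d_call = rep(NA_character_, n),
    j_call = rep_len(j_call, n),
    locus = rep_len(locus, n),
    cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
    read_count = rep_len(read_count, n),
    is_complete = rep_len(is_complete, n),
    out_of_frame = rep_len(out_of_frame, n),
    stringsAsFactors = FALSE
  )
}

make_rep <- function(records, sample_id = "S1", library_reads = 1e6) {
  sample_repertoire(sample_id, records, library_reads)
}

# random in-frame CDR3 (anchored C ... F/W, no stop codons), like the
# generator emits but built independently here
rand_cdr3 <- function(len_nt) {
  stopifnot(len_nt %% 3 == 0, len_nt >= 9)
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("TGT",
         paste(sample(codons, len_nt / 3 - 2, replace = TRUE),
               collapse = ""),
         sample(c("TTT", "TGG"), 1))
}

# mutate exactly k positions of a sequence (may hit anchors; fine for
# clustering tests, which ignore productivity)
mutate_at <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# --- clustering oracle -----------------------------------------------------

# naive pairwise identity: double character loop
oracle_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  hits <- 0
  for (i in seq_along(av)) {
    if (av[i] == bv[i] && av[i] != "N") hits <- hits + 1
  }
  hits / length(av)
}

# brute-force single-linkage components via DFS over the all-pairs graph;
# returns a list of character vectors of sequence_ids, canonicalised
oracle_single_linkage <- function(seqs, ids, threshold) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) adj[i, j] <- oracle_identity(seqs[i], seqs[j]) >= threshold
    }
  }
  visited <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (visited[s]) next
    stack <- s
    comp <- integer(0)
    while (length(stack)) {
      v <- stack[[1]]
      stack <- stack[-1]
      if (visited[v]) next
      visited[v] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, which(adj[v, ] & !visited))
    }
    comps[[length(comps) + 1]] <- sort(ids[comp])
  }
  canonicalise_partition(comps)
}

canonicalise_partition <- function(comps) {
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[[`, character(1), 1))]
}

# partition of a clone_set as a canonical list of sequence-id vectors
partition_of <- function(clone_set) {
  canonicalise_partition(
    unname(split(clone_set$membership$sequence_id,
                 clone_set$membership$clone_id))
  )
}

# --- BH step-up oracle -----------------------------------------------------

# textbook formulation: p_(i) * m / i, running minimum from the largest
# rank downwards, computed with an explicit loop
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, ps[i] * m / i)
    adj[i] <- running
  }
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# --- misc ------------------------------------------------------------------

expect_same_partition <- function(a, b) {
  expect_equal(length(a), length(b))
  expect_identical(a, b)
}
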