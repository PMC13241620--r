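test_that("cdr3_identity matches the position-count definition", {
  expect_equal(cdr3_identity("ATGCATGC", "ATGCATGC"), 1.0)
  expect_equal(cdr3_identity("ATGCATGC", "ATGCATGG"), 0.875)
  # 18/20 positions agree
  expect_equal(cdr3_identity("ATGCATGCATGCATGCATGC",
                             "ATGCATGCATGCATGCATTT"), 0.90)
  # symmetric, and N never matches (even N vs N)
  expect_equal(cdr3_identity("ATGN", "ATGN"), 0.75)
  expect_equal(cdr3_identity("ATGN", "ATGA"), cdr3_identity("ATGA", "ATGN"))
  expect_error(cdr3_identity("ATG", "ATGC"), "equal")
  # random pairs agree with the naive double-loop oracle
  set.seed(5)
  for (i in 1:25) {
    a <- rand_cdr3(12)
    b <- mutate_at(a, sample(0:6, 1))
    expect_equal(cdr3_identity(a, b), oracle_identity(a, b))
  }
})

test_that("partition_group handles chained, identical and split cases", {
  # chain A-B-C: id(A,B) and id(B,C) = 0.95, id(A,C) = 0.90 -> one clone
  # at threshold 0.95 via single linkage
  A <- "ATGCATGCATGCATGCATGC"
  B <- "ATGCATGCATGCATGCATGG"            # 19/20 = 0.95 vs A
  C <- "ATGCATGCATGCATGCATTG"            # 19/20 vs B, 18/20 = 0.90 vs A
  expect_equal(cdr3_identity(A, B), 0.95)
  expect_equal(cdr3_identity(B, C), 0.95)
  expect_equal(cdr3_identity(A, C), 0.90)
  rec <- make_records(c(A, B, C))
  comps <- partition_group(rec, 0.95)
  expect_equal(length(comps), 1L)

  # identical sequences always merge; reads aggregate in assign_clones
  rec2 <- make_records(c(A, A), read_count = c(2L, 3L))
  cs <- assign_clones(make_rep(rec2))
  expect_equal(cs$n_unique, 1L)
  expect_equal(cs$clones$total_reads, 5)

  # 0.85 identity at threshold 0.90 stays split
  D <- mutate_at(A, 3)
  expect_lt(cdr3_identity(A, D), 0.90)
  comps2 <- partition_group(make_records(c(A, D)), 0.90)
  expect_equal(length(comps2), 2L)

  # identity exactly at threshold joins (inclusive "at least")
  comps3 <- partition_group(make_records(c(A, C)), 0.90)
  expect_equal(length(comps3), 1L)

  # mixed lengths violate the precondition
  expect_error(partition_group(make_records(c(A, substr(A, 1, 12))), 0.9),
               "precondition")
})

test_that("assign_clones groups by locus, V, J, length and threshold class", {
  nt <- "TGTGCCAGCAGCTTGGGGTTT"
  # same gene different allele: one clone at gene level, two at allele level
  rec <- make_records(c(nt, nt), v_call = c("TRBV7-2*01", "TRBV7-2*02"))
  expect_equal(assign_clones(make_rep(rec))$n_unique, 1L)
  cfg_allele <- clonotyping_config(gene_match_level = "allele")
  expect_equal(assign_clones(make_rep(rec), cfg_allele)$n_unique, 2L)

  # single record and empty repertoire
  one <- assign_clones(make_rep(make_records(nt, read_count = 7L)))
  expect_equal(one$n_unique, 1L)
  expect_equal(one$n_reads, 7)
  empty <- assign_clones(make_rep(make_records(character(0))))
  expect_equal(empty$n_unique, 0L)

  # records missing V or J are excluded and counted
  rec2 <- make_records(c(nt, nt))
  rec2$v_call[2] <- NA
  cs <- assign_clones(make_rep(rec2))
  expect_equal(cs$n_unique, 1L)
  expect_equal(attr(cs, "unassigned"), 1L)

  # BCR vs TCR thresholds: 18/20 identity merges IGH (0.90) but not TRB (0.95)
  A <- "TGTCATGCATGCATGCATGG"
  B <- "TGTCATGCATGCATGCGGGG"
  expect_equal(cdr3_identity(A, B), 0.90)
  bcr <- make_records(c(A, B), v_call = "IGHV3-23*01", j_call = "IGHJ4*01")
  tcr <- make_records(c(A, B))
  expect_equal(assign_clones(make_rep(bcr))$n_unique, 1L)
  expect_equal(assign_clones(make_rep(tcr))$n_unique, 2L)
})

test_that("assign_clones equals the brute-force single-linkage oracle", {
  set.seed(101)
  cfg <- clonotyping_config()
  for (i in 1:50) {
    L <- 3 * sample(3:15, 1)
    n <- sample(2:12, 1)
    base <- rand_cdr3(L)
    seqs <- c(base, vapply(seq_len(n - 1), function(j)
      mutate_at(base, sample(0:min(L, 8), 1)), character(1)))
    locus <- sample(c("IGH", "TRB"), 1)
    thr <- if (locus == "IGH") 0.90 else 0.95
    rec <- make_records(seqs,
                        v_call = paste0(locus, "V1*01"),
                        j_call = paste0(locus, "J1*01"),
                        read_count = sample(1:9, n, replace = TRUE))
    cs <- assign_clones(make_rep(rec), cfg)
    expect_same_partition(
      partition_of(cs),
      oracle_single_linkage(seqs, rec$sequence_id, thr)
    )
  }
})

test_that("clone partition is invariant to input order and ids deterministic", {
  set.seed(77)
  L <- 24
  base <- rand_cdr3(L)
  seqs <- c(base, vapply(1:9, function(i) mutate_at(base, sample(1:5, 1)),
                         character(1)))
  rec <- make_records(seqs, read_count = sample(1:9, 10, replace = TRUE))
  cs1 <- assign_clones(make_rep(rec))
  perm <- sample(nrow(rec))
  cs2 <- assign_clones(make_rep(rec[perm, ]))
  expect_same_partition(partition_of(cs1), partition_of(cs2))
  expect_identical(sort(cs1$clones$clone_id), sort(cs2$clones$clone_id))
  expect_identical(cs1$clones, cs2$clones)
})

test_that("raising the threshold never decreases the clone count", {
  set.seed(88)
  for (i in 1:10) {
    base <- rand_cdr3(30)
    seqs <- vapply(1:8, function(j) mutate_at(base, sample(0:6, 1)),
                   character(1))
    rec <- make_records(seqs)
    n_clones <- vapply(c(0.80, 0.90, 0.95, 1.0), function(thr) {
      cfg <- clonotyping_config(bcr_identity_threshold = thr,
                                tcr_identity_threshold = thr)
      assign_clones(make_rep(rec), cfg)$n_unique
    }, integer(1))
    expect_true(all(diff(n_clones) >= 0))
  }
})

test_that("reads are conserved: clone totals equal record totals per locus", {
  set.seed(99)
  params <- simulation_params(loci = c("IGH", "TRB"), read_scale = 0.3)
  rec <- rbind(simulate_repertoire("LSP", "IGH", params, "S1"),
               simulate_repertoire("LSP", "TRB", params, "S1"))
  rep <- make_rep(rec, library_reads = sum(rec$read_count) + 10)
  cs <- assign_clones(filter_productive(rep))
  for (lo in c("IGH", "TRB")) {
    expect_equal(sum(cs$clones$total_reads[cs$clones$locus == lo]),
                 sum(rec$read_count[rec$locus == lo]))
  }
})
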