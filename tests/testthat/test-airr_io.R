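test_that("read_airr_table parses records, counts and inferred loci", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sequence_id\tv_call\tj_call\tjunction\tjunction_aa\tconsensus_count",
    "a1\tTRBV7-2*01\tTRBJ2-1*01\tTGTGCCAGCAGCTTGGGG\tCASSLG\t5",
    "a2\tTRBV7-2*01\tTRBJ2-1*01\tTGTGCCAGCAGCTTGTGG\tCASSLW\t3"
  ), tmp)
  rep <- read_airr_table(tmp, "S1", 1e6)
  expect_s3_class(rep, "sample_repertoire")
  expect_equal(nrow(rep$records), 2)
  expect_equal(rep$records$read_count, c(5L, 3L))
  expect_equal(rep$records$locus, c("TRB", "TRB"))
  expect_equal(rep$records$cdr3_nt[1], "TGTGCCAGCAGCTTGGGG")

  # IGK inferred from the v_call prefix without a locus column
  writeLines(c(
    "v_call\tj_call\tjunction\tjunction_aa",
    "IGKV1-5*01\tIGKJ1*01\tTGTCAACAGTTT\tCQQF"
  ), tmp)
  rep2 <- read_airr_table(tmp, "S2", 1000)
  expect_equal(rep2$records$locus, "IGK")
  expect_equal(rep2$records$read_count, 1L)  # no count column => 1

  # header-only and zero-byte files are empty repertoires, not errors
  writeLines("sequence_id\tv_call\tj_call\tjunction", tmp)
  expect_equal(nrow(read_airr_table(tmp, "S3", 10)$records), 0)
  file.create(tmp)
  writeLines(character(0), tmp)
  expect_equal(nrow(read_airr_table(tmp, "S4", 10)$records), 0)
})

test_that("read_airr_table rejects tables missing mandatory columns", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("v_call\tjunction", "TRBV7-2\tTGTGCC"), tmp)
  expect_error(read_airr_table(tmp, "S1", 10), "j_call")
  writeLines(c("v_call\tj_call", "TRBV7-2\tTRBJ2-1"), tmp)
  expect_error(read_airr_table(tmp, "S1", 10), "junction")
})

test_that("count precedence is consensus_count > duplicate_count > count", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "v_call\tj_call\tjunction\tduplicate_count\tconsensus_count\tcount",
    "TRBV7-2\tTRBJ2-1\tTGTGCCAGCTTT\t7\t4\t9"
  ), tmp)
  expect_equal(read_airr_table(tmp, "S", 100)$records$read_count, 4L)
  writeLines(c(
    "v_call\tj_call\tjunction\tduplicate_count\tcount",
    "TRBV7-2\tTRBJ2-1\tTGTGCCAGCTTT\t7\t9"
  ), tmp)
  expect_equal(read_airr_table(tmp, "S", 100)$records$read_count, 7L)
})

test_that("records with >10% ambiguous CDR3 bases are dropped with warning", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "v_call\tj_call\tjunction",
    "TRBV7-2\tTRBJ2-1\tTGTNNNNNNTTT",      # 6/12 N: dropped
    "TRBV7-2\tTRBJ2-1\tTGTGCCAGCNTT"       # 1/12 N: kept
  ), tmp)
  expect_warning(rep <- read_airr_table(tmp, "S", 100), "ambiguous")
  expect_equal(nrow(rep$records), 1)
})

test_that("read_trust4_report maps the dialect and flags out-of-frame rows", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "#count\tfrequency\tCDR3nt\tCDR3aa\tV\tD\tJ\tC",
    "8\t0.5\tTGTGCCAGCAGCTTGTTT\tCASSLF\tTRBV7-2\t.\tTRBJ2-1\t.",
    "3\t0.2\tTGTGCCAGCAGCTTGTT\tout_of_frame\tTRBV7-2\t.\tTRBJ2-1\t."
  ), tmp)
  rep <- read_trust4_report(tmp, "S1", 1e5)
  expect_equal(nrow(rep$records), 2)
  expect_equal(rep$records$read_count[1], 8L)
  expect_equal(rep$records$locus[1], "TRB")
  expect_equal(rep$records$v_call[1], "TRBV7-2")
  expect_true(rep$records$out_of_frame[2])
  expect_false(rep$records$out_of_frame[1])

  # empty report
  writeLines("#count\tfrequency\tCDR3nt\tCDR3aa\tV\tD\tJ\tC", tmp)
  expect_equal(nrow(read_trust4_report(tmp, "S1", 10)$records), 0)

  # unrecognised header is a format error
  writeLines(c("a\tb\tc", "1\t2\t3"), tmp)
  expect_error(read_trust4_report(tmp, "S1", 10), "TRUST4")
})

test_that("filter_productive keeps exactly in-frame, stop-free, complete CDR3s", {
  rec <- make_records(
    cdr3_nt = c("TGTGCCAGCTTT",   # productive, kept
                "TGTGCCTAATTT",   # internal stop codon
                "TGTGCCAGCTT",    # out of frame (11 nt)
                "",               # no CDR3
                "TGTGCCAGCTGG"),  # productive but incomplete flag
    is_complete = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  rec$out_of_frame <- nchar(rec$cdr3_nt) %% 3 != 0 & nzchar(rec$cdr3_nt)
  rep <- make_rep(rec)
  kept <- filter_productive(rep)
  expect_equal(kept$records$sequence_id, "seq001")

  # stop codon in the reported junction is enough for removal
  rec2 <- make_records("TGTGCCAGCTTT", cdr3_aa = "CA*F")
  expect_equal(nrow(filter_productive(make_rep(rec2))$records), 0)

  # inconsistent reported junction vs translation is removed
  rec3 <- make_records("TGTGCCAGCTTT", cdr3_aa = "CGGF")
  expect_equal(nrow(filter_productive(make_rep(rec3))$records), 0)

  # 'X' ambiguity does not count as disagreement
  rec4 <- make_records("TGTGCCNGCTTT", cdr3_aa = "CAXF")
  expect_equal(nrow(filter_productive(make_rep(rec4))$records), 1)
})

test_that("filter_productive is idempotent and order-preserving", {
  set.seed(11)
  nt <- vapply(rep(12, 8), rand_cdr3, character(1))
  rec <- make_records(nt, read_count = sample(1:5, 8, replace = TRUE))
  rec$is_complete[c(2, 5)] <- FALSE
  rep <- make_rep(rec)
  once <- filter_productive(rep)
  twice <- filter_productive(once)
  expect_identical(once$records, twice$records)
  expect_identical(once$records$sequence_id,
                   rec$sequence_id[rec$is_complete])
})

test_that("write/read round-trips a repertoire field-wise", {
  set.seed(21)
  nt <- vapply(rep(15, 3), rand_cdr3, character(1))
  rec <- make_records(nt, read_count = c(4L, 2L, 1L))
  rep <- make_rep(rec, sample_id = "RT", library_reads = 5000)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_rearrangements(rep, tmp)
  back <- read_airr_table(tmp, "RT", 5000)
  for (col in c("sequence_id", "v_call", "j_call", "locus", "cdr3_nt",
                "cdr3_aa", "read_count", "is_complete", "out_of_frame")) {
    expect_equal(back$records[[col]], rep$records[[col]], label = col)
  }
  # empty repertoire -> header-only file -> empty repertoire
  e <- make_rep(make_records(character(0)))
  write_rearrangements(e, tmp)
  expect_equal(nrow(read_airr_table(tmp, "RT", 10)$records), 0)
})

test_that("locus inference agrees with an explicit locus column", {
  set.seed(31)
  vs <- c("IGHV3-23*01", "IGKV1-5*01", "IGLV2-14*01", "TRAV1-2*01",
          "TRBV7-2*01", "TRDV1*01", "TRGV9*01")
  nt <- vapply(rep(12, length(vs)), rand_cdr3, character(1))
  rec <- make_records(nt, v_call = vs, j_call = "XXX")
  rec$j_call <- paste0(substr(vs, 1, 3), "J1*01")
  rep <- make_rep(rec)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_rearrangements(rep, tmp)  # writes explicit locus column
  with_locus <- read_airr_table(tmp, "S", 1e6)
  tbl <- read.delim(tmp)
  tbl$locus <- NULL
  write.table(tbl, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  without_locus <- read_airr_table(tmp, "S", 1e6)
  expect_equal(without_locus$records$locus, with_locus$records$locus)
  expect_equal(with_locus$records$locus, substr(vs, 1, 3))
})

test_that("sample_repertoire enforces its invariants", {
  rec <- make_records("TGTGCCAGCTTT", read_count = 10L)
  expect_error(sample_repertoire("S", rec, 5), "library_reads")
  expect_error(sample_repertoire("S", rec, -1), "positive")
  rec$locus <- "ABC"
  expect_error(sample_repertoire("S", rec, 100), "locus")
})
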