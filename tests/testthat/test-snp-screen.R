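test_that("longest-isoform reduction keeps one maximal transcript per component", {
  tx <- make_transcripts(
    c("c1_seq1", "c1_seq2", "c2_seq1", "c3_seqB", "c3_seqA"),
    c("c1", "c1", "c2", "c3", "c3"),
    c(strrep("A", 500), strrep("A", 800), "ACGT",
      strrep("C", 800), strrep("G", 800))
  )
  cat <- dedup_longest_isoform(tx)
  expect_equal(cat$transcript_id[cat$component_id == "c1"], "c1_seq2")
  expect_equal(cat$length[cat$component_id == "c1"], 800L)
  # single-isoform component kept unchanged
  expect_equal(cat$transcript_id[cat$component_id == "c2"], "c2_seq1")
  # length tie broken by lexicographically smallest id
  expect_equal(cat$transcript_id[cat$component_id == "c3"], "c3_seqA")
  expect_setequal(attr(cat, "discarded"), c("c1_seq1", "c3_seqB"))
  expect_equal(nrow(dedup_longest_isoform(tx[0, ])), 0)
})

test_that("frequencies follow allele counts, zero depth is flagged undefined", {
  v <- make_variants("t1", c(0, 1, 2), "A", "G",
                     ref_a = c(90, 0, 0), alt_a = c(10, 120, 0),
                     ref_b = c(50, 50, 50), alt_b = c(50, 50, 50))
  f <- estimate_frequencies(v)
  expect_equal(f$f_a, c(0.10, 1.0, NA))
  expect_equal(f$maf_a, c(0.10, 0.0, NA))
  expect_equal(f$depth_a, c(100L, 120L, 0L))
})

test_that("retention thresholds are inclusive and tallied per rule", {
  cfg <- pipeline_config()
  v <- make_variants("t1", 0:2, "A", "G",
                     ref_a = c(95, 95, 94), alt_a = c(5, 5, 5),
                     ref_b = c(100, 100, 100), alt_b = c(100, 100, 100),
                     qual = c(30, 29.9, 30))
  f <- filter_snps(estimate_frequencies(v), cfg)
  # site 1: MAF exactly 0.05, qual exactly 30, depth exactly 100 -> retained
  expect_true(f$pass_a[1])
  expect_false(f$pass_a[2])  # quality just below
  expect_false(f$pass_a[3])  # depth 99
  tally <- attr(f, "tally")
  expect_equal(tally$fail_qual, 1L)
  expect_equal(tally$fail_depth_a, 1L)
  expect_equal(tally$retained_b, 2L)
})

test_that("filtering matches a row-by-row re-application of the rules", {
  set.seed(7)
  n <- 60
  v <- make_variants(rep("t1", n), seq_len(n) - 1, "A", "G",
                     ref_a = sample(0:150, n, TRUE),
                     alt_a = sample(0:20, n, TRUE),
                     ref_b = sample(0:150, n, TRUE),
                     alt_b = sample(0:20, n, TRUE),
                     qual = sample(c(10, 29, 30, 45), n, TRUE))
  cfg <- pipeline_config()
  f <- filter_snps(estimate_frequencies(v), cfg)
  oracle <- oracle_filter(f, cfg)
  expect_equal(f$pass_a, oracle$pass_a)
  expect_equal(f$pass_b, oracle$pass_b)
})

test_that("sharing classification follows the declared rules", {
  v <- make_variants(
    "t1", 0:4, "A", "G",
    ref_a = c(500, 700, 700, 980, 0),
    alt_a = c(500, 300, 300, 20, 1000),
    ref_b = c(500, 1000, 0, 990, 1000),
    alt_b = c(500, 0, 0, 10, 0)
  )
  v <- compute_D(classify_sharing(filter_snps(estimate_frequencies(v))))
  expect_equal(v$class, c("common", "specificA", "uncallable",
                          "filtered", "filtered"))
  # oppositely fixed site rescued for D despite failing per-species MAF
  expect_true(v$d_callable[5])
  expect_equal(v$D[5], 1.0)
  expect_false(v$d_callable[4])
})

test_that("classification is an exact partition and monotone in depth_min", {
  set.seed(11)
  n <- 300
  v <- make_variants(rep("t1", n), seq_len(n) - 1, "A", "G",
                     ref_a = sample(0:200, n, TRUE),
                     alt_a = sample(0:60, n, TRUE),
                     ref_b = sample(0:200, n, TRUE),
                     alt_b = sample(0:60, n, TRUE),
                     qual = sample(c(20, 35, 50), n, TRUE))
  f <- estimate_frequencies(v)
  classes <- function(depth_min) {
    cfg <- pipeline_config(depth_min = depth_min)
    attr(classify_sharing(filter_snps(f, cfg), cfg), "class_tally")
  }
  for (dm in c(50, 100, 150)) {
    tally <- classes(dm)
    expect_equal(sum(unlist(tally)), n)
  }
  lo <- classes(100)
  hi <- classes(160)
  for (cl in c("specificA", "specificB", "common")) {
    expect_lte(hi[[cl]], lo[[cl]])
  }
})
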