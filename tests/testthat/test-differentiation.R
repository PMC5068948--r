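test_that("D is the absolute frequency difference, with declared invariances", {
  v <- variants_from_freqs(f_a = c(1.0, 0.3, 0.97), f_b = c(0.0, 0.3, 0.02))
  expect_equal(v$D, c(1.0, 0.0, 0.95))
  # swapping species labels leaves D unchanged
  vs <- variants_from_freqs(f_a = c(0.0, 0.3, 0.02), f_b = c(1.0, 0.3, 0.97))
  expect_equal(vs$D, v$D)
  # flipping ref/alt orientation in BOTH species leaves D unchanged
  vf <- variants_from_freqs(f_a = 1 - c(1.0, 0.3, 0.97),
                            f_b = 1 - c(0.0, 0.3, 0.02))
  expect_equal(vf$D, v$D)
  expect_true(all(v$D >= 0 & v$D <= 1))
})

test_that("D-bar equals the group mean, checked against an independent group-by", {
  # worked micro-example
  v <- variants_from_freqs(f_a = c(1.0, 0.95, 1.0), f_b = c(0, 0.05, 0.05))
  cat <- make_transcripts("t1", "u1", strrep("A", 10))
  cat <- dedup_longest_isoform(cat)
  rec <- compute_Dbar(v, cat)
  expect_equal(rec$dbar, mean(c(1.0, 0.9, 0.95)))
  expect_equal(rec$n_snps, 3L)

  # 100 unigenes with random SNP lists vs a tapply oracle
  set.seed(21)
  n <- 600
  comp <- sprintf("u%03d", sample(100, n, replace = TRUE))
  f_a <- runif(n, 0.06, 0.94)
  f_b <- runif(n, 0.06, 0.94)
  v2 <- variants_from_freqs(f_a, f_b, transcript = comp,
                            position = seq_along(comp) - 1L)
  cat2 <- dedup_longest_isoform(
    make_transcripts(unique(comp), unique(comp),
                     rep(strrep("A", 700), length(unique(comp)))))
  rec2 <- compute_Dbar(v2, cat2)
  oracle <- tapply(abs(v2$f_a - v2$f_b), v2$transcript_id, mean)
  expect_equal(rec2$dbar, as.numeric(oracle[rec2$component_id]))
  expect_true(all(rec2$dbar >= rec2$d_min & rec2$dbar <= rec2$d_max))

  # SNPs on discarded isoforms never enter D-bar
  tx3 <- make_transcripts(c("u1_seq1", "u1_seq2"), "u1",
                          c(strrep("A", 20), strrep("A", 10)))
  cat3 <- dedup_longest_isoform(tx3)
  v3 <- variants_from_freqs(c(1, 0.2), c(0, 0.8),
                            transcript = c("u1_seq1", "u1_seq2"),
                            position = c(0L, 0L))
  rec3 <- compute_Dbar(v3, cat3)
  expect_equal(rec3$n_snps, 1L)
  expect_equal(rec3$dbar, 1.0)
})

test_that("divergent selection is inclusive at the threshold and binned right-closed", {
  rec <- data.frame(component_id = c("a", "b", "c"),
                    transcript_id = c("a", "b", "c"),
                    n_snps = c(1L, 1L, 1L),
                    dbar = c(0.94, 0.9399, 0.95),
                    d_min = 0, d_max = 1, stringsAsFactors = FALSE)
  v <- variants_from_freqs(c(0.99, 0.5), c(0.05, 0.5))
  sel <- select_divergent(rec, v, pipeline_config())
  expect_setequal(sel$unigenes$component_id, c("a", "c"))
  expect_equal(nrow(sel$snps), 1)
  expect_equal(sum(sel$histogram$count), 3)
  expect_equal(sel$histogram$count[sel$histogram$bin == "(0.9,0.95]"], 3)

  none <- select_divergent(rec[rec$dbar < 0.9, ], v[0, ], pipeline_config())
  expect_equal(nrow(none$unigenes), 0)
})

test_that("Nei identity and distance follow the per-locus formula", {
  # identical frequency profiles
  same <- nei_identity_distance(c(0.3, 0.8), c(0.3, 0.8))
  expect_equal(same$mean_identity, 1)
  expect_equal(same$distance_of_mean, 0)
  expect_equal(same$mean_of_distances, 0)

  # hand-computed single locus: x = (0.9, 0.1), y = (0.1, 0.9)
  one <- nei_identity_distance(0.9, 0.1)
  expect_equal(one$mean_identity, 0.18 / 0.82, tolerance = 1e-12)

  # orthogonal profiles: identity zero, log-distance undefined but counted
  orth <- nei_identity_distance(1, 0)
  expect_equal(orth$mean_identity, 0)
  expect_true(is.na(orth$distance_of_mean))
  expect_equal(orth$n_zero_identity, 1L)

  expect_error(nei_identity_distance(numeric(0), numeric(0)), "empty")

  # Jensen: -ln(mean I) <= mean(-ln I) on random frequency sets
  set.seed(31)
  for (rep in 1:20) {
    r <- nei_identity_distance(runif(50, 0.01, 0.99), runif(50, 0.01, 0.99))
    expect_lte(r$distance_of_mean, r$mean_of_distances + 1e-12)
  }
})

test_that("estimated D converges to the planted difference with binomial spread", {
  set.seed(41)
  delta <- 0.6
  n_depth <- 400
  f_a_true <- 0.8
  f_b_true <- 0.2
  alt_a <- rbinom(2000, n_depth, f_a_true)
  alt_b <- rbinom(2000, n_depth, f_b_true)
  d_hat <- abs(alt_a / n_depth - alt_b / n_depth)
  expect_equal(mean(d_hat), delta, tolerance = 0.01)
  sd_expected <- sqrt((f_a_true * (1 - f_a_true) +
                         f_b_true * (1 - f_b_true)) / n_depth)
  expect_equal(sd(d_hat), sd_expected, tolerance = 0.1)
})

test_that("normality check behaves on calibrated and degenerate input", {
  set.seed(51)
  normal <- normality_test(rnorm(5000))
  expect_gt(normal$p_value, 0.01)
  # bimodal D-bar-like mixture with peaks near 0.5 and 0.95
  bimodal <- c(rnorm(1500, 0.5, 0.1), rnorm(500, 0.95, 0.02))
  expect_lt(normality_test(bimodal)$p_value, 0.01)
  expect_error(normality_test(rep(0.5, 10)), "constant")
  expect_error(normality_test(c(1, 2)), "at least 3")
})
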