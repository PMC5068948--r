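test_that("substitution typing follows the genetic code and CDS geometry", {
  # transcript: 2 nt UTR, then codons TTT TCG AAA, then UTR
  seq <- paste0("CC", "TTTTCGAAA", "GG")
  # third position of TTT: T->C is synonymous (Phe/Phe)
  s <- classify_substitution(4, "T", "C", 2, 11, "+", seq)
  expect_equal(s$effect, "S")
  expect_equal(c(s$aa_ref, s$aa_alt), c("F", "F"))
  # TCG -> TTG: Ser -> Leu, nonsynonymous
  ns <- classify_substitution(6, "C", "T", 2, 11, "+", seq)
  expect_equal(ns$effect, "NS")
  expect_equal(c(ns$aa_ref, ns$aa_alt), c("S", "L"))
  # before the CDS start: noncoding
  expect_equal(classify_substitution(1, "C", "A", 2, 11, "+", seq)$effect,
               "NC")
  expect_equal(classify_substitution(11, "G", "A", 2, 11, "+", seq)$effect,
               "NC")
  expect_error(classify_substitution(4, "A", "C", 2, 11, "+", seq),
               "mismatch")
})

test_that("substitution typing is strand-aware and flags ambiguous codons", {
  cds <- "ATGTCGAAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  seq <- paste0("GG", rc, "CC")
  # the TCG codon sits at transcript positions [5,8) on the minus strand;
  # its middle base C appears as G at transcript position 6
  m <- classify_substitution(6, "G", "A", 2, 11, "-", seq)
  expect_equal(m$codon_ref, "TCG")
  expect_equal(m$codon_alt, "TTG")   # complement of A is T
  expect_equal(m$effect, "NS")

  seqn <- paste0("CC", "TTNTCGAAA", "GG")
  amb <- classify_substitution(3, "T", "C", 2, 11, "+", seqn)
  expect_true(amb$undeterminable)
  expect_true(is.na(amb$effect))
})

test_that("candidate assembly unions the two rules with full evidence", {
  cfg <- pipeline_config()
  tx <- make_transcripts(c("u1", "u2", "u3"), c("u1", "u2", "u3"),
                         rep(strrep("A", 50), 3))
  catalog <- dedup_longest_isoform(tx)
  v <- variants_from_freqs(
    f_a = c(1, 1, 0.98, 1, 0.5),
    f_b = c(0, 0.02, 0, 0, 0.5),
    transcript = c("u1", "u1", "u1", "u2", "u3"),
    position = c(0L, 5L, 9L, 0L, 0L)
  )
  dbar <- compute_Dbar(v, catalog)
  sel <- select_divergent(dbar, v, cfg)
  expect_setequal(sel$unigenes$component_id, c("u1", "u2"))

  kaks <- data.frame(
    gene_id = "u2", ratio_ab = 0.62, ka_ab = 0.03, ks_ab = 0.048,
    ratio_a_out = 0.14, ratio_b_out = 0.13, candidate = TRUE,
    flagged_candidate = FALSE, stringsAsFactors = FALSE
  )
  cand <- assemble_candidates(sel$unigenes, v, catalog, kaks,
                              config = cfg)
  expect_setequal(cand$component_id, c("u1", "u2"))
  expect_equal(cand$reasons[cand$component_id == "u1"], "multi_snp")
  expect_equal(cand$n_high_d_snps[cand$component_id == "u1"], 3L)
  expect_equal(cand$reasons[cand$component_id == "u2"], "high_kaks")
  # u1 had no ortholog triple: reported in exclusions
  expect_equal(attr(cand, "exclusions")$component_id, "u1")

  # stage independence: dropping the Ka/Ks stage keeps multi-SNP candidates
  cand2 <- assemble_candidates(sel$unigenes, v, catalog, kaks = NULL,
                               config = cfg)
  expect_equal(cand2$component_id, "u1")
  expect_equal(cand2$reasons, "multi_snp")
})

test_that("run summaries conserve counts and handle empty input", {
  cfg <- pipeline_config()
  tx <- make_transcripts("u1", "u1", strrep("A", 10))
  catalog <- dedup_longest_isoform(tx)
  v <- variants_from_freqs(numeric(0), numeric(0), transcript = character(0),
                           position = integer(0))
  dbar <- compute_Dbar(v, catalog)
  sel <- select_divergent(dbar, v, cfg)
  s <- summarize_run(v, dbar, sel)
  expect_equal(s$n_divergent_unigenes, 0)
  expect_equal(s$n_candidates, 0)
  expect_equal(sum(unlist(s$snp_classes)), 0)

  # breakdown sums to the number of selected unigenes and their SNPs sum
  # to the selected Nei universe
  set.seed(91)
  n <- 40
  comp <- sprintf("u%02d", sample(12, n, TRUE))
  v2 <- variants_from_freqs(runif(n, 0.9, 0.95), runif(n, 0, 0.02),
                            transcript = comp,
                            position = seq_len(n) - 1L)
  cat2 <- dedup_longest_isoform(
    make_transcripts(unique(comp), unique(comp),
                     rep(strrep("A", 100), length(unique(comp)))))
  dbar2 <- compute_Dbar(v2, cat2)
  sel2 <- select_divergent(dbar2, v2, cfg)
  s2 <- summarize_run(v2, dbar2, sel2)
  bd <- s2$divergent_snp_breakdown
  expect_equal(bd$one_snp + bd$two_snps + bd$three_or_more,
               s2$n_divergent_unigenes)
  expect_equal(s2$n_snps_in_divergent_unigenes,
               sum(sel2$unigenes$n_snps))
})

test_that("an end-to-end run recovers the planted candidate structure", {
  p <- simulation_params(
    n_unigenes = 40, n_shared_snps = 60, n_specific_snps = 60,
    n_fixed_snps = 6, n_fixed_unigenes = 3, fixed_snp_layout = c(3, 2, 1),
    depth_mean = 2000, depth_dispersion = 1e6, qual_mean = 60, qual_sd = 5,
    orf_codons = c(110, 160), n_orphan_genes = 0, rng_seed = 13
  )
  d <- withr::local_tempdir()
  suppressMessages(emit_dataset(d, p, force = TRUE))
  res <- suppressMessages(run_pipeline(d, pipeline_config()))
  truth <- utils::read.delim(file.path(d, "truth_snps.tsv"))
  planted <- sort(unique(truth$component_id[truth$class == "fixed"]))
  expect_equal(sort(res$selection$unigenes$component_id), planted)
  # the unigene with three planted fixed SNPs is a multi-SNP candidate
  multi <- truth$component_id[truth$class == "fixed"]
  multi <- names(which(table(multi) >= 3))
  expect_true(multi %in% res$candidates$component_id)
  expect_match(
    res$candidates$reasons[res$candidates$component_id == multi],
    "multi_snp")
  # provenance: every candidate reason is replayable from the thresholds
  for (i in seq_len(nrow(res$candidates))) {
    r <- res$candidates[i, ]
    ok <- (r$n_high_d_snps >= 3) ||
      (!is.na(r$ratio_ab) && r$ratio_ab >= 0.5 &&
         r$ratio_a_out < 0.5 && r$ratio_b_out < 0.5)
    expect_true(ok)
  }
})
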