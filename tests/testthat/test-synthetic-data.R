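small_params <- function(...) {
  args <- list(n_unigenes = 20, n_shared_snps = 30,
               n_specific_snps = 40, n_fixed_snps = 4,
               n_fixed_unigenes = 3, n_orphan_genes = 2,
               orf_codons = c(105, 140), rng_seed = 99)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_params, args)
}

test_that("generators are seeded-deterministic", {
  p <- small_params()
  t1 <- simulate_unigenes(p)
  t2 <- simulate_unigenes(p)
  expect_identical(t1, t2)
  a1 <- simulate_allele_counts(t1, p)
  a2 <- simulate_allele_counts(t2, p)
  expect_identical(a1, a2)
})

test_that("catalog structure respects isoform bounds and identity reduction", {
  p <- simulation_params(n_unigenes = 5, isoforms_per_unigene = c(1, 3),
                         rng_seed = 3)
  tx <- simulate_unigenes(p)
  expect_equal(length(unique(tx$component_id)), 5)
  expect_gte(nrow(tx), 5)
  expect_lte(nrow(tx), 15)

  p1 <- simulation_params(n_unigenes = 4, isoforms_per_unigene = c(1, 1),
                          rng_seed = 3)
  tx1 <- simulate_unigenes(p1)
  cat1 <- dedup_longest_isoform(tx1)
  expect_equal(sort(cat1$transcript_id), sort(tx1$transcript_id))

  expect_warning(empty <- simulate_unigenes(
    simulation_params(n_unigenes = 0)), "zero unigenes")
  expect_equal(nrow(empty), 0)
})

test_that("planted ORFs are real reading frames", {
  p <- small_params()
  tx <- simulate_unigenes(p)
  orfs <- attr(tx, "truth_orfs")
  for (i in sample(nrow(orfs), 5)) {
    seq <- tx$sequence[match(orfs$transcript_id[i], tx$transcript_id)]
    cds <- substr(seq, orfs$orf_start[i] + 1, orfs$orf_end[i])
    prot <- translate_cds(cds)
    expect_equal(substr(prot, 1, 1), "M")
    expect_false(grepl("\\*", prot))
    expect_equal(nchar(prot), orfs$n_residues[i])
  }
})

test_that("planted SNPs agree with the reference base and their class", {
  p <- small_params()
  tx <- simulate_unigenes(p)
  ac <- simulate_allele_counts(tx, p)
  v <- ac$variants
  truth <- ac$truth
  # coordinate property: transcript base at position equals ref allele
  seq_by <- setNames(tx$sequence, tx$transcript_id)
  base <- substring(seq_by[v$transcript_id], v$position + 1, v$position + 1)
  expect_equal(unname(base), v$ref)
  # class definition in the truth table
  fx <- truth$class == "fixed"
  expect_true(all(truth$f_a[fx] %in% c(0, 1) & truth$f_b[fx] %in% c(0, 1) &
                    truth$f_a[fx] != truth$f_b[fx]))
  expect_true(all(truth$f_a[truth$class == "specificB"] == 0))
  expect_true(all(truth$f_b[truth$class == "specificA"] == 0))
  sh <- truth$class == "shared"
  expect_true(all(truth$f_a[sh] > 0.05 & truth$f_a[sh] < 0.95))
  # fixed SNPs live on their own unigene pool, disjoint from the others
  expect_length(intersect(truth$component_id[fx], truth$component_id[!fx]), 0)
})

test_that("fixed sites at high depth produce all-or-nothing counts", {
  p <- small_params(depth_mean = 200, depth_dispersion = 1e8)
  tx <- simulate_unigenes(p)
  ac <- simulate_allele_counts(tx, p)
  fx <- ac$truth$class == "fixed"
  v <- ac$variants[fx, ]
  t <- ac$truth[fx, ]
  expect_true(all(ifelse(t$f_a == 1, v$ref_a == 0, v$alt_a == 0)))
  expect_true(all(ifelse(t$f_b == 1, v$ref_b == 0, v$alt_b == 0)))
})

test_that("observed |F_A - F_B| of shared sites matches the exact binomial expectation", {
  p <- simulation_params(n_unigenes = 50, n_shared_snps = 1000,
                         n_specific_snps = 0, n_fixed_snps = 0,
                         n_fixed_unigenes = 0,
                         shared_freq_range = c(0.5, 0.5),
                         depth_mean = 500, depth_dispersion = 1e9,
                         rng_seed = 17)
  tx <- simulate_unigenes(p)
  ac <- simulate_allele_counts(tx, p)
  f <- estimate_frequencies(ac$variants)
  observed <- mean(abs(f$f_a - f$f_b))
  expected <- oracle_mean_abs_freq_diff(500, 0.5)
  expect_equal(observed, expected, tolerance = 0.1)
})

test_that("codon evolution respects omega = 0 and t = 0", {
  set.seed(5)
  anc <- random_cds(120)
  expect_identical(simulate_codon_evolution(anc, omega = 1, t = 0), anc)
  ev <- simulate_codon_evolution(anc, omega = 0, t = 0.5, seed = 2)
  expect_false(identical(ev, anc))
  expect_identical(translate_cds(ev), translate_cds(anc))
  expect_error(simulate_codon_evolution("ATGTAAAAA", 1, 0.1),
               "internal stop")
})

test_that("emit_dataset writes a complete, reproducible bundle", {
  p <- small_params()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages(emit_dataset(d1, p, force = TRUE))
  suppressMessages(emit_dataset(d2, p, force = TRUE))
  files <- c("transcripts.fasta", "variants.vcf", "variants.tsv",
             "cds_ingroup_a.fasta", "cds_ingroup_b.fasta",
             "cds_outgroup.fasta", "truth_snps.tsv", "truth_genes.tsv",
             "truth_orfs.tsv", "manifest.json")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(manifest$rng_seed, 99)
  expect_error(suppressMessages(emit_dataset(d1, p)), "not empty")

  p0 <- small_params(n_fixed_snps = 0L, n_fixed_unigenes = 0L)
  d3 <- withr::local_tempdir()
  suppressMessages(emit_dataset(d3, p0, force = TRUE))
  truth <- utils::read.delim(file.path(d3, "truth_snps.tsv"))
  expect_false(any(truth$class == "fixed"))
})
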