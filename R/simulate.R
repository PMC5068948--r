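# Synthetic two-species transcriptome generator. Produces (a) a unigene
# catalog with isoforms sharing a common exonic core and a planted ORF,
# (b) per-site allele counts for three planted SNP classes (shared
# polymorphic, species-specific polymorphic, fixed interspecific
# differences) with negative-binomial depths and binomial allele sampling,
# and (c) ortholog CDS triples evolved from a common ancestor under
# controlled per-gene selection pressure, together with the ground-truth
# tables the recovery tests consume.

#' Parameters of the synthetic dataset
#'
#' Defaults are a desk-scale rendering of a two-species head-transcriptome
#' screen: the three planted SNP-class sizes keep the roughly 10.6 : 6.1 : 1
#' proportions observed between species-specific and shared SNPs in
#' tephritid sister species (scaled down by a factor of about 20), depths
#' are overdispersed around 300x, and ortholog triples use a short ingroup
#' path and a several-fold longer outgroup path.
#'
#' @param n_unigenes Number of components (unigenes).
#' @param isoforms_per_unigene Length-2 integer range of isoform counts.
#' @param orf_codons Length-2 range of planted protein lengths (residues).
#' @param utr_length Length-2 range of 5' and 3' UTR lengths (nt).
#' @param isoform_extra Length-2 range of extra flanking bases a non-core
#'   isoform may add on each side.
#' @param n_shared_snps Sites polymorphic in both species.
#' @param n_specific_snps Sites polymorphic in exactly one species.
#' @param specific_fraction_a Fraction of species-specific sites assigned
#'   to species A.
#' @param n_fixed_snps Oppositely fixed interspecific differences.
#' @param n_fixed_unigenes Number of distinct unigenes carrying the fixed
#'   differences; fixed sites are planted on unigenes disjoint from those
#'   receiving shared/specific sites so that truth-table recovery of the
#'   divergent set is well defined.
#' @param fixed_snp_layout Optional integer vector (length
#'   `n_fixed_unigenes`, summing to `n_fixed_snps`) giving the number of
#'   fixed SNPs per fixed-difference unigene; `NULL` distributes them as
#'   evenly as possible.
#' @param shared_freq_range True alt-allele frequencies of shared (and the
#'   polymorphic side of specific) sites are drawn uniformly from this
#'   open interval.
#' @param depth_mean,depth_dispersion Negative-binomial depth per site per
#'   species (`mu`, `size`).
#' @param qual_mean,qual_sd Phred-scaled site quality, normal, clamped at 0.
#' @param omega_per_gene Ingroup-branch Ka/Ks truth per gene: a scalar, a
#'   vector recycled over genes, or `NULL` to draw a two-point mixture with
#'   `p_omega_high` of genes at `omega_high` and the rest at `omega_low`.
#' @param omega_low,omega_high,p_omega_high Mixture used when
#'   `omega_per_gene` is `NULL`.
#' @param omega_outgroup Selection pressure on the outgroup branch.
#' @param t_ingroup Expected substitutions per nucleotide site on the path
#'   between the two ingroup species (split evenly over their two
#'   branches); 0.05 yields ingroup synonymous distances of a few percent,
#'   the scale seen between recently diverged sister species.
#' @param t_outgroup Expected substitutions per nucleotide site on the
#'   outgroup branch; must exceed `t_ingroup`. The default 0.5 puts
#'   outgroup synonymous distances above 1, the scale seen against a
#'   confamilial outgroup genus.
#' @param n_orphan_genes Genes omitted from the species-B CDS set, so the
#'   reciprocal-best-hit step has unpaired decoys.
#' @param rng_seed Integer seed; every generator is deterministic given it.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_unigenes = 600,
                              isoforms_per_unigene = c(1L, 3L),
                              orf_codons = c(120L, 400L),
                              utr_length = c(30L, 300L),
                              isoform_extra = c(0L, 150L),
                              n_shared_snps = 319L,
                              n_specific_snps = 5337L,
                              specific_fraction_a = 0.632,
                              n_fixed_snps = 11L,
                              n_fixed_unigenes = 8L,
                              fixed_snp_layout = NULL,
                              shared_freq_range = c(0.05, 0.95),
                              depth_mean = 300,
                              depth_dispersion = 3,
                              qual_mean = 45,
                              qual_sd = 10,
                              omega_per_gene = NULL,
                              omega_low = 0.15,
                              omega_high = 0.8,
                              p_omega_high = 0.075,
                              omega_outgroup = 0.1,
                              t_ingroup = 0.05,
                              t_outgroup = 0.5,
                              n_orphan_genes = 10L,
                              rng_seed = 1L) {
  p <- as.list(environment())
  stopifnot(
    p$n_unigenes >= 0, p$n_shared_snps >= 0, p$n_specific_snps >= 0,
    p$n_fixed_snps >= 0, p$t_ingroup >= 0,
    p$t_outgroup > p$t_ingroup,
    is.null(p$omega_per_gene) || all(p$omega_per_gene > 0),
    p$omega_outgroup > 0,
    diff(p$isoforms_per_unigene) >= 0, p$isoforms_per_unigene[1] >= 1
  )
  if (!is.null(p$fixed_snp_layout)) {
    if (length(p$fixed_snp_layout) != p$n_fixed_unigenes ||
        sum(p$fixed_snp_layout) != p$n_fixed_snps) {
      stop("fixed_snp_layout must have length n_fixed_unigenes and sum ",
           "to n_fixed_snps")
    }
  }
  class(p) <- "simulation_params"
  p
}

.sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

.random_nt <- function(n) {
  if (n == 0) "" else paste(sample(NUCS, n, replace = TRUE), collapse = "")
}

#' Random coding sequence
#'
#' An ATG start followed by uniformly drawn sense codons; no internal stop
#' and no terminal stop codon.
#'
#' @param n_codons Number of codons (residues) including the start.
#' @return A nucleotide string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons) {
  .codon_setup()
  stopifnot(n_codons >= 1)
  paste(c("ATG", sample(.ds$sense, n_codons - 1, replace = TRUE)),
        collapse = "")
}

#' Simulate a unigene catalog with isoforms
#'
#' Each unigene is a common exonic core (5' UTR, a planted ORF, 3' UTR)
#' shared by all its isoforms; isoforms differ by random extra flanking
#' sequence, so the longest isoform always contains the core and the
#' longest-isoform reduction is meaningful. The planted ORF coordinates per
#' transcript are returned in the `truth_orfs` attribute.
#'
#' @param params A [simulation_params()] object.
#' @return A transcripts data.frame as from [read_transcripts()], with
#'   attribute `truth_orfs`: a data.frame `transcript_id`, `component_id`,
#'   `orf_start`, `orf_end` (0-based half-open, stop codon excluded),
#'   `n_residues`.
#' @export
simulate_unigenes <- function(params) {
  .codon_setup()
  set.seed(params$rng_seed)
  n <- params$n_unigenes
  if (n == 0) {
    warning("zero unigenes requested; returning an empty catalog")
    empty <- data.frame(transcript_id = character(),
                        component_id = character(),
                        sequence = character(), stringsAsFactors = FALSE)
    attr(empty, "truth_orfs") <- data.frame()
    return(empty)
  }
  stops <- c("TAA", "TAG", "TGA")
  rows <- vector("list", n)
  orfs <- vector("list", n)
  for (i in seq_len(n)) {
    comp <- sprintf("comp%05d_c0", i)
    k <- .sample_range(1, params$orf_codons)
    cds <- paste0(random_cds(k), sample(stops, 1))
    utr5 <- .random_nt(.sample_range(1, params$utr_length))
    utr3 <- .random_nt(.sample_range(1, params$utr_length))
    core <- paste0(utr5, cds, utr3)
    n_iso <- .sample_range(1, params$isoforms_per_unigene)
    extra5 <- .sample_range(n_iso, params$isoform_extra)
    extra3 <- .sample_range(n_iso, params$isoform_extra)
    seqs <- vapply(seq_len(n_iso), function(j) {
      paste0(.random_nt(extra5[j]), core, .random_nt(extra3[j]))
    }, character(1))
    ids <- sprintf("%s_seq%d", comp, seq_len(n_iso))
    rows[[i]] <- data.frame(transcript_id = ids, component_id = comp,
                            sequence = seqs, stringsAsFactors = FALSE)
    orfs[[i]] <- data.frame(
      transcript_id = ids, component_id = comp,
      orf_start = nchar(utr5) + extra5,
      orf_end = nchar(utr5) + extra5 + 3L * k,
      n_residues = k, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "truth_orfs") <- do.call(rbind, orfs)
  out
}

#' Plant SNP classes and draw per-species allele counts
#'
#' SNPs are planted on the unigene (longest) transcript of each component.
#' Fixed interspecific differences go to a dedicated pool of
#' `n_fixed_unigenes` components; shared and species-specific sites are
#' scattered over the remaining components. For every site, each species'
#' depth is drawn from a negative binomial and its alt-allele count
#' binomially at the site's true frequency: shared sites draw both true
#' frequencies uniformly from `shared_freq_range`, specific sites draw one
#' and set the other to 0, fixed sites use (1, 0) or (0, 1).
#'
#' @param transcripts A transcripts data.frame ([simulate_unigenes()]).
#' @param params A [simulation_params()] object.
#' @return A list with `variants` (a `variant_table`) and `truth` (a
#'   data.frame `transcript_id`, `component_id`, `position`, `class`,
#'   `f_a`, `f_b`).
#' @export
simulate_allele_counts <- function(transcripts, params) {
  if (nrow(transcripts) == 0) stop("empty transcript catalog")
  set.seed(params$rng_seed + 1L)
  catalog <- dedup_longest_isoform(transcripts)
  comps <- catalog$component_id
  if (params$n_fixed_unigenes > length(comps)) {
    stop("n_fixed_unigenes exceeds the number of unigenes")
  }
  fixed_pool <- sample(comps, params$n_fixed_unigenes)
  other_pool <- setdiff(comps, fixed_pool)
  if (length(other_pool) == 0 &&
      params$n_shared_snps + params$n_specific_snps > 0) {
    stop("no unigenes left for non-fixed SNPs")
  }

  layout <- params$fixed_snp_layout
  if (is.null(layout) && params$n_fixed_unigenes > 0) {
    base <- params$n_fixed_snps %/% params$n_fixed_unigenes
    layout <- rep(base, params$n_fixed_unigenes)
    extra <- params$n_fixed_snps - sum(layout)
    if (extra > 0) layout[seq_len(extra)] <- layout[seq_len(extra)] + 1L
  }

  n_a <- round(params$n_specific_snps * params$specific_fraction_a)
  n_b <- params$n_specific_snps - n_a
  alloc <- data.frame(
    component_id = c(rep(fixed_pool, layout),
                     sample(other_pool, params$n_shared_snps, replace = TRUE),
                     sample(other_pool, n_a, replace = TRUE),
                     sample(other_pool, n_b, replace = TRUE)),
    class = c(rep("fixed", params$n_fixed_snps),
              rep("shared", params$n_shared_snps),
              rep("specificA", n_a), rep("specificB", n_b)),
    stringsAsFactors = FALSE
  )

  seq_by_tx <- stats::setNames(transcripts$sequence,
                               transcripts$transcript_id)
  tx_by_comp <- stats::setNames(catalog$transcript_id, catalog$component_id)
  len_by_comp <- stats::setNames(catalog$length, catalog$component_id)

  # distinct positions per unigene across all its planted SNPs
  alloc <- alloc[order(alloc$component_id), , drop = FALSE]
  pos <- integer(nrow(alloc))
  for (comp in unique(alloc$component_id)) {
    idx <- which(alloc$component_id == comp)
    L <- len_by_comp[[comp]]
    if (length(idx) > L) {
      stop("more SNPs requested than positions available on ", comp)
    }
    pos[idx] <- sample.int(L, length(idx)) - 1L
  }
  alloc$position <- pos
  alloc$transcript_id <- unname(tx_by_comp[alloc$component_id])

  m <- nrow(alloc)
  ref <- substring(seq_by_tx[alloc$transcript_id],
                   alloc$position + 1L, alloc$position + 1L)
  alt <- vapply(ref, function(r) sample(NUCS[NUCS != r], 1), character(1))

  rng <- params$shared_freq_range
  f_a <- f_b <- numeric(m)
  cls <- alloc$class
  sh <- cls == "shared"
  f_a[sh] <- stats::runif(sum(sh), rng[1], rng[2])
  f_b[sh] <- stats::runif(sum(sh), rng[1], rng[2])
  sa <- cls == "specificA"
  f_a[sa] <- stats::runif(sum(sa), rng[1], rng[2])
  f_b[sa] <- 0
  sb <- cls == "specificB"
  f_a[sb] <- 0
  f_b[sb] <- stats::runif(sum(sb), rng[1], rng[2])
  fx <- cls == "fixed"
  a_is_alt <- stats::runif(sum(fx)) < 0.5
  f_a[fx] <- as.numeric(a_is_alt)
  f_b[fx] <- as.numeric(!a_is_alt)

  depth_a <- stats::rnbinom(m, size = params$depth_dispersion,
                            mu = params$depth_mean)
  depth_b <- stats::rnbinom(m, size = params$depth_dispersion,
                            mu = params$depth_mean)
  alt_a <- stats::rbinom(m, depth_a, f_a)
  alt_b <- stats::rbinom(m, depth_b, f_b)
  qual <- round(pmax(0, stats::rnorm(m, params$qual_mean, params$qual_sd)), 1)

  variants <- data.frame(
    transcript_id = alloc$transcript_id, position = alloc$position,
    ref = unname(ref), alt = unname(alt),
    ref_a = depth_a - alt_a, alt_a = alt_a,
    ref_b = depth_b - alt_b, alt_b = alt_b,
    qual = qual, stringsAsFactors = FALSE
  )
  truth <- data.frame(
    transcript_id = alloc$transcript_id, component_id = alloc$component_id,
    position = alloc$position, class = cls, f_a = f_a, f_b = f_b,
    stringsAsFactors = FALSE
  )
  ord <- order(variants$transcript_id, variants$position)
  list(variants = .variant_table(variants[ord, , drop = FALSE],
                                 c("A", "B"), 0L),
       truth = {
         t2 <- truth[ord, , drop = FALSE]
         rownames(t2) <- NULL
         t2
       })
}

#' Evolve a coding sequence under a mutation-acceptance process
#'
#' Single-nucleotide changes are proposed uniformly over positions and
#' alternative bases; proposals creating a stop codon are rejected outright.
#' For `omega <= 1` synonymous proposals are always accepted and
#' nonsynonymous ones with probability `omega`; for `omega > 1` the roles
#' are reversed (synonymous acceptance `1/omega`), so the process never
#' needs acceptance probabilities above 1. The number of accepted
#' substitutions is Poisson with mean `t * length(cds)`. This is a
#' deliberately minimal codon model (no transition/transversion bias,
#' uniform codon frequencies) sufficient to make NG86 recovery testable.
#'
#' @param ancestor_cds Nucleotide string, length a multiple of 3, no
#'   internal stop codon.
#' @param omega Selection pressure (> 0, or 0 for strict purifying).
#' @param t Expected substitutions per nucleotide site of the coding
#'   sequence (branch length).
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return The evolved CDS string.
#' @export
simulate_codon_evolution <- function(ancestor_cds, omega, t, seed = NULL) {
  .codon_setup()
  if (!is.null(seed)) set.seed(seed)
  stopifnot(omega >= 0, t >= 0)
  s <- strsplit(toupper(ancestor_cds), "")[[1]]
  L <- length(s)
  if (L %% 3 != 0) stop("ancestor length must be a multiple of 3")
  if (any(!s %in% NUCS)) stop("ancestor must contain only A, C, G, T")
  aa0 <- .codon_aa(.split_codons(ancestor_cds))
  if (any(aa0 == "*")) stop("ancestor contains an internal stop codon")
  k_target <- stats::rpois(1, t * L)
  if (k_target == 0) return(paste(s, collapse = ""))
  if (omega <= 1) {
    p_syn <- 1
    p_non <- omega
  } else {
    p_syn <- 1 / omega
    p_non <- 1
  }
  aa_by <- .ds$aa_by_codon
  accepted <- 0L
  proposals <- 0L
  max_proposals <- 1000L * k_target + 10000L
  while (accepted < k_target) {
    proposals <- proposals + 1L
    if (proposals > max_proposals) {
      stop("mutation-acceptance process failed to reach the target ",
           "substitution count (omega = ", omega, ")")
    }
    pos <- sample.int(L, 1)
    cur <- s[pos]
    alt <- sample(NUCS[NUCS != cur], 1)
    ci <- ((pos - 1L) %/% 3L) * 3L + 1L
    cod <- s[ci:(ci + 2L)]
    old_aa <- aa_by[[paste(cod, collapse = "")]]
    cod[pos - ci + 1L] <- alt
    new_aa <- aa_by[[paste(cod, collapse = "")]]
    if (new_aa == "*") next
    p_acc <- if (new_aa == old_aa) p_syn else p_non
    if (p_acc <= 0) next
    if (p_acc < 1 && stats::runif(1) > p_acc) next
    s[pos] <- alt
    accepted <- accepted + 1L
  }
  paste(s, collapse = "")
}

#' Evolve ortholog CDS triples for every unigene
#'
#' The planted ORF of each unigene (stop codon removed) is the common
#' ancestor; the two ingroup copies evolve on branches of length
#' `t_ingroup / 2` under the gene's ingroup omega, the outgroup copy on a
#' branch of length `t_outgroup` under `omega_outgroup`. A random subset of
#' `n_orphan_genes` genes is dropped from the species-B set.
#'
#' @param transcripts Output of [simulate_unigenes()] (must carry the
#'   `truth_orfs` attribute).
#' @param params A [simulation_params()] object.
#' @return A list with named character vectors `cds_a`, `cds_b`, `cds_out`
#'   (names are component ids) and `truth_genes`, a data.frame of the true
#'   per-gene parameters.
#' @export
simulate_ortholog_triples <- function(transcripts, params) {
  orfs <- attr(transcripts, "truth_orfs")
  if (is.null(orfs)) stop("transcripts lack the truth_orfs attribute")
  set.seed(params$rng_seed + 2L)
  catalog <- dedup_longest_isoform(transcripts)
  orfs <- orfs[match(catalog$transcript_id, orfs$transcript_id), ,
               drop = FALSE]
  seq_by_tx <- stats::setNames(transcripts$sequence,
                               transcripts$transcript_id)
  n <- nrow(catalog)
  omega <- params$omega_per_gene
  if (is.null(omega)) {
    omega <- ifelse(stats::runif(n) < params$p_omega_high,
                    params$omega_high, params$omega_low)
  } else {
    omega <- rep_len(omega, n)
  }
  orphans <- if (params$n_orphan_genes > 0) {
    sample(catalog$component_id, min(params$n_orphan_genes, n))
  } else {
    character(0)
  }
  cds_a <- cds_b <- cds_out <- character(n)
  for (i in seq_len(n)) {
    anc <- substr(seq_by_tx[[catalog$transcript_id[i]]],
                  orfs$orf_start[i] + 1L, orfs$orf_end[i])
    cds_a[i] <- simulate_codon_evolution(anc, omega[i], params$t_ingroup / 2)
    cds_b[i] <- simulate_codon_evolution(anc, omega[i], params$t_ingroup / 2)
    cds_out[i] <- simulate_codon_evolution(anc, params$omega_outgroup,
                                           params$t_outgroup)
  }
  names(cds_a) <- names(cds_b) <- names(cds_out) <- catalog$component_id
  truth_genes <- data.frame(
    gene_id = catalog$component_id,
    omega_ingroup = omega,
    omega_outgroup = params$omega_outgroup,
    t_ingroup = params$t_ingroup,
    t_outgroup = params$t_outgroup,
    has_ortholog_b = !(catalog$component_id %in% orphans),
    stringsAsFactors = FALSE
  )
  list(cds_a = cds_a, cds_b = cds_b[truth_genes$has_ortholog_b],
       cds_out = cds_out, truth_genes = truth_genes)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the reference transcripts (FASTA), the variant table (VCF and
#' TSV), per-species and outgroup CDS FASTAs, the ground-truth tables and a
#' JSON manifest recording the parameters and seed. Identical parameters
#' and seed produce byte-identical files.
#'
#' @param out_dir Output directory.
#' @param params A [simulation_params()] object.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, a named list of the written paths.
#' @export
emit_dataset <- function(out_dir, params = simulation_params(),
                         force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop("output directory ", out_dir,
         " exists and is not empty (use force = TRUE)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  transcripts <- simulate_unigenes(params)
  ac <- simulate_allele_counts(transcripts, params)
  tri <- simulate_ortholog_triples(transcripts, params)
  paths <- list(
    transcripts = file.path(out_dir, "transcripts.fasta"),
    variants_vcf = file.path(out_dir, "variants.vcf"),
    variants_tsv = file.path(out_dir, "variants.tsv"),
    cds_a = file.path(out_dir, "cds_ingroup_a.fasta"),
    cds_b = file.path(out_dir, "cds_ingroup_b.fasta"),
    cds_out = file.path(out_dir, "cds_outgroup.fasta"),
    truth_snps = file.path(out_dir, "truth_snps.tsv"),
    truth_genes = file.path(out_dir, "truth_genes.tsv"),
    truth_orfs = file.path(out_dir, "truth_orfs.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_fasta(stats::setNames(transcripts$sequence,
                              transcripts$transcript_id),
              paths$transcripts)
  write_variants(ac$variants, paths$variants_vcf, format = "vcf")
  write_variants(ac$variants, paths$variants_tsv, format = "tsv")
  write_fasta(tri$cds_a, paths$cds_a)
  write_fasta(tri$cds_b, paths$cds_b)
  write_fasta(tri$cds_out, paths$cds_out)
  tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(ac$truth, paths$truth_snps)
  tsv(tri$truth_genes, paths$truth_genes)
  tsv(attr(transcripts, "truth_orfs"), paths$truth_orfs)
  manifest <- params
  class(manifest) <- NULL
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  .log_stage("dataset written to %s (%d transcripts, %d variants, %.1fs)",
             out_dir, nrow(transcripts), nrow(ac$variants),
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(paths)
}
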