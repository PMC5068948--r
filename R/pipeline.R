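# End-to-end orchestration: variant screen -> differentiation -> ortholog
# Ka/Ks -> candidate report. Each stage is also callable on its own.

#' Run the full candidate-gene screen on a dataset directory
#'
#' Expects the file layout written by [emit_dataset()]: reference
#' `transcripts.fasta`, a variant table (`variants.tsv` or `variants.vcf`),
#' and optionally `cds_ingroup_a.fasta`, `cds_ingroup_b.fasta`,
#' `cds_outgroup.fasta` with gene ids equal to component ids. The Ka/Ks
#' stage follows the study design: only the D-bar-selected unigenes are
#' submitted to ortholog detection (reciprocal best hits against the full
#' species-B and outgroup sets), protein alignment, back-translation and
#' NG86 estimation.
#'
#' @param input_dir Dataset directory.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the report files (per-SNP
#'   TSV, per-unigene TSV, D-bar histogram, candidates, exclusions,
#'   summary JSON).
#' @return Invisibly, a list with all stage results: `transcripts`,
#'   `catalog`, `variants` (classified, with D), `dbar`, `selection`,
#'   `nei_all`, `nei_selected`, `normality`, `kaks`, `candidates`,
#'   `summary`.
#' @export
run_pipeline <- function(input_dir, config = pipeline_config(),
                         out_dir = NULL) {
  t0 <- Sys.time()
  tx_path <- file.path(input_dir, "transcripts.fasta")
  var_tsv <- file.path(input_dir, "variants.tsv")
  var_vcf <- file.path(input_dir, "variants.vcf")
  transcripts <- read_transcripts(tx_path)
  variants <- if (file.exists(var_tsv)) {
    read_variants(var_tsv, format = "tsv")
  } else {
    read_variants(var_vcf, format = "vcf")
  }
  .log_stage("loaded %d transcripts, %d variant sites",
             nrow(transcripts), nrow(variants))

  catalog <- dedup_longest_isoform(transcripts)
  v <- estimate_frequencies(variants)
  v <- filter_snps(v, config)
  v <- classify_sharing(v, config)
  on_unigene <- v$transcript_id %in% catalog$transcript_id
  v$d_callable <- v$d_callable & on_unigene
  v <- compute_D(v)
  dbar <- compute_Dbar(v, catalog)
  selection <- select_divergent(dbar, v, config)
  .log_stage("screen: %s; %d divergent unigenes, %d high-D SNPs",
             paste(names(attr(v, "class_tally")),
                   unlist(attr(v, "class_tally")), collapse = ", "),
             nrow(selection$unigenes), nrow(selection$snps))

  nei_all <- if (any(v$d_callable)) {
    nei_identity_distance(v$f_a[v$d_callable], v$f_b[v$d_callable])
  }
  comp_of <- stats::setNames(catalog$component_id, catalog$transcript_id)
  sel_members <- v[!is.na(v$D) &
                     comp_of[v$transcript_id] %in%
                       selection$unigenes$component_id, , drop = FALSE]
  nei_sel <- if (nrow(sel_members)) {
    nei_identity_distance(sel_members$f_a, sel_members$f_b)
  }
  normality <- if (nrow(dbar) >= 3 && stats::sd(dbar$dbar) > 0) {
    x <- dbar$dbar
    if (length(x) > 5000) x <- sample(x, 5000)
    normality_test(x)
  }

  kaks <- NULL
  effects <- NULL
  cds_paths <- file.path(input_dir, c("cds_ingroup_a.fasta",
                                      "cds_ingroup_b.fasta",
                                      "cds_outgroup.fasta"))
  if (all(file.exists(cds_paths)) && nrow(selection$unigenes)) {
    kaks <- .kaks_stage(cds_paths, selection$unigenes$component_id, config)
    effects <- .effect_stage(transcripts, catalog, selection, sel_members,
                             config)
  }
  candidates <- assemble_candidates(selection$unigenes, v, catalog, kaks,
                                    effects, config)
  summary <- summarize_run(v, dbar, selection, nei_all, nei_sel,
                           normality, candidates)
  .log_stage("pipeline done: %d candidates (%.1fs)", nrow(candidates),
             as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- function(df, name) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    snp_out <- v[!is.na(v$D),
                 c("transcript_id", "position", "f_a", "f_b", "D")]
    tsv(snp_out[order(snp_out$transcript_id, snp_out$position), ],
        "snps_d.tsv")
    dbar_out <- dbar
    dbar_out$selected <- dbar_out$dbar >= config$dbar_threshold
    tsv(dbar_out, "unigenes_dbar.tsv")
    tsv(selection$histogram, "dbar_histogram.tsv")
    if (!is.null(kaks)) tsv(kaks, "kaks.tsv")
    write_report(candidates, file.path(out_dir, "candidates.tsv"), "tsv")
    tsv(attr(candidates, "exclusions"), "exclusions.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(list(transcripts = transcripts, catalog = catalog,
                 variants = v, dbar = dbar, selection = selection,
                 nei_all = nei_all, nei_selected = nei_sel,
                 normality = normality, kaks = kaks,
                 candidates = candidates, summary = summary))
}

.strip_terminal_stop <- function(cds) {
  n <- nchar(cds)
  if (n >= 3 && n %% 3 == 0 && .codon_aa(substr(cds, n - 2, n)) == "*") {
    substr(cds, 1, n - 3)
  } else {
    cds
  }
}

# Ortholog detection + alignment + NG86 for the selected genes.
.kaks_stage <- function(cds_paths, selected_ids, config) {
  read_cds <- function(p) {
    tx <- read_transcripts(p, isoform_sep = "")  # ids verbatim
    stats::setNames(tx$sequence, tx$transcript_id)
  }
  cds_a <- read_cds(cds_paths[1])
  cds_b <- read_cds(cds_paths[2])
  cds_out <- read_cds(cds_paths[3])
  cds_a <- cds_a[names(cds_a) %in% selected_ids]
  if (!length(cds_a)) return(NULL)
  prot <- function(x) vapply(x, function(s) {
    translate_cds(.strip_terminal_stop(s))
  }, character(1))
  prot_a <- prot(cds_a)
  prot_b <- prot(cds_b)
  prot_out <- prot(cds_out)
  rbh_ab <- reciprocal_best_hits(prot_a, prot_b)
  rbh_ao <- reciprocal_best_hits(prot_a, prot_out)
  rows <- list()
  for (i in seq_len(nrow(rbh_ab))) {
    ga <- rbh_ab$id_a[i]
    gb <- rbh_ab$id_b[i]
    go <- rbh_ao$id_b[match(ga, rbh_ao$id_a)]
    if (is.na(go)) next
    tri <- tryCatch(
      .aligned_triple(cds_a[[ga]], cds_b[[gb]], cds_out[[go]]),
      error = function(e) NULL
    )
    if (is.null(tri)) next
    rule <- kaks_candidate_rule(tri, config)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = ga, gene_b = gb, gene_out = go,
      ratio_ab = tri$ab$ratio, ka_ab = tri$ab$ka, ks_ab = tri$ab$ks,
      ratio_a_out = tri$a_out$ratio, ka_a_out = tri$a_out$ka,
      ks_a_out = tri$a_out$ks,
      ratio_b_out = tri$b_out$ratio, ka_b_out = tri$b_out$ka,
      ks_b_out = tri$b_out$ks,
      candidate = rule$candidate,
      flagged_candidate = rule$flagged_candidate,
      rationale = rule$rationale,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Pairwise protein alignments back-translated onto a common codon frame.
# Each pair is aligned independently (only pairs are compared downstream).
.aligned_triple <- function(cds_a, cds_b, cds_out) {
  cds_a <- .strip_terminal_stop(toupper(cds_a))
  cds_b <- .strip_terminal_stop(toupper(cds_b))
  cds_out <- .strip_terminal_stop(toupper(cds_out))
  pair <- function(x, y) {
    al <- align_proteins(translate_cds(x), translate_cds(y))
    list(x = back_translate(al$a, x), y = back_translate(al$b, y))
  }
  ab <- pair(cds_a, cds_b)
  ao <- pair(cds_a, cds_out)
  bo <- pair(cds_b, cds_out)
  structure(
    list(ab = ng86_kaks(ab$x, ab$y),
         a_out = ng86_kaks(ao$x, ao$y),
         b_out = ng86_kaks(bo$x, bo$y)),
    class = "kaks_triple"
  )
}

# Effect classification of the selected unigenes' member SNPs, using the
# primary predicted ORF of each selected transcript.
.effect_stage <- function(transcripts, catalog, selection, sel_members,
                          config) {
  if (!nrow(sel_members)) return(NULL)
  sel_tx <- unique(sel_members$transcript_id)
  tx <- transcripts[transcripts$transcript_id %in% sel_tx, , drop = FALSE]
  cds <- predict_cds(tx, min_residues = config$min_orf_residues)
  rows <- list()
  for (i in seq_len(nrow(sel_members))) {
    tid <- sel_members$transcript_id[i]
    seq <- tx$sequence[match(tid, tx$transcript_id)]
    ann <- cds[cds$transcript_id == tid, , drop = FALSE]
    eff <- if (nrow(ann)) {
      classify_substitution(sel_members$position[i], sel_members$ref[i],
                            sel_members$alt[i], ann$start, ann$end,
                            ann$strand, seq)
    } else {
      list(effect = "NC", aa_ref = NA_character_, aa_alt = NA_character_)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = tid, position = sel_members$position[i],
      effect = eff$effect, aa_ref = eff$aa_ref, aa_alt = eff$aa_alt,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
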