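# SNP effect classification (noncoding / synonymous / nonsynonymous) and
# assembly of the final candidate-gene report.

.comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify a substitution as noncoding, synonymous or nonsynonymous
#'
#' A SNP outside `[cds_start, cds_end)` is `NC`. Inside, the alt allele is
#' substituted into its codon (strand-aware: on `-` the complement of the
#' allele enters the reverse-complemented CDS) and both codons are
#' translated with the standard genetic code: same residue is `S`,
#' different is `NS`. A codon containing `N` yields an `NA` effect with the
#' `undeterminable` flag.
#'
#' @param position 0-based SNP position on the transcript.
#' @param ref,alt Reference and alternative alleles (transcript strand).
#' @param cds_start,cds_end 0-based half-open CDS coordinates on the
#'   transcript (stop codon excluded).
#' @param strand `"+"` or `"-"`.
#' @param sequence The transcript sequence.
#' @return A list `effect` (`"NC"`, `"S"`, `"NS"` or `NA`), `aa_ref`,
#'   `aa_alt`, `codon_ref`, `codon_alt`, `undeterminable`.
#' @export
classify_substitution <- function(position, ref, alt, cds_start, cds_end,
                                  strand = "+", sequence) {
  .codon_setup()
  sequence <- toupper(sequence)
  if (position < 0 || position >= nchar(sequence)) {
    stop("position ", position, " outside the transcript")
  }
  base_at <- substr(sequence, position + 1, position + 1)
  if (base_at != toupper(ref)) {
    stop("reference allele mismatch at position ", position,
         ": transcript has ", base_at, ", variant says ", ref)
  }
  if (position < cds_start || position >= cds_end) {
    return(list(effect = "NC", aa_ref = NA_character_,
                aa_alt = NA_character_, codon_ref = NA_character_,
                codon_alt = NA_character_, undeterminable = FALSE))
  }
  cds <- substr(sequence, cds_start + 1, cds_end)
  if (strand == "-") {
    cds <- .revcomp(cds)
    off <- (cds_end - 1) - position
    alt_c <- unname(.comp_base[toupper(alt)])
  } else {
    off <- position - cds_start
    alt_c <- toupper(alt)
  }
  codon_idx <- off %/% 3
  within <- off %% 3
  codon_ref <- substr(cds, codon_idx * 3 + 1, codon_idx * 3 + 3)
  codon_alt <- codon_ref
  substr(codon_alt, within + 1, within + 1) <- alt_c
  aa_ref <- .codon_aa(codon_ref)
  aa_alt <- .codon_aa(codon_alt)
  if (aa_ref == "X" || aa_alt == "X") {
    return(list(effect = NA_character_, aa_ref = aa_ref, aa_alt = aa_alt,
                codon_ref = codon_ref, codon_alt = codon_alt,
                undeterminable = TRUE))
  }
  list(effect = if (aa_ref == aa_alt) "S" else "NS",
       aa_ref = aa_ref, aa_alt = aa_alt,
       codon_ref = codon_ref, codon_alt = codon_alt,
       undeterminable = FALSE)
}

#' Assemble the candidate-gene report
#'
#' Candidates are drawn from the divergent (D-bar selected) unigenes and
#' carry one or both reasons: `multi_snp` (at least
#' `min_snps_for_multi_snp_rule` member SNPs with D at or above
#' `d_threshold`) and `high_kaks` (the branch-specific Ka/Ks rule).
#' Selected unigenes whose ortholog triple is missing or not evaluable are
#' reported in the `exclusions` attribute.
#'
#' @param divergent The `unigenes` element of [select_divergent()].
#' @param variants Output of [compute_D()].
#' @param catalog A `unigene_catalog`.
#' @param kaks A data.frame with columns `gene_id`, `ratio_ab`, `ka_ab`,
#'   `ks_ab`, `ratio_a_out`, `ratio_b_out`, `candidate`,
#'   `flagged_candidate` (see [run_pipeline()]), or `NULL` when the Ka/Ks
#'   stage was not run.
#' @param effects Optional data.frame `transcript_id`, `position`,
#'   `effect`, `aa_ref`, `aa_alt` for the member SNPs.
#' @param config A [pipeline_config()].
#' @return A data.frame of candidates (`component_id`, `dbar`, `n_snps`,
#'   `n_high_d_snps`, `reasons`, Ka/Ks columns, `effects`); attribute
#'   `exclusions` lists divergent unigenes with no evaluable triple.
#' @export
assemble_candidates <- function(divergent, variants, catalog, kaks = NULL,
                                effects = NULL,
                                config = pipeline_config()) {
  comp_of <- stats::setNames(catalog$component_id, catalog$transcript_id)
  v <- variants[!is.na(variants$D), , drop = FALSE]
  v$component_id <- unname(comp_of[v$transcript_id])
  rows <- list()
  excl <- list()
  for (i in seq_len(nrow(divergent))) {
    comp <- divergent$component_id[i]
    member <- v[!is.na(v$component_id) & v$component_id == comp, ,
                drop = FALSE]
    n_high <- sum(member$D >= config$d_threshold)
    multi <- n_high >= config$min_snps_for_multi_snp_rule
    krow <- if (!is.null(kaks) && comp %in% kaks$gene_id) {
      kaks[kaks$gene_id == comp, , drop = FALSE]
    } else {
      NULL
    }
    high_kaks <- !is.null(krow) && isTRUE(krow$candidate)
    if (!is.null(kaks) && is.null(krow)) {
      excl[[length(excl) + 1L]] <- data.frame(
        component_id = comp, reason = "no evaluable ortholog triple",
        stringsAsFactors = FALSE
      )
    }
    if (!multi && !high_kaks) next
    eff <- ""
    if (!is.null(effects)) {
      me <- merge(member[, c("transcript_id", "position")], effects,
                  by = c("transcript_id", "position"))
      if (nrow(me)) {
        me <- me[order(me$position), , drop = FALSE]
        eff <- paste(ifelse(me$effect %in% "NC", "NC",
                            sprintf("%s(%s>%s)", me$effect, me$aa_ref,
                                    me$aa_alt)),
                     collapse = ",")
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      component_id = comp,
      dbar = divergent$dbar[i],
      n_snps = divergent$n_snps[i],
      n_high_d_snps = n_high,
      reasons = paste(c(if (multi) "multi_snp",
                        if (high_kaks) "high_kaks"), collapse = ","),
      ratio_ab = if (is.null(krow)) NA_real_ else krow$ratio_ab,
      ka_ab = if (is.null(krow)) NA_real_ else krow$ka_ab,
      ks_ab = if (is.null(krow)) NA_real_ else krow$ks_ab,
      ratio_a_out = if (is.null(krow)) NA_real_ else krow$ratio_a_out,
      ratio_b_out = if (is.null(krow)) NA_real_ else krow$ratio_b_out,
      effects = eff,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    component_id = character(), dbar = numeric(), n_snps = integer(),
    n_high_d_snps = integer(), reasons = character(),
    ratio_ab = numeric(), ka_ab = numeric(), ks_ab = numeric(),
    ratio_a_out = numeric(), ratio_b_out = numeric(),
    effects = character(), stringsAsFactors = FALSE
  )
  if (nrow(out)) {
    out <- out[order(-out$dbar, out$component_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(component_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}

#' Machine-readable summary of a pipeline run
#'
#' Aggregates the stage counts: SNPs per sharing class, the divergent-set
#' breakdown by number of member SNPs (1 / 2 / 3-or-more), Nei
#' identity/distance for the full and selected SNP sets, the normality
#' check, and the candidate counts per reason.
#'
#' @param classes Output of [classify_sharing()].
#' @param dbar_records Output of [compute_Dbar()].
#' @param selection Output of [select_divergent()].
#' @param nei_all,nei_selected [nei_identity_distance()] results (either
#'   may be `NULL`).
#' @param normality [normality_test()] result or `NULL`.
#' @param candidates Output of [assemble_candidates()] or `NULL`.
#' @return A nested list, suitable for `jsonlite::write_json`.
#' @export
summarize_run <- function(classes, dbar_records, selection,
                          nei_all = NULL, nei_selected = NULL,
                          normality = NULL, candidates = NULL) {
  sel <- selection$unigenes
  breakdown <- list(
    one_snp = sum(sel$n_snps == 1),
    two_snps = sum(sel$n_snps == 2),
    three_or_more = sum(sel$n_snps >= 3)
  )
  nei_list <- function(x) {
    if (is.null(x)) NULL else x[c("mean_identity", "distance_of_mean",
                                  "mean_of_distances", "n_loci",
                                  "n_zero_identity")]
  }
  reasons <- if (!is.null(candidates) && nrow(candidates)) {
    strsplit(candidates$reasons, ",", fixed = TRUE)
  } else {
    list()
  }
  list(
    snp_classes = attr(classes, "class_tally"),
    n_rescued_fixed = attr(classes, "n_rescued_fixed"),
    n_unigenes_with_snps = nrow(dbar_records),
    n_divergent_unigenes = nrow(sel),
    divergent_snp_breakdown = breakdown,
    n_high_d_snps = nrow(selection$snps),
    n_snps_in_divergent_unigenes = sum(sel$n_snps),
    nei_all_snps = nei_list(nei_all),
    nei_divergent_snps = nei_list(nei_selected),
    normality = normality,
    n_candidates = if (is.null(candidates)) 0L else nrow(candidates),
    n_multi_snp_candidates =
      sum(vapply(reasons, function(r) "multi_snp" %in% r, logical(1))),
    n_kaks_candidates =
      sum(vapply(reasons, function(r) "high_kaks" %in% r, logical(1)))
  )
}
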