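# Isoform-to-unigene reduction, per-species allele-frequency estimation,
# SNP filtering and species-sharing classification.

#' Reduce isoforms to unigenes (longest transcript per component)
#'
#' Within each component the longest transcript is kept as the unigene;
#' length ties are broken by the lexicographically smallest transcript id.
#' Variants on discarded isoforms are excluded downstream.
#'
#' @param transcripts A transcripts data.frame (see [read_transcripts()]).
#' @return A data.frame of class `unigene_catalog` with columns
#'   `component_id`, `transcript_id`, `length`; attribute `discarded` holds
#'   the discarded isoform ids.
#' @export
dedup_longest_isoform <- function(transcripts) {
  if (nrow(transcripts) == 0) {
    out <- data.frame(component_id = character(), transcript_id = character(),
                      length = integer(), stringsAsFactors = FALSE)
    attr(out, "discarded") <- character(0)
    class(out) <- c("unigene_catalog", "data.frame")
    return(out)
  }
  len <- nchar(transcripts$sequence)
  ord <- order(transcripts$component_id, -len, transcripts$transcript_id)
  t2 <- transcripts[ord, , drop = FALSE]
  keep <- !duplicated(t2$component_id)
  out <- data.frame(component_id = t2$component_id[keep],
                    transcript_id = t2$transcript_id[keep],
                    length = len[ord][keep], stringsAsFactors = FALSE)
  out <- out[order(out$component_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- t2$transcript_id[!keep]
  class(out) <- c("unigene_catalog", "data.frame")
  out
}

#' Estimate per-species alt-allele frequencies
#'
#' F = alt / (ref + alt) per species; a species with zero depth at a site
#' has an undefined frequency (`NA`) and the site is flagged as not
#' evaluable in that species. Frequencies are always oriented to the alt
#' allele of the shared reference, so they are comparable across species.
#'
#' @param variants A `variant_table`.
#' @return The input with added columns `depth_a`, `depth_b`, `f_a`, `f_b`,
#'   `maf_a`, `maf_b`.
#' @export
estimate_frequencies <- function(variants) {
  v <- variants
  v$depth_a <- v$ref_a + v$alt_a
  v$depth_b <- v$ref_b + v$alt_b
  v$f_a <- ifelse(v$depth_a > 0, v$alt_a / v$depth_a, NA_real_)
  v$f_b <- ifelse(v$depth_b > 0, v$alt_b / v$depth_b, NA_real_)
  v$maf_a <- pmin(v$f_a, 1 - v$f_a)
  v$maf_b <- pmin(v$f_b, 1 - v$f_b)
  v
}

#' Apply the per-species SNP filters
#'
#' A site is retained for species s iff its minor allele frequency in s is
#' at least `maf_min`, the site quality at least `qual_min` and the depth
#' in s at least `depth_min` (all thresholds inclusive). Per-rule rejection
#' counts are reported in the `tally` attribute.
#'
#' @param variants Output of [estimate_frequencies()].
#' @param config A [pipeline_config()].
#' @return The input with logical columns `pass_a`, `pass_b`; attribute
#'   `tally` is a named list of per-rule rejection counts.
#' @export
filter_snps <- function(variants, config = pipeline_config()) {
  v <- variants
  qual_ok <- v$qual >= config$qual_min
  depth_a_ok <- v$depth_a >= config$depth_min
  depth_b_ok <- v$depth_b >= config$depth_min
  maf_a_ok <- !is.na(v$maf_a) & v$maf_a >= config$maf_min
  maf_b_ok <- !is.na(v$maf_b) & v$maf_b >= config$maf_min
  v$pass_a <- qual_ok & depth_a_ok & maf_a_ok
  v$pass_b <- qual_ok & depth_b_ok & maf_b_ok
  attr(v, "tally") <- list(
    n_input = nrow(v),
    fail_qual = sum(!qual_ok),
    fail_depth_a = sum(!depth_a_ok),
    fail_depth_b = sum(!depth_b_ok),
    fail_maf_a = sum(!maf_a_ok),
    fail_maf_b = sum(!maf_b_ok),
    retained_a = sum(v$pass_a),
    retained_b = sum(v$pass_b)
  )
  v
}

#' Classify sites as species-specific, shared, or set aside
#'
#' The partition is exact: every input site falls in exactly one of
#' `common` (a SNP in both species), `specificA` / `specificB` (a SNP in
#' one species with evaluable coverage but sub-threshold MAF in the other),
#' `uncallable` (inadequate depth in either species; such sites are never
#' counted as specific), or `filtered` (quality failure, or evaluable in
#' both species but a SNP in neither).
#'
#' Separately, the logical column `d_callable` marks sites usable for the
#' differentiation index D: sites with both frequencies defined and
#' adequate depth/quality that are a SNP in at least one species, plus --
#' when `rescue_fixed_differences` is enabled -- oppositely fixed sites
#' whose within-species MAF is 0 in both species. With
#' `d_universe = "shared"` only `common` (and rescued fixed) sites enter D.
#'
#' @param variants Output of [estimate_frequencies()].
#' @param config A [pipeline_config()].
#' @return The input with columns `class` and `d_callable`; attribute
#'   `class_tally` is the named count per class.
#' @export
classify_sharing <- function(variants, config = pipeline_config()) {
  v <- variants
  qual_ok <- v$qual >= config$qual_min
  call_a <- v$depth_a >= config$depth_min
  call_b <- v$depth_b >= config$depth_min
  snp_a <- !is.na(v$maf_a) & v$maf_a >= config$maf_min
  snp_b <- !is.na(v$maf_b) & v$maf_b >= config$maf_min

  cls <- rep("filtered", nrow(v))
  uncall <- qual_ok & !(call_a & call_b)
  cls[uncall] <- "uncallable"
  both <- qual_ok & call_a & call_b
  cls[both & snp_a & snp_b] <- "common"
  if (config$require_other_species_coverage) {
    cls[both & snp_a & !snp_b] <- "specificA"
    cls[both & !snp_a & snp_b] <- "specificB"
  } else {
    cls[qual_ok & call_a & snp_a & !(call_b & snp_b)] <- "specificA"
    cls[qual_ok & call_b & snp_b & !(call_a & snp_a)] <- "specificB"
  }
  opp_fixed <- both &
    ((v$f_a >= 1 - config$maf_min & v$f_b <= config$maf_min) |
     (v$f_a <= config$maf_min & v$f_b >= 1 - config$maf_min))
  opp_fixed[is.na(opp_fixed)] <- FALSE

  d_callable <- both & !is.na(v$f_a) & !is.na(v$f_b)
  if (config$d_universe == "shared") {
    d_callable <- d_callable & (snp_a & snp_b)
  } else {
    d_callable <- d_callable & (snp_a | snp_b)
  }
  if (config$rescue_fixed_differences) {
    d_callable <- d_callable | opp_fixed
  }
  v$class <- cls
  v$d_callable <- d_callable
  tally <- table(factor(cls, levels = c("specificA", "specificB", "common",
                                        "uncallable", "filtered")))
  attr(v, "class_tally") <- as.list(tally)
  attr(v, "n_rescued_fixed") <- sum(opp_fixed & !(snp_a | snp_b))
  v
}
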