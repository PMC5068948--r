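# Pairwise global protein alignment (Needleman-Wunsch, affine gaps,
# BLOSUM62), reciprocal-best-hit ortholog detection, and back-translation
# of protein alignments to codon alignments.

.aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
    "F", "P", "S", "T", "W", "Y", "V", "X")
}

.check_protein <- function(x, what = "protein") {
  bad <- setdiff(unique(strsplit(toupper(x), "")[[1]]), .aa_alphabet())
  if (length(bad)) {
    stop(what, " contains non-amino-acid symbol(s): ",
         paste(bad, collapse = ", "))
  }
  toupper(x)
}

#' Global protein alignment with affine gap penalties
#'
#' Needleman-Wunsch alignment under BLOSUM62 with gap cost
#' `gap_open + gap_extend * length` per gap, delegated to
#' `Biostrings::pairwiseAlignment` (deterministic traceback).
#'
#' @param a,b Amino-acid strings (standard 20 letters plus X).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A list `a`, `b` (gapped aligned strings) and `score`.
#' @export
align_proteins <- function(a, b, gap_open = 11, gap_extend = 1) {
  a <- .check_protein(a, "first sequence")
  b <- .check_protein(b, "second sequence")
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty protein sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"
  )
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' All-vs-all global alignment scores between two protein sets
#'
#' @param set_a,set_b Named character vectors of protein sequences.
#' @inheritParams align_proteins
#' @return A numeric matrix, rows = `set_a`, columns = `set_b`.
#' @export
alignment_scores <- function(set_a, set_b, gap_open = 11, gap_extend = 1) {
  stopifnot(length(set_a) > 0, length(set_b) > 0,
            !is.null(names(set_a)), !is.null(names(set_b)))
  pat <- Biostrings::AAStringSet(toupper(set_a))
  scores <- vapply(seq_along(set_b), function(j) {
    Biostrings::pairwiseAlignment(
      pat, Biostrings::AAString(toupper(set_b[[j]])),
      substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
      gapExtension = gap_extend, type = "global", scoreOnly = TRUE
    )
  }, numeric(length(set_a)))
  scores <- matrix(scores, nrow = length(set_a),
                   dimnames = list(names(set_a), names(set_b)))
  scores
}

#' Reciprocal-best-hit ortholog pairs
#'
#' A pair (a, b) is reported iff b is a's unique best-scoring partner and a
#' is b's; a tie for best on either side disqualifies the sequence
#' (conservative), and scores below `min_score` are ignored.
#'
#' @param set_a,set_b Named character vectors of protein sequences.
#' @param min_score Minimum alignment score for a hit to count.
#' @param scores Optional precomputed score matrix
#'   ([alignment_scores()]); when supplied, `set_a`/`set_b` may be `NULL`.
#' @inheritParams align_proteins
#' @return A data.frame `id_a`, `id_b`, `score`.
#' @export
reciprocal_best_hits <- function(set_a, set_b, min_score = 50,
                                 gap_open = 11, gap_extend = 1,
                                 scores = NULL) {
  if (is.null(scores)) {
    scores <- alignment_scores(set_a, set_b, gap_open, gap_extend)
  }
  scores[scores < min_score] <- NA_real_
  best_unique <- function(v) {
    if (all(is.na(v))) return(NA_integer_)
    m <- max(v, na.rm = TRUE)
    w <- which(!is.na(v) & v == m)
    if (length(w) == 1) w else NA_integer_
  }
  best_b <- apply(scores, 1, best_unique)
  best_a <- apply(scores, 2, best_unique)
  pairs <- which(!is.na(best_b) &
                   vapply(seq_along(best_b), function(i) {
                     j <- best_b[i]
                     !is.na(best_a[j]) && best_a[j] == i
                   }, logical(1)))
  data.frame(
    id_a = rownames(scores)[pairs],
    id_b = colnames(scores)[best_b[pairs]],
    score = scores[cbind(pairs, best_b[pairs])],
    stringsAsFactors = FALSE
  )
}

#' Back-translate an aligned protein to a codon alignment
#'
#' Each residue column of the gapped protein expands to its source codon
#' from the original CDS; gap residues expand to `---`. The ungapped
#' protein must equal the translation of the CDS (a terminal stop codon on
#' the CDS is tolerated and dropped).
#'
#' @param aligned_protein Gapped amino-acid string (`-` for gaps).
#' @param cds The original, ungapped coding sequence.
#' @return A gapped nucleotide string of length `3 * nchar(aligned_protein)`.
#' @export
back_translate <- function(aligned_protein, cds) {
  cds <- toupper(cds)
  prot <- gsub("-", "", aligned_protein, fixed = TRUE)
  n_res <- nchar(prot)
  if (nchar(cds) == 3 * (n_res + 1)) {
    last <- substr(cds, nchar(cds) - 2, nchar(cds))
    if (.codon_aa(last) == "*") cds <- substr(cds, 1, nchar(cds) - 3)
  }
  if (nchar(cds) != 3 * n_res) {
    stop("CDS length (", nchar(cds), ") does not match ", n_res,
         " aligned residues")
  }
  trans <- translate_cds(cds)
  if (toupper(prot) != trans) {
    mism <- which(strsplit(toupper(prot), "")[[1]] !=
                    strsplit(trans, "")[[1]])[1]
    stop("protein does not match CDS translation at residue ", mism,
         " ('", substr(prot, mism, mism), "' vs '",
         substr(trans, mism, mism), "')")
  }
  cod <- .split_codons(cds)
  res <- strsplit(toupper(aligned_protein), "")[[1]]
  out <- character(length(res))
  out[res == "-"] <- "---"
  out[res != "-"] <- cod
  paste(out, collapse = "")
}

#' Branch-specific Ka/Ks candidate rule
#'
#' A gene is a clean candidate iff the ingroup-pair ratio is at least
#' `kaks_candidate_min` while both ingroup-vs-outgroup ratios are strictly
#' below `kaks_outgroup_max`. Degenerate estimates (`ks_zero`,
#' `jc_saturated`) keep the gene off the clean list but on a flagged list
#' when the usable ratios satisfy the rule; `Inf` ingroup ratios (Ks = 0,
#' Ka > 0) satisfy the ingroup condition but are always flagged.
#'
#' @param triple A [kaks_triple()] result, or a list with numeric elements
#'   `ratio_ab`, `ratio_a_out`, `ratio_b_out` (and optional logical
#'   `flagged`).
#' @param config A [pipeline_config()].
#' @return A list `candidate` (clean), `flagged_candidate`, `rationale`.
#' @export
kaks_candidate_rule <- function(triple, config = pipeline_config()) {
  if (inherits(triple, "kaks_triple")) {
    r_ab <- triple$ab$ratio
    r_ao <- triple$a_out$ratio
    r_bo <- triple$b_out$ratio
    degenerate <- triple$ab$ks_zero || triple$ab$jc_saturated ||
      triple$a_out$ks_zero || triple$a_out$jc_saturated ||
      triple$b_out$ks_zero || triple$b_out$jc_saturated
  } else {
    r_ab <- triple$ratio_ab
    r_ao <- triple$ratio_a_out
    r_bo <- triple$ratio_b_out
    degenerate <- isTRUE(triple$flagged) || is.infinite(r_ab) ||
      is.infinite(r_ao) || is.infinite(r_bo)
  }
  if (any(is.na(c(r_ab, r_ao, r_bo))) ||
      any(is.nan(c(r_ab, r_ao, r_bo)))) {
    return(list(candidate = FALSE, flagged_candidate = FALSE,
                rationale = "rule not evaluable: undefined pairwise ratio"))
  }
  passes <- r_ab >= config$kaks_candidate_min &&
    r_ao < config$kaks_outgroup_max && r_bo < config$kaks_outgroup_max
  rationale <- sprintf(
    "ingroup %.4g %s %.3g; outgroup %.4g/%.4g %s %.3g%s",
    r_ab, if (r_ab >= config$kaks_candidate_min) ">=" else "<",
    config$kaks_candidate_min, r_ao, r_bo,
    if (r_ao < config$kaks_outgroup_max &&
        r_bo < config$kaks_outgroup_max) "<" else "not both <",
    config$kaks_outgroup_max,
    if (degenerate) "; degenerate estimate flagged" else ""
  )
  list(candidate = passes && !degenerate,
       flagged_candidate = passes && degenerate,
       rationale = rationale)
}
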