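# Nei-Gojobori (1986) approximate Ka/Ks with Jukes-Cantor correction.
#
# Sites are counted fractionally per codon (average of the two sequences);
# observed synonymous/nonsynonymous differences are averaged with equal
# weight over all minimal mutational pathways between differing codons,
# excluding pathways through stop codons. The per-codon quantities come
# from cached 64 x 64 lookup tables (see genetic-code.R).

#' Estimate Ka and Ks for a pair of aligned coding sequences (NG86)
#'
#' Both sequences must have equal length, a multiple of 3, and be codon
#' alignments of one another (e.g. the output of [back_translate()]).
#' Codon columns in which either sequence carries a gap, an ambiguous base,
#' or a stop codon are skipped and counted in `n_skipped`.
#'
#' Proportions of differences are corrected for multiple hits with the
#' Jukes-Cantor formula d = -(3/4) log(1 - (4/3) p). A proportion p >= 3/4
#' cannot be corrected; the corresponding distance is `NA` and the result is
#' flagged `jc_saturated`. `Ks = 0` with `Ka > 0` yields `ratio = Inf` and
#' the `ks_zero` flag; `Ka = Ks = 0` yields `ratio = NaN`.
#'
#' @param seq_a,seq_b Aligned nucleotide strings (may contain `-` and `N`).
#' @return An object of class `kaks_result`: a list with elements `ka`, `ks`,
#'   `ratio`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `n_codons`, `n_skipped`,
#'   `ks_zero`, `jc_saturated`.
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @examples
#' ng86_kaks("TTTTTC", "TTTTTT")  # one synonymous third-position change
#' @export
ng86_kaks <- function(seq_a, seq_b) {
  tabs <- .ng86_tables()
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length (",
         nchar(seq_a), " vs ", nchar(seq_b), ")")
  }
  if (nchar(seq_a) %% 3 != 0) {
    stop("alignment length must be a multiple of 3, got ", nchar(seq_a))
  }
  ca <- .split_codons(seq_a)
  cb <- .split_codons(seq_b)
  ia <- match(ca, .ds$codons)
  ib <- match(cb, .ds$codons)
  keep <- !is.na(ia) & !is.na(ib) &
    .ds$aa[pmax(ia, 1)] != "*" & .ds$aa[pmax(ib, 1)] != "*"
  keep[is.na(keep)] <- FALSE
  n_skipped <- sum(!keep)
  ia <- ia[keep]
  ib <- ib[keep]
  n_codons <- length(ia)
  if (n_codons == 0) {
    stop("no comparable codon columns in the alignment")
  }
  S <- sum((.ds$syn_sites[ia] + .ds$syn_sites[ib]) / 2)
  N <- 3 * n_codons - S
  Sd <- sum(tabs$sd[cbind(ia, ib)])
  Nd <- sum(tabs$nd[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  ks <- .jc_correct(pS)
  ka <- .jc_correct(pN)
  jc_saturated <- is.na(ks) || is.na(ka)
  ks_zero <- isTRUE(!is.na(ka) && !is.na(ks) && ks == 0 && ka > 0)
  ratio <- if (jc_saturated) {
    NA_real_
  } else if (ks > 0) {
    ka / ks
  } else if (ka > 0) {
    Inf
  } else {
    NaN
  }
  structure(
    list(ka = ka, ks = ks, ratio = ratio,
         S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
         n_codons = n_codons, n_skipped = n_skipped,
         ks_zero = ks_zero, jc_saturated = jc_saturated),
    class = "kaks_result"
  )
}

.jc_correct <- function(p) {
  if (p >= 3 / 4) return(NA_real_)
  -3 / 4 * log(1 - 4 / 3 * p)
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86 Ka/Ks over %d codons (%d skipped)\n",
              x$n_codons, x$n_skipped))
  cat(sprintf("  Ka = %.4g (Nd = %.3f over N = %.2f sites)\n",
              x$ka, x$Nd, x$N))
  cat(sprintf("  Ks = %.4g (Sd = %.3f over S = %.2f sites)\n",
              x$ks, x$Sd, x$S))
  cat(sprintf("  Ka/Ks = %.4g%s%s\n", x$ratio,
              if (x$ks_zero) " [ks_zero]" else "",
              if (x$jc_saturated) " [jc_saturated]" else ""))
  invisible(x)
}

#' NG86 Ka/Ks for an ortholog triple (two ingroup species plus outgroup)
#'
#' Computes the three pairwise NG86 estimates of an ortholog set: between
#' the two ingroup species, and between each ingroup species and the
#' outgroup. Input sequences must be codon alignments of one another over a
#' common coordinate system (equal lengths, multiples of 3).
#'
#' @param cds_a,cds_b,cds_out Aligned CDS strings for ingroup species A and
#'   B and the outgroup.
#' @return A list of class `kaks_triple` with elements `ab`, `a_out`,
#'   `b_out`, each a [ng86_kaks()] result.
#' @export
kaks_triple <- function(cds_a, cds_b, cds_out) {
  structure(
    list(ab = ng86_kaks(cds_a, cds_b),
         a_out = ng86_kaks(cds_a, cds_out),
         b_out = ng86_kaks(cds_b, cds_out)),
    class = "kaks_triple"
  )
}
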