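# Codon-usage tables and Wright's effective number of codons (Nc).

# Synonymous families of the standard genetic code, grouped by degeneracy.
# Met and Trp are single-codon and excluded; stops are excluded. The
# degeneracy-class counts (9 two-fold, 1 three-fold, 5 four-fold, 3
# six-fold) are the weights in Wright's formula.
.codon_families <- function() {
  .codon_setup()
  fam <- split(.ds$codons[.ds$aa != "*"], .ds$aa[.ds$aa != "*"])
  fam[vapply(fam, length, integer(1)) > 1]
}

#' Codon usage table and Wright's Nc for a set of coding sequences
#'
#' Counts codons over all sequences and computes, per amino acid, the
#' synonymous-codon fractions and the codon homozygosity
#' F = sum(p_i^2); Wright's effective number of codons is
#' Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, with Fk the average homozygosity of
#' the k-fold degenerate families. Families with no observed codons are
#' dropped from their class average; a missing three-fold class (Ile only)
#' is imputed as the mean of the two- and four-fold averages, the standard
#' fallback. With `bias_correct = TRUE` the small-sample estimator
#' F = (n * sum(p_i^2) - 1) / (n - 1) is used instead (families with fewer
#' than 2 codons, or non-positive F, are dropped); note the corrected
#' estimator is unbounded above for near-uniform small samples, while the
#' default keeps Nc in [20, 61] for any input.
#'
#' @param cds A character vector of CDS strings (lengths multiples of 3).
#'   Terminal stop codons are counted in the table but never enter Nc.
#' @param bias_correct Use the small-sample homozygosity estimator.
#' @return A list of class `codon_usage`: `counts` (named, 64), `fractions`
#'   (per-amino-acid synonymous fractions), `family_F` (homozygosity per
#'   multi-codon amino acid), `nc`.
#' @export
codon_usage <- function(cds, bias_correct = FALSE) {
  .codon_setup()
  if (length(cds) == 0) stop("empty CDS set")
  codons <- unlist(lapply(toupper(cds), function(s) {
    if (nchar(s) %% 3 != 0) {
      stop("CDS length must be a multiple of 3, got ", nchar(s))
    }
    .split_codons(s)
  }))
  codons <- codons[codons %in% .ds$codons]
  counts <- table(factor(codons, levels = .ds$codons))
  counts <- stats::setNames(as.integer(counts), .ds$codons)

  fam <- .codon_families()
  fractions <- rep(NA_real_, 64)
  names(fractions) <- .ds$codons
  family_F <- rep(NA_real_, length(fam))
  names(family_F) <- names(fam)
  for (aa in names(fam)) {
    n_i <- counts[fam[[aa]]]
    n <- sum(n_i)
    if (n == 0) next
    p <- n_i / n
    fractions[fam[[aa]]] <- p
    if (bias_correct) {
      if (n >= 2) {
        f <- (n * sum(p^2) - 1) / (n - 1)
        family_F[aa] <- if (f > 0) f else NA_real_
      }
    } else {
      family_F[aa] <- sum(p^2)
    }
  }
  deg <- vapply(fam, length, integer(1))
  f_bar <- vapply(c(2, 3, 4, 6), function(k) {
    vals <- family_F[deg == k]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  names(f_bar) <- c("F2", "F3", "F4", "F6")
  if (is.na(f_bar["F3"]) && !is.na(f_bar["F2"]) && !is.na(f_bar["F4"])) {
    f_bar["F3"] <- mean(f_bar[c("F2", "F4")])
  }
  nc <- if (any(is.na(f_bar))) NA_real_ else {
    2 + 9 / f_bar[["F2"]] + 1 / f_bar[["F3"]] +
      5 / f_bar[["F4"]] + 3 / f_bar[["F6"]]
  }
  structure(list(counts = counts, fractions = fractions,
                 family_F = family_F, f_bar = f_bar, nc = nc),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("Codon usage over %d codons; Nc = %.2f\n",
              sum(x$counts), x$nc))
  invisible(x)
}

#' Mean square difference between two codon-usage tables
#'
#' The mean over sense codons of the squared difference of per-amino-acid
#' synonymous fractions; codons whose amino acid is unobserved in either
#' table are skipped. Values near 0 indicate indistinguishable codon usage.
#'
#' @param usage_a,usage_b Two [codon_usage()] results.
#' @return A single number.
#' @export
codon_usage_msd <- function(usage_a, usage_b) {
  fa <- usage_a$fractions
  fb <- usage_b$fractions
  ok <- !is.na(fa) & !is.na(fb)
  if (!any(ok)) stop("no codons comparable between the two tables")
  mean((fa[ok] - fb[ok])^2)
}
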