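# Codon-level lookup tables shared by the NG86 estimator, the ORF finder,
# the codon-usage statistics and the codon-evolution simulator. Built once
# per session from the standard genetic code and cached.

NUCS <- c("A", "C", "G", "T")

.ds <- new.env(parent = emptyenv())

.codon_setup <- function() {
  if (!is.null(.ds$codons)) return(invisible())
  gc <- Biostrings::GENETIC_CODE
  .ds$codons <- names(gc)
  .ds$aa <- unname(gc)
  .ds$aa_by_codon <- gc
  .ds$sense <- .ds$codons[.ds$aa != "*"]

  # Fractional synonymous site count per codon (NG86): at each of the three
  # positions the synonymous fraction of the three possible changes; changes
  # that create a stop codon count as nonsynonymous so that S + N = 3 exactly.
  syn <- rep(NA_real_, 64)
  names(syn) <- .ds$codons
  for (cod in .ds$sense) {
    ch <- strsplit(cod, "")[[1]]
    aa0 <- gc[[cod]]
    n_syn <- 0L
    for (p in 1:3) {
      for (b in NUCS[NUCS != ch[p]]) {
        alt <- ch
        alt[p] <- b
        if (identical(gc[[paste(alt, collapse = "")]], aa0)) n_syn <- n_syn + 1L
      }
    }
    syn[cod] <- n_syn / 3
  }
  .ds$syn_sites <- syn
  invisible()
}

.codon_aa <- function(codon) {
  a <- .ds$aa_by_codon[codon]
  a[is.na(a)] <- "X"
  unname(a)
}

.perm_list <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Average synonymous/nonsynonymous step counts over all minimal mutational
# pathways between two sense codons. Pathways passing through a stop codon
# are excluded and the average is over the remaining ones; if every pathway
# is blocked (cannot happen for sense codons under the standard code at
# <= 3 differences, but guarded), all pathways are used with steps touching
# a stop counted as nonsynonymous.
.path_counts <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  x1 <- strsplit(c1, "")[[1]]
  x2 <- strsplit(c2, "")[[1]]
  dpos <- which(x1 != x2)
  k <- length(dpos)
  perms <- .perm_list[[k]]
  walk <- function(exclude_stops) {
    sds <- numeric(0)
    nds <- numeric(0)
    for (ord in perms) {
      cur <- x1
      sd <- 0
      nd <- 0
      ok <- TRUE
      for (p in dpos[ord]) {
        aa_cur <- .ds$aa_by_codon[[paste(cur, collapse = "")]]
        cur[p] <- x2[p]
        aa_new <- .ds$aa_by_codon[[paste(cur, collapse = "")]]
        if (aa_new == "*" && exclude_stops) {
          ok <- FALSE
          break
        }
        if (aa_new == aa_cur && aa_new != "*") sd <- sd + 1 else nd <- nd + 1
      }
      if (ok) {
        sds <- c(sds, sd)
        nds <- c(nds, nd)
      }
    }
    if (length(sds)) c(sd = mean(sds), nd = mean(nds)) else NULL
  }
  res <- walk(TRUE)
  if (is.null(res)) res <- walk(FALSE)
  res
}

# 64 x 64 matrices of pathway-averaged Sd and Nd; entries involving stop
# codons are NA (stop-containing columns are skipped upstream).
.ng86_tables <- function() {
  .codon_setup()
  if (!is.null(.ds$sd_mat)) {
    return(list(sd = .ds$sd_mat, nd = .ds$nd_mat))
  }
  n <- 64L
  sd_mat <- matrix(NA_real_, n, n, dimnames = list(.ds$codons, .ds$codons))
  nd_mat <- sd_mat
  sense_idx <- which(.ds$aa != "*")
  for (i in sense_idx) {
    for (j in sense_idx) {
      if (j < i) next
      pc <- .path_counts(.ds$codons[i], .ds$codons[j])
      sd_mat[i, j] <- sd_mat[j, i] <- pc[["sd"]]
      nd_mat[i, j] <- nd_mat[j, i] <- pc[["nd"]]
    }
  }
  .ds$sd_mat <- sd_mat
  .ds$nd_mat <- nd_mat
  list(sd = sd_mat, nd = nd_mat)
}

.split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a coding sequence with the standard genetic code
#'
#' Codons containing characters other than A, C, G, T (for example `N` or an
#' alignment gap) translate to `X`; stop codons translate to `*`.
#'
#' @param cds A nucleotide string whose length is a multiple of 3.
#' @return A single amino-acid string, one residue per codon.
#' @export
translate_cds <- function(cds) {
  .codon_setup()
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length must be a multiple of 3, got ", nchar(cds))
  }
  if (nchar(cds) == 0) return("")
  paste(.codon_aa(.split_codons(cds)), collapse = "")
}
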