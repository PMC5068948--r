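# Six-frame ORF prediction on transcripts.

#' Find open reading frames in all six frames
#'
#' Scans the three forward and three reverse-complement frames for maximal
#' stop-to-stop segments. Within a segment the first ATG starts the ORF
#' (`complete` when both an ATG and a terminal stop are present); a segment
#' without ATG is reported from its 5' edge and flagged incomplete. Only
#' ORFs of at least `min_residues` residues are reported; the longest per
#' sequence is marked `primary` (ties: smallest start, `+` before `-`).
#'
#' Coordinates are 0-based half-open on the forward strand of the input
#' transcript and exclude the stop codon, so `end - start` is always
#' `3 * n_residues`.
#'
#' @param sequence A nucleotide string over A, C, G, T, N.
#' @param min_residues Minimum protein length in residues (inclusive).
#' @return A data.frame `strand`, `frame`, `start`, `end`, `n_residues`,
#'   `has_start`, `has_stop`, `complete`, `primary`, ordered by decreasing
#'   length.
#' @export
find_orfs <- function(sequence, min_residues = 100) {
  .codon_setup()
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  L <- nchar(sequence)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else .revcomp(sequence)
    for (frame in 0:2) {
      n_cod <- (L - frame) %/% 3
      if (n_cod < 1) next
      codons <- substring(s, frame + 1 + 3 * (seq_len(n_cod) - 1),
                          frame + 3 * seq_len(n_cod))
      aa <- .codon_aa(codons)
      stop_idx <- which(aa == "*")
      seg_starts <- c(1L, stop_idx + 1L)
      seg_ends <- c(stop_idx - 1L, n_cod)
      for (k in seq_along(seg_starts)) {
        a <- seg_starts[k]
        b <- seg_ends[k]
        if (a > b) next
        has_stop <- k <= length(stop_idx)
        atg <- which(codons[a:b] == "ATG")
        if (length(atg)) {
          a_orf <- a + atg[1] - 1L
          has_start <- TRUE
        } else {
          a_orf <- a
          has_start <- FALSE
        }
        n_res <- b - a_orf + 1L
        if (n_res < min_residues) next
        start_local <- frame + 3L * (a_orf - 1L)   # 0-based on strand s
        end_local <- frame + 3L * b
        if (strand == "+") {
          start_t <- start_local
          end_t <- end_local
        } else {
          start_t <- L - end_local
          end_t <- L - start_local
        }
        res[[length(res) + 1L]] <- data.frame(
          strand = strand, frame = frame, start = start_t, end = end_t,
          n_residues = n_res, has_start = has_start, has_stop = has_stop,
          complete = has_start && has_stop, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(res)) {
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      n_residues = integer(), has_start = logical(),
                      has_stop = logical(), complete = logical(),
                      primary = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$n_residues, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$primary <- seq_len(nrow(out)) == 1L
  out
}

#' Predict the primary CDS of each transcript
#'
#' Runs [find_orfs()] per transcript and keeps the primary (longest) ORF.
#'
#' @param transcripts A transcripts data.frame.
#' @param min_residues Minimum protein length.
#' @return A data.frame `transcript_id`, `strand`, `frame`, `start`, `end`,
#'   `n_residues`, `complete`, `cds` (the extracted, strand-corrected CDS
#'   string). Transcripts without a qualifying ORF are absent.
#' @export
predict_cds <- function(transcripts, min_residues = 100) {
  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    orfs <- find_orfs(transcripts$sequence[i], min_residues)
    if (!nrow(orfs)) next
    o <- orfs[orfs$primary, , drop = FALSE]
    cds <- substr(transcripts$sequence[i], o$start + 1L, o$end)
    if (o$strand == "-") cds <- .revcomp(cds)
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = transcripts$transcript_id[i],
      strand = o$strand, frame = o$frame, start = o$start, end = o$end,
      n_residues = o$n_residues, complete = o$complete, cds = cds,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(), strand = character(),
                      frame = integer(), start = integer(),
                      end = integer(), n_residues = integer(),
                      complete = logical(), cds = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
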