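# Fixture builders shared across the test files. Everything is generated
# in code; no fixture files.

make_variants <- function(transcript, position, ref, alt,
                          ref_a, alt_a, ref_b, alt_b, qual = 40) {
  n <- length(position)
  df <- data.frame(
    transcript_id = rep_len(transcript, n), position = as.integer(position),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    ref_a = as.integer(rep_len(ref_a, n)), alt_a = as.integer(rep_len(alt_a, n)),
    ref_b = as.integer(rep_len(ref_b, n)), alt_b = as.integer(rep_len(alt_b, n)),
    qual = as.numeric(rep_len(qual, n)), stringsAsFactors = FALSE
  )
  attr(df, "species") <- c("A", "B")
  attr(df, "n_excluded") <- 0L
  class(df) <- c("variant_table", "data.frame")
  df
}

make_transcripts <- function(transcript_id, component_id, sequence) {
  data.frame(transcript_id = transcript_id, component_id = component_id,
             sequence = sequence, stringsAsFactors = FALSE)
}

# classified + D-computed variants from frequency pairs at high depth
variants_from_freqs <- function(f_a, f_b, transcript = "t1",
                                position = NULL, depth = 1000,
                                config = pipeline_config()) {
  n <- length(f_a)
  if (is.null(position)) position <- seq_len(n) - 1L
  v <- make_variants(rep_len(transcript, n), position,
                     rep("A", n), rep("G", n),
                     round(depth * (1 - f_a)), round(depth * f_a),
                     round(depth * (1 - f_b)), round(depth * f_b))
  v <- estimate_frequencies(v)
  v <- filter_snps(v, config)
  v <- classify_sharing(v, config)
  compute_D(v)
}

random_sense_codon_seq <- function(n_codons) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
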