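# Readers and writers for the formats the pipeline touches: transcript and
# CDS FASTA (via Biostrings), variant tables (VCF with per-sample allele
# depths via vcfR, or a flat TSV), and the deterministic report writer.

.log_stage <- function(fmt, ...) {
  message(sprintf("[divscreen %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

.tsv_cols <- c("transcript", "pos", "ref", "alt",
               "refA", "altA", "refB", "altB", "qual")

#' Read transcripts from a FASTA file
#'
#' Headers are parsed into a transcript id (the first whitespace-delimited
#' token) and a component (unigene) id obtained by stripping an isoform
#' suffix: with the default `isoform_sep = "_seq"`, `"comp1_c0_seq2"` maps
#' to component `"comp1_c0"`. Headers without the suffix form their own
#' single-transcript component. Sequences are upper-cased and `U` is mapped
#' to `T`; characters outside `A`, `C`, `G`, `T`, `N` are an error.
#'
#' @param path FASTA file.
#' @param isoform_sep Token that separates the component id from the
#'   isoform index in the header.
#' @return A data.frame with columns `transcript_id`, `component_id`,
#'   `sequence`, in input order.
#' @export
read_transcripts <- function(path, isoform_sep = "_seq") {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) {
    warning("empty FASTA: ", path)
    return(data.frame(transcript_id = character(), component_id = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(ids == "")) {
    stop("malformed FASTA header (empty id) at record ", which(ids == "")[1])
  }
  if (anyDuplicated(ids)) {
    stop("duplicated transcript id: ", ids[duplicated(ids)][1])
  }
  sequence <- chartr("u", "t", toupper(as.character(seqs)))
  sequence <- chartr("U", "T", sequence)
  if (any(nchar(sequence) == 0)) {
    stop("empty sequence for record ", ids[nchar(sequence) == 0][1])
  }
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("sequence of ", ids[bad][1],
         " contains characters outside {A,C,G,T,N}")
  }
  component_id <- ifelse(
    grepl(isoform_sep, ids, fixed = TRUE),
    sub(paste0(.escape_fixed(isoform_sep), ".*$"), "", ids),
    ids
  )
  data.frame(transcript_id = unname(ids), component_id = component_id,
             sequence = unname(sequence), stringsAsFactors = FALSE)
}

.escape_fixed <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of nucleotide or protein sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read biallelic variant sites with per-species allele counts
#'
#' Accepts either a VCF (v4.2, two samples, with a per-sample `AD`
#' allele-depth FORMAT field) or a tab-separated table with columns
#' `transcript pos ref alt refA altA refB altB qual` where `pos` is
#' 0-based. VCF positions are 1-based and converted to 0-based internally.
#' Only biallelic single-nucleotide records are kept; multiallelic and
#' indel records are counted in the `n_excluded` attribute, not silently
#' dropped.
#'
#' @param path Input file; format is inferred from the extension unless
#'   `format` is given.
#' @param species_labels Length-2 character vector naming the two species
#'   samples, in the column order of the table / the sample order of the
#'   VCF. For a VCF the labels must match the sample names.
#' @param format `"auto"`, `"vcf"` or `"tsv"`.
#' @return A data.frame of class `variant_table` with columns
#'   `transcript_id`, `position` (0-based), `ref`, `alt`, `ref_a`, `alt_a`,
#'   `ref_b`, `alt_b`, `qual`; attributes `species` (the labels) and
#'   `n_excluded` (multiallelic/indel records dropped).
#' @export
read_variants <- function(path, species_labels = c("A", "B"),
                          format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (length(species_labels) != 2) {
    stop("species_labels must have length 2")
  }
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") .read_variants_vcf(path, species_labels)
  else .read_variants_tsv(path, species_labels)
}

.variant_table <- function(df, species, n_excluded) {
  rownames(df) <- NULL
  attr(df, "species") <- species
  attr(df, "n_excluded") <- n_excluded
  class(df) <- c("variant_table", "data.frame")
  df
}

.read_variants_tsv <- function(path, species) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.tsv_cols, names(df))
  if (length(missing_cols)) {
    stop("variant TSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  snv <- nchar(df$ref) == 1 & nchar(df$alt) == 1 &
    df$ref %in% NUCS & df$alt %in% NUCS & df$ref != df$alt
  n_excluded <- sum(!snv)
  df <- df[snv, , drop = FALSE]
  out <- data.frame(
    transcript_id = df$transcript,
    position = as.integer(df$pos),
    ref = df$ref, alt = df$alt,
    ref_a = as.integer(df$refA), alt_a = as.integer(df$altA),
    ref_b = as.integer(df$refB), alt_b = as.integer(df$altB),
    qual = as.numeric(df$qual),
    stringsAsFactors = FALSE
  )
  .variant_table(out, species, n_excluded)
}

.read_variants_vcf <- function(path, species) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_mat <- vcfR::getFIX(vcf)
  if (is.null(dim(fix_mat))) fix_mat <- t(fix_mat)  # single-record VCF
  fix <- as.data.frame(fix_mat, stringsAsFactors = FALSE)
  if (!"AD" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID) {
    stop("VCF lacks the per-sample AD (allele depth) FORMAT field")
  }
  samples <- colnames(vcf@gt)[-1]
  if (!all(species %in% samples)) {
    stop("species label(s) not found among VCF samples: ",
         paste(setdiff(species, samples), collapse = ", "))
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  keep <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% NUCS & fix$ALT %in% NUCS & !grepl(",", fix$ALT)
  keep[is.na(keep)] <- FALSE
  n_excluded <- sum(!keep)
  parse_ad <- function(x, which) {
    parts <- strsplit(ifelse(is.na(x), "0,0", x), ",", fixed = TRUE)
    vapply(parts, function(p) as.integer(p[which]), integer(1))
  }
  ad_a <- ad[, species[1]]
  ad_b <- ad[, species[2]]
  out <- data.frame(
    transcript_id = fix$CHROM[keep],
    position = as.integer(fix$POS[keep]) - 1L,
    ref = fix$REF[keep], alt = fix$ALT[keep],
    ref_a = parse_ad(ad_a[keep], 1), alt_a = parse_ad(ad_a[keep], 2),
    ref_b = parse_ad(ad_b[keep], 1), alt_b = parse_ad(ad_b[keep], 2),
    qual = suppressWarnings(as.numeric(fix$QUAL[keep])),
    stringsAsFactors = FALSE
  )
  .variant_table(out, species, n_excluded)
}

#' Write a variant table
#'
#' `format = "tsv"` writes the flat 0-based table read back by
#' [read_variants()]; `format = "vcf"` writes a minimal VCF v4.2 with
#' 1-based positions and per-sample `AD:DP` fields.
#'
#' @param variants A `variant_table` (see [read_variants()]).
#' @param path Output file.
#' @param format `"tsv"` or `"vcf"`.
#' @export
write_variants <- function(variants, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  species <- attr(variants, "species")
  if (is.null(species)) species <- c("A", "B")
  if (format == "tsv") {
    out <- data.frame(
      transcript = variants$transcript_id, pos = variants$position,
      ref = variants$ref, alt = variants$alt,
      refA = variants$ref_a, altA = variants$alt_a,
      refB = variants$ref_b, altB = variants$alt_b,
      qual = variants$qual, stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=divscreen",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", species), collapse = "\t")
    )
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t%s\t.\t.\tAD:DP\t%d,%d:%d\t%d,%d:%d",
      variants$transcript_id, variants$position + 1L,
      variants$ref, variants$alt, format(variants$qual, trim = TRUE),
      variants$ref_a, variants$alt_a, variants$ref_a + variants$alt_a,
      variants$ref_b, variants$alt_b, variants$ref_b + variants$alt_b
    )
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Write a candidate report
#'
#' Rows are sorted by decreasing D-bar with ties broken by unigene id, so
#' re-running on identical input yields byte-identical output.
#'
#' @param records A data.frame with at least `component_id` and `dbar`
#'   columns (see [assemble_candidates()]).
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (nrow(records)) {
    records <- records[order(-records$dbar, records$component_id), ,
                       drop = FALSE]
    rownames(records) <- NULL
  }
  if (format == "tsv") {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
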