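# Interspecific differentiation: per-SNP index D, per-unigene mean D-bar,
# selection of divergent unigenes, Nei genetic identity/distance over SNP
# sets, and a descriptive normality check of the D-bar distribution.

#' Per-SNP interspecific differentiation index D
#'
#' D = |F_A - F_B|, the absolute difference of the alt-allele frequencies
#' of the two species. Only `d_callable` sites (see [classify_sharing()])
#' receive a value; other sites get `NA` and are counted in the
#' `n_excluded` attribute.
#'
#' @param variants Output of [classify_sharing()].
#' @return The input with a numeric `D` column.
#' @export
compute_D <- function(variants) {
  v <- variants
  v$D <- ifelse(v$d_callable, abs(v$f_a - v$f_b), NA_real_)
  attr(v, "n_excluded_from_D") <- sum(!v$d_callable)
  v
}

#' Per-unigene mean differentiation D-bar
#'
#' D-bar is the arithmetic mean of D over the callable SNPs of a unigene.
#' Only SNPs on the chosen (longest) transcript of each component enter;
#' variants on discarded isoforms are dropped. Unigenes with zero callable
#' SNPs are omitted.
#'
#' @param variants Output of [compute_D()].
#' @param catalog A `unigene_catalog` ([dedup_longest_isoform()]).
#' @return A data.frame `component_id`, `transcript_id`, `n_snps`, `dbar`,
#'   `d_min`, `d_max`, ordered by `component_id`.
#' @export
compute_Dbar <- function(variants, catalog) {
  keep <- variants$transcript_id %in% catalog$transcript_id &
    !is.na(variants$D)
  v <- variants[keep, , drop = FALSE]
  comp <- catalog$component_id[match(v$transcript_id,
                                     catalog$transcript_id)]
  if (nrow(v) == 0) {
    return(data.frame(component_id = character(),
                      transcript_id = character(), n_snps = integer(),
                      dbar = numeric(), d_min = numeric(),
                      d_max = numeric(), stringsAsFactors = FALSE))
  }
  agg <- tapply(v$D, comp, function(d) {
    c(n = length(d), dbar = mean(d), d_min = min(d), d_max = max(d))
  })
  m <- do.call(rbind, agg)
  out <- data.frame(
    component_id = names(agg),
    transcript_id = catalog$transcript_id[match(names(agg),
                                                catalog$component_id)],
    n_snps = as.integer(m[, "n"]),
    dbar = m[, "dbar"], d_min = m[, "d_min"], d_max = m[, "d_max"],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$component_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select divergent unigenes and highly differentiated SNPs
#'
#' Thresholds are inclusive. Also returns the D-bar histogram in
#' right-closed bins of width 0.05 (the 0 bin is `[0, 0.05]`, then
#' `(0.05, 0.10]`, ...).
#'
#' @param records Output of [compute_Dbar()].
#' @param variants Output of [compute_D()].
#' @param config A [pipeline_config()].
#' @return A list with `unigenes` (records with `dbar >= dbar_threshold`),
#'   `snps` (variant rows with `D >= d_threshold`), and `histogram`
#'   (data.frame `bin`, `count`).
#' @export
select_divergent <- function(records, variants,
                             config = pipeline_config()) {
  sel_u <- records[records$dbar >= config$dbar_threshold, , drop = FALSE]
  sel_s <- variants[!is.na(variants$D) &
                      variants$D >= config$d_threshold, , drop = FALSE]
  breaks <- seq(0, 1, by = 0.05)
  bins <- cut(records$dbar, breaks = breaks, include.lowest = TRUE,
              right = TRUE)
  hist <- as.data.frame(table(bins), stringsAsFactors = FALSE)
  names(hist) <- c("bin", "count")
  list(unigenes = sel_u, snps = sel_s, histogram = hist)
}

#' Nei genetic identity and distance over a SNP set
#'
#' Treats every SNP as a biallelic locus with allele-frequency vectors
#' x = (F_A, 1 - F_A) and y = (F_B, 1 - F_B). The per-locus normalized
#' identity is I_l = (x . y) / sqrt((x . x)(y . y)). Because the printed
#' summaries in the population-genetics literature mix two conventions,
#' both are returned: `distance_of_mean` = -ln(mean I_l) (Nei's standard
#' ratio-of-means form collapses to this for loci of equal weight) and
#' `mean_of_distances`, the mean of per-locus -ln(I_l). Loci with I_l = 0
#' (orthogonal profiles, i.e. oppositely fixed) are excluded from the
#' log-mean and counted in `n_zero_identity`; by Jensen's inequality
#' `distance_of_mean <= mean_of_distances` whenever both are defined.
#'
#' @param f_a,f_b Numeric vectors of per-SNP alt-allele frequencies.
#' @return A list of class `nei_result`: `mean_identity`,
#'   `distance_of_mean`, `mean_of_distances`, `n_loci`, `n_zero_identity`.
#' @export
nei_identity_distance <- function(f_a, f_b) {
  ok <- !is.na(f_a) & !is.na(f_b)
  f_a <- f_a[ok]
  f_b <- f_b[ok]
  if (length(f_a) == 0) stop("empty SNP set: Nei identity undefined")
  num <- f_a * f_b + (1 - f_a) * (1 - f_b)
  den <- sqrt((f_a^2 + (1 - f_a)^2) * (f_b^2 + (1 - f_b)^2))
  i_l <- num / den
  mean_i <- mean(i_l)
  zero <- i_l <= 0
  structure(
    list(mean_identity = mean_i,
         distance_of_mean = if (mean_i > 0) -log(mean_i) else NA_real_,
         mean_of_distances = if (any(!zero)) mean(-log(i_l[!zero]))
                             else NA_real_,
         n_loci = length(i_l),
         n_zero_identity = sum(zero)),
    class = "nei_result"
  )
}

#' @export
print.nei_result <- function(x, ...) {
  cat(sprintf(paste0("Nei identity/distance over %d loci\n",
                     "  mean identity      I = %.4f\n",
                     "  -ln(mean I)          = %.4f\n",
                     "  mean of -ln(I_l)     = %.4f (%d zero-identity loci",
                     " excluded)\n"),
              x$n_loci, x$mean_identity, x$distance_of_mean,
              x$mean_of_distances, x$n_zero_identity))
  invisible(x)
}

#' Shapiro-Wilk normality check of the D-bar distribution
#'
#' A thin, descriptive wrapper: no decision logic is attached to the
#' result. Requires 3 to 5000 observations (the test's implementation
#' limit); larger inputs are an error, as is a constant vector.
#'
#' @param dbar_values Numeric vector of per-unigene D-bar values.
#' @return A list `W`, `p_value`.
#' @export
normality_test <- function(dbar_values) {
  x <- dbar_values[!is.na(dbar_values)]
  if (length(x) < 3) stop("normality test requires at least 3 values")
  if (stats::sd(x) == 0) stop("normality test undefined for constant input")
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p_value = ht$p.value)
}
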