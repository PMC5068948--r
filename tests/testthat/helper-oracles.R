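# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms (recursion, exhaustive
# enumeration, exact convolution) than the production code paths.

# Recursive enumeration of all minimal mutational pathways between two
# codons; pathways through stop codons are excluded, steps are classified
# by translating with Biostrings' genetic code directly.
oracle_path_counts <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  x1 <- strsplit(c1, "")[[1]]
  x2 <- strsplit(c2, "")[[1]]
  paths <- list()
  recurse <- function(cur, remaining, sd, nd) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- x2[p]
      aa_new <- gc[[paste(nxt, collapse = "")]]
      if (aa_new == "*") next
      aa_old <- gc[[paste(cur, collapse = "")]]
      syn <- aa_new == aa_old
      recurse(nxt, setdiff(remaining, p), sd + syn, nd + !syn)
    }
  }
  recurse(x1, which(x1 != x2), 0L, 0L)
  if (!length(paths)) return(NULL)
  m <- do.call(rbind, paths)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

# Exhaustive-optimum global alignment score with affine gap cost
# open + extend * length, plain recursion (sequences of length <= 8).
oracle_align_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, B[av[i], bv[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(av)) {  # gap in b
      cost <- gap_extend + if (state == "gb") 0 else gap_open
      best <- max(best, -cost + rec(i + 1, j, "gb"))
    }
    if (j <= length(bv)) {  # gap in a
      cost <- gap_extend + if (state == "ga") 0 else gap_open
      best <- max(best, -cost + rec(i, j + 1, "ga"))
    }
    best
  }
  rec(1, 1, "m")
}

# Exact E|X/n - Y/n| for X, Y ~ Binomial(n, p) by convolution.
oracle_mean_abs_freq_diff <- function(n, p) {
  k <- 0:n
  d <- stats::dbinom(k, n, p)
  sum(outer(d, d) * abs(outer(k, k, "-")) / n)
}

# Direct re-application of the three SNP retention rules, row by row.
oracle_filter <- function(v, cfg) {
  pass <- function(maf, depth, qual) {
    !is.na(maf) && maf >= cfg$maf_min && qual >= cfg$qual_min &&
      depth >= cfg$depth_min
  }
  data.frame(
    pass_a = vapply(seq_len(nrow(v)), function(i) {
      pass(v$maf_a[i], v$depth_a[i], v$qual[i])
    }, logical(1)),
    pass_b = vapply(seq_len(nrow(v)), function(i) {
      pass(v$maf_b[i], v$depth_b[i], v$qual[i])
    }, logical(1))
  )
}
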