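#' Pipeline configuration
#'
#' Bundles the thresholds of the candidate-gene screen. Defaults follow the
#' screening rules for closely related tephritid species pairs: a site is a
#' SNP within a species when its minor allele frequency is at least 0.05,
#' its Phred-scaled quality at least 30 and its read depth at least 100;
#' unigenes with mean interspecific differentiation of at least 0.94 are
#' selected as divergent; genes with ingroup Ka/Ks >= 0.5 but outgroup
#' Ka/Ks < 0.5 pass the branch rule; at least three highly differentiated
#' SNPs in one unigene trigger the multi-SNP rule.
#'
#' @param maf_min Minimum per-species minor allele frequency (inclusive).
#' @param qual_min Minimum Phred-scaled site quality (inclusive).
#' @param depth_min Minimum per-species read depth (inclusive).
#' @param dbar_threshold Unigene-level differentiation threshold on D-bar.
#' @param d_threshold SNP-level differentiation threshold on D.
#' @param kaks_candidate_min Minimum ingroup-pair Ka/Ks for a candidate.
#' @param kaks_outgroup_max Outgroup-branch Ka/Ks must be strictly below
#'   this for the branch rule.
#' @param min_orf_residues Minimum predicted protein length, in residues.
#' @param min_snps_for_multi_snp_rule Number of highly differentiated SNPs
#'   that makes a unigene a candidate on its own.
#' @param require_other_species_coverage A SNP is called species-specific
#'   only when the other species has evaluable depth at the site; set
#'   `FALSE` to drop that requirement.
#' @param rescue_fixed_differences Oppositely fixed sites (frequencies near
#'   1 vs 0) have within-species MAF below `maf_min` in both species; when
#'   `TRUE` they remain usable for D despite failing the per-species MAF
#'   rule, provided depth and quality pass in both species.
#' @param d_universe Which callable sites enter the D / D-bar computation:
#'   `"all"` uses every site with defined frequencies in both species that
#'   is a SNP in at least one species (plus rescued fixed differences);
#'   `"shared"` restricts to sites polymorphic in both species (plus
#'   rescued fixed differences).
#' @param rng_seed Integer seed recorded with the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(maf_min = 0.05,
                            qual_min = 30,
                            depth_min = 100,
                            dbar_threshold = 0.94,
                            d_threshold = 0.94,
                            kaks_candidate_min = 0.5,
                            kaks_outgroup_max = 0.5,
                            min_orf_residues = 100,
                            min_snps_for_multi_snp_rule = 3,
                            require_other_species_coverage = TRUE,
                            rescue_fixed_differences = TRUE,
                            d_universe = c("all", "shared"),
                            rng_seed = 1L) {
  d_universe <- match.arg(d_universe)
  cfg <- list(
    maf_min = maf_min,
    qual_min = qual_min,
    depth_min = depth_min,
    dbar_threshold = dbar_threshold,
    d_threshold = d_threshold,
    kaks_candidate_min = kaks_candidate_min,
    kaks_outgroup_max = kaks_outgroup_max,
    min_orf_residues = min_orf_residues,
    min_snps_for_multi_snp_rule = min_snps_for_multi_snp_rule,
    require_other_species_coverage = require_other_species_coverage,
    rescue_fixed_differences = rescue_fixed_differences,
    d_universe = d_universe,
    rng_seed = as.integer(rng_seed)
  )
  num <- c("maf_min", "qual_min", "depth_min", "dbar_threshold",
           "d_threshold", "kaks_candidate_min", "kaks_outgroup_max",
           "min_orf_residues", "min_snps_for_multi_snp_rule")
  for (nm in num) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] < 0) {
      stop("config field '", nm, "' must be a single non-negative number")
    }
  }
  if (cfg$maf_min > 0.5) stop("maf_min must not exceed 0.5")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error, missing keys take the defaults.
#'
#' @param path Path to a YAML file of flat key-value pairs.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (nm in setdiff(names(x), NULL)) {
    cat(sprintf("  %-32s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
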