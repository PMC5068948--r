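---
title: "Screening two-species transcriptomes for candidate speciation genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening two-species transcriptomes for candidate speciation genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscreen)
```

## The problem

Closely related species that still exchange migrants — for example sister
species of tephritid fruit flies such as *Anastrepha fraterculus* and
*A. obliqua* — are often morphologically near-identical, yet a small set of
genes can carry fixed or nearly fixed differences between them. Finding
those genes from transcriptome data serves two purposes: the fixed sites
are diagnostic markers, and genes accumulating fixed differences despite
ongoing gene flow are candidates for involvement in the differentiation
process itself.

`divscreen` implements that screen as a reusable, testable pipeline. The
inputs are per-site allele counts of the two species over a shared
reference transcriptome (VCF with allele-depth fields, or a flat table),
the transcript sequences with their isoform-to-component map, and coding
sequences of an outgroup species. Because real read data are not needed to
exercise any stage, the package also ships a seeded generator that plants
every signal the screen looks for and records the truth.

## The screening statistics

**Unigene reduction.** De novo assemblies report several isoforms per
component; isoforms share exonic sequence, so SNPs would be counted
repeatedly. Only the longest transcript of each component (the *unigene*)
is analysed; ties are broken by the lexicographically smallest transcript
id so the reduction is deterministic.

**SNP filters.** Within each species a site is accepted as a SNP when its
minor allele frequency is at least `maf_min` (default 0.05), the
Phred-scaled site quality at least `qual_min` (default 30) and the read
depth at least `depth_min` (default 100). All three thresholds are
inclusive. Sites are then partitioned exactly into `specificA`,
`specificB`, `common`, `uncallable` (inadequate depth in either species —
never counted as species-specific) and `filtered`.

**Differentiation indices.** For a site with alt-allele frequencies
$F_A$ and $F_B$ in the two species, the interspecific differentiation
index is $D = |F_A - F_B|$, and per unigene $\bar D$ is the arithmetic
mean of $D$ over its callable SNPs. Unigenes with
$\bar D \ge$ `dbar_threshold` (default 0.94) form the divergent set; SNPs
with $D \ge$ `d_threshold` are reported individually. A Shapiro–Wilk test
of the $\bar D$ distribution is attached descriptively.

Two decisions here were genuinely open:

* *Fixed differences versus the MAF rule.* A site fixed for alternative
  alleles ($F_A = 1$, $F_B = 0$) has within-species MAF 0 in both species
  and would fail the per-species MAF filter, yet such sites are precisely
  what the screen is after. By default (`rescue_fixed_differences = TRUE`)
  oppositely fixed sites that pass depth and quality in both species stay
  usable for $D$. The flag makes the alternative reading available.
* *The universe of D.* `d_universe = "all"` (default) computes $D$ on all
  sites that are a SNP in at least one species; `"shared"` restricts to
  sites polymorphic in both. Published summaries exist under both
  conventions, so both are supported rather than resolved.

**Nei identity and distance.** Each SNP is treated as a biallelic locus
with frequency vectors $x = (F_A, 1-F_A)$, $y = (F_B, 1-F_B)$ and
per-locus normalized identity
$I_l = x\cdot y / \sqrt{(x\cdot x)(y\cdot y)}$. Printed pairs of
identity/distance values in the literature are not always consistent with
a single convention, so both are returned: $-\ln(\text{mean } I_l)$ and
the mean of per-locus $-\ln I_l$ (zero-identity loci excluded from the
log and counted). Jensen's inequality guarantees the first never exceeds
the second; the test suite asserts this on every random dataset it draws.

**The Ka/Ks branch rule.** Divergent unigenes are submitted to an
ortholog screen: six-frame ORF prediction keeps coding sequences of at
least `min_orf_residues` (default 100) residues; reciprocal best hits
under global protein alignment (Needleman–Wunsch, BLOSUM62, affine gaps
11/1) identify orthologs between the two species and against the
outgroup, with ties for best conservatively unpaired; aligned proteins
are back-translated onto their source codons; and each pair receives an
NG86 estimate. A gene passes the branch rule when the ingroup-pair ratio
is at least `kaks_candidate_min` (default 0.5) while **both**
ingroup-versus-outgroup ratios are strictly below `kaks_outgroup_max`
(default 0.5) — elevated exchange only on the branch separating the
sister pair. A 0.5 cutoff (rather than the textbook 1.0) reflects that
positively selected regions are usually embedded in conserved domains
that drag the gene-wide ratio down, especially for recently diverged
species.

**Candidates.** The final report unions two reasons over the divergent
set: `multi_snp` (at least `min_snps_for_multi_snp_rule` = 3 member SNPs
with $D$ at or above the threshold) and `high_kaks` (the branch rule).
Every record carries its evidence: D-bar, SNP counts, the three pairwise
ratios, and per-SNP effect typing (noncoding / synonymous /
nonsynonymous, by substituting the alt allele into its codon
strand-aware).

## NG86 details and numerical choices

Sites are counted fractionally: at each codon position the synonymous
fraction of the three possible changes, averaged over the two sequences;
changes creating stop codons count as nonsynonymous, which keeps
$S + N = 3 \times$ codons exactly (asserted in the tests). Observed
differences average, with equal weight, over all minimal mutational
pathways between differing codons; pathways through stop codons are
excluded and the average renormalized (under the standard code every
sense-codon pair retains at least one admissible pathway — verified
exhaustively). Proportions are corrected with Jukes–Cantor,
$d = -\tfrac34\ln(1-\tfrac43 p)$; $p \ge 3/4$ cannot be corrected and
flags the estimate `jc_saturated`. $K_s = 0$ with $K_a > 0$ yields an
undefined-large ratio (`Inf`) and the `ks_zero` flag; flagged genes never
enter the clean candidate list, only a flagged list. Alignment columns
containing gaps, ambiguous bases or stop codons are skipped and counted.

Codon-usage bias uses Wright's effective number of codons,
$N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$, with the
plug-in homozygosity $F = \sum_i p_i^2$ per synonymous family by default.
The plug-in form keeps $N_c$ inside $[20, 61]$ with the exact endpoints
at one-codon-per-amino-acid and uniform usage; the small-sample corrected
estimator $(nF-1)/(n-1)$ is available via `bias_correct = TRUE` but is
unbounded above on near-uniform small samples. A missing three-fold
family (isoleucine only) is imputed as the mean of the two- and four-fold
averages, the standard fallback.

## What the generator emulates — and what it does not

`simulation_params()` describes a dataset by its planted structure:

* unigenes whose isoforms share a common exonic core (5' UTR, a planted
  ORF, 3' UTR) plus random flanks, so longest-isoform reduction is
  meaningful and the planted ORF is recoverable;
* three SNP classes — shared polymorphic (both true frequencies uniform
  on (0.05, 0.95)), species-specific (one frequency drawn, the other 0)
  and oppositely fixed (1 versus 0) — with per-species depths drawn from
  a negative binomial (default mean 300, dispersion 3; overdispersed
  RNA-seq-like coverage that deliberately stresses the depth filter) and
  alt counts drawn binomially at the true frequency. The default class
  sizes (5337 specific at a 63:37 split between species, 319 shared, 11
  fixed on 8 dedicated unigenes) keep the relative proportions observed
  in a published two-species tephritid head-transcriptome screen, scaled
  down by roughly a factor of 20 so a full run takes seconds;
* ortholog CDS triples evolved from the planted ORF as common ancestor
  under a mutation–acceptance process: proposals are uniform
  single-nucleotide changes, stop-creating proposals are rejected,
  synonymous proposals are accepted with probability 1 and nonsynonymous
  with probability $\min(1, \omega)$ (roles reversed above 1). Branch
  lengths are expected substitutions per nucleotide site; the defaults
  ($t = 0.05$ between the sister species, 0.5 on the outgroup branch,
  outgroup $\omega = 0.1$) reproduce the magnitudes seen in published
  ortholog tables for this configuration — ingroup $K_s$ of a few
  percent, outgroup $K_s$ above 1. Per-gene ingroup $\omega$ defaults to
  a two-point mixture (7.5% of genes at 0.8, the rest at 0.15), matching
  the observed fraction of elevated-ratio genes.

Fixed differences are planted on unigenes disjoint from those receiving
polymorphic SNPs, so "the planted divergent set" is well defined for
recovery tests.

The generator does **not** emulate read-level artifacts (mapping error,
strand bias, indels), linked SNPs within a haplotype, expression-level
variation between libraries, within-species population structure (one
population per species, as in the motivating study design), or
transition/transversion and codon-frequency bias in the codon model.
Passing recovery tests therefore demonstrates correctness of the
estimators and rules under clean sampling noise, not robustness to
real-data pathologies.

## Problem sizes used by the automated checks

The test suite and the acceptance script size their simulations so a full
run stays light: the default-conditions dataset uses 600 unigenes and
about 5700 planted SNPs; exact fixed-difference recovery uses 2612
unigenes (164 fixed-difference, 2448 background) at per-species depth
$10^4$, where binomial noise cannot push a background unigene (true
$D \le 0.9$) across the 0.94 threshold; selection-pressure recovery uses
200 replicate genes of 300 codons per $\omega \in \{0.1, 0.5, 1.0\}$ and
classifies 100 genes each at $\omega = 0.2$ and $1.2$; estimator-versus-
oracle equivalence samples $10^4$ codon pairs against exhaustive pathway
enumeration.

## Known limitations

* NG86 is an approximate counting method; it ignores
  transition/transversion bias and unequal codon frequencies, and at high
  divergence the Jukes–Cantor correction saturates. Maximum-likelihood
  codon models and branch-site tests are out of scope.
* The Shapiro–Wilk wrapper subsamples to 5000 values (the test's
  implementation limit) on larger inputs.
* E-value-based ortholog screening against large databases is replaced by
  score-thresholded reciprocal best hits, appropriate at the scale of a
  selected gene set but not a substitute for a database search.
* `Inf` and `NaN` ratios are deliberate sentinel values; downstream
  consumers should branch on the `ks_zero`/`jc_saturated` flags rather
  than on the numbers.
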