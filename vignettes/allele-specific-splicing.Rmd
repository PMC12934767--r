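---
title: "Allele-specific alternative splicing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific alternative splicing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelesplice)
```

# The measurement

A heterozygous SNP expressed in mature mRNA splits a gene's reads into
two haplotype-resolved pools. If the SNP lies in an alternatively
spliced region and one haplotype includes that region more often, the
reference-allele ratio `R = ref / (ref + alt)` at the SNP departs from
what the same individual's constitutive exons show. That within-sample
contrast is the core of allele-specific alternative splicing (ASAS)
analysis: it controls for trans-acting and environmental influences
because both alleles share one cellular context.

`call_asas()` implements the contrast. For each sample and each
heterozygous SNP in an alternative region with at least `min_coverage`
(default 20) reads, it builds a 2x2 table from the SNP's
haplotype-oriented counts and the summed haplotype-oriented counts of
the gene's phased heterozygous constitutive SNPs, and applies a
two-sided Fisher's exact test. Orientation matters: without phase, the
allele labels of different constitutive SNPs cannot be aggregated
coherently, which is why unphased heterozygous constitutive SNPs are
excluded rather than guessed. P-values are BH-adjusted within each
sample, and significant SNP-event pairs become *tag SNPs*. An exact
test was chosen because per-sample counts are small; its known
limitation — it assumes binomial sampling within the sample — is
discussed under *Limitations*.

Genes with no usable constitutive SNP yield untestable records with a
reason code rather than errors; the same applies to low coverage and
homozygosity. HLA genes are dropped (`filter_hla()`) because their
polymorphism makes allelic alignment unreliable.

# Concordance scoring of candidate functional SNPs

A tag SNP marks an event but need not cause it. To nominate causal
(*functional*) candidates, every SNP in the same gene is scored against
the tag SNP across the cohort. With imbalance `d_i = 0.5 - R_i` at the
tag SNP in individual `i`:

* candidate heterozygous: `S_i = d_i^2 / 0.5^2` — a functional
  heterozygote should produce strong imbalance;
* candidate homozygous: `S_i = 1 - d_i^2 / 0.5^2` — a functional
  homozygote should leave the tag balanced;
* candidate equal to the tag SNP: the heterozygous branch, by
  definition.

The two branches are exact complements (`S_het + S_hom = 1` at equal
`d`), so the score is bounded in [0, 1] and a functional SNP pushes the
whole distribution toward 1.

**Null test.** The source method does not name a test statistic, so a
design choice was required. We permute the candidate's genotype labels
across individuals, keeping the imbalances fixed, and compare the
observed mean score to the permuted means, one-sided (functional SNPs
raise the mean) with an add-one pseudocount so p is never zero.
Individuals are sorted by (genotype, imbalance) before permuting, which
makes the p-value invariant to relabelling individuals. The mean was
preferred over a shape-aware statistic (the expected score distribution
can be bimodal) because it is monotone in the signal, cheap, and
calibrated; a shape statistic remains a possible refinement. One known
blind spot is intrinsic to label permutation: when every usable
individual is heterozygous at the candidate (e.g. the candidate *is*
the tag SNP, which is heterozygous in every testable sample), there is
nothing to permute and p = 1 is returned with a reason. Such candidates
are still recovered through their pairings with other tag SNPs of the
gene.

**Testability.** A candidate-tag pair is tested only if at least 10% of
usable individuals are heterozygous for the candidate (inclusive, "at
least") and the number of scores strictly exceeds 10% of the stratum
size ("exceeded"). BH adjustment is applied across all pairs within a
mode; strata smaller than 20 individuals are skipped with a warning,
mirroring the exclusion of very small clinical strata.

**Modes and disease specificity.** The scan runs on all samples or
restricted to AD or control samples. Tag SNPs are designated
cohort-wide; only the per-individual ratios and genotype pairings are
restricted per mode. This keeps the candidate universe identical across
modes, which `disease_specific_functional()` requires when it partitions
candidates testable in both groups into both / AD-only / control-only.
Had tags been re-discovered per mode, any AD-only effect would erase the
control-mode universe and the comparison would be impossible.

**Reporting.** Within a gene, candidates are ranked by smallest p, then
largest mean score, then smallest absolute distance to the exon, then
SNP id (`rank_candidates()`); the distance convention is negative
upstream of the exon start, positive downstream of the end, zero inside.
`distance_profile()` normalises observed candidate positions by the
positional distribution of all testable SNPs and resamples equally
sized testable sets (default 100) as a flatness control.

# Differential allelic imbalance between groups

Per-sample allelic counts are overdispersed relative to the binomial:
biological state and library effects vary across samples. We therefore
model a tag SNP's counts with a beta-binomial parameterised by mean
`mu` and intra-class correlation `rho` (`alpha = mu(1-rho)/rho`,
`beta = (1-mu)(1-rho)/rho`; `rho = 0` is the binomial limit, evaluated
exactly as such). `bb_lrt()` compares a pooled model against
group-specific `(mu, rho)` and refers `2(ll_A + ll_B - ll_0)` (floored
at zero) to a chi-square with 2 degrees of freedom. Group-specific
dispersion — hence 2 df rather than 1 — was chosen because disease can
plausibly alter variability as well as the mean.

`differential_scan()` tests each designated tag SNP with at least 5
tested measurements per group, and calls significance only when the
nominal p is at most 0.05 **and** the absolute difference in group mean
allelic ratios is at least 0.1. No multiplicity correction is applied;
the effect-size filter plays that role, since sub-0.1 shifts are within
experimental variability for this assay. Group means are unweighted
means of per-sample ratios so that deep samples do not dominate. The
"tag SNP in at least 5 samples per group" requirement is interpreted as
5 tested measurements per group for a SNP that is a designated tag
anywhere in the region; requiring *significant* calls in both groups
would make exactly the interesting (group-specific) events untestable.
Ratios are reference-allele based and are not re-oriented by the
functional allele; with a tag SNP in consistent LD with its functional
SNP the orientation is consistent across individuals, but for tags with
no such structure a sign-aware extension could gain power.

**Optimisation.** `bb_fit()` maximises the likelihood with a fixed,
deterministic multi-start scheme: the likelihood is screened on a grid
(`mu` in 0.1..0.9, `rho` in {0.001, 0.05, 0.2}) plus a method-of-moments
start, Nelder-Mead runs from the best starts on a logit scale, and a
closed-form binomial boundary candidate (`rho = 0`, pooled ratio)
competes with the interior optimum. Identical data give identical fits;
degenerate all-identical data short-circuit to `rho = 0` with `mu`
clamped into `(1e-6, 1-1e-6)`.

# Enrichment machinery

All empirical p-values use the add-one pseudocount
`(1 + #extreme) / (1 + B)`, so they are valid and bounded below by
`1/(B+1)`.

* `matched_background_sets()` matches each query gene on expression and
  length within ±10% (widened stepwise to ±25% when no match exists,
  then dropped with a warning), excludes ASAS genes, and samples
  without replacement within a set. The matching windows only behave as
  intended against a genome-scale universe: in a universe of a few
  thousand genes each query gene has a handful of eligible matches and
  the "10,000 sets" collapse onto near-copies. The bundled
  `simulate_gene_universe()` therefore defaults to 12,000 genes and a
  200-gene query — the realistic scale of an expressed genome and of an
  ASAS gene set.
* `empirical_term_enrichment()` compares per-term query counts to their
  distribution over the background sets. Because counts are integers,
  the empirical p is slightly conservative for small queries (ties
  inflate `#{>=}`); at the default query scale the null distribution is
  close to uniform, which the tests verify.
* `ld_overlap()` pairs query SNPs with GWAS SNPs sharing an LD block
  within a 200 kb window; unmapped SNPs become singleton blocks, and
  exact positional coincidence is flagged separately. LD blocks are a
  precomputed input: deriving them from genotype panels is out of
  scope. The GWAS significance filter (5e-8) is assumed applied to the
  association table upstream.
* `gwas_enrichment_score()` is the ratio of in-LD proportions; a zero
  background numerator gets a Haldane-style 0.5 added to all four cells
  for the score only (the Fisher test always uses raw counts). Trait
  categories are case-insensitive keyword matches with precedence
  AD > brain > immune for multi-category labels.
* `ks_pvalue_enrichment()` is one-sided toward smaller observed
  p-values by default (two-sided exposed);
  `resampled_effect_comparison()` and `resampling_fold_change()`
  compare observed values against pooled equal-size draws with rank-sum
  tests plus empirical percentiles/p-values, the latter defining fold
  change as observed median over the median of per-iteration medians
  (undefined and flagged when the null median is zero).
* Fisher's exact p-values throughout use the point-mass-inclusive
  two-sided rule (sum of table probabilities not exceeding the observed
  probability within a 1e-7 relative guard).

# 5' UTR and proteome analyses

Exons are classified against one representative transcript of their
gene — the flagged canonical transcript when it overlaps, else the
overlapping coding transcript with the longest CDS, else `NC_EXON` —
by largest base overlap among 5' UTR / CDS / 3' UTR spans, with ties
favouring the UTR classes the analysis is about. Classification against
a single representative rather than all transcripts is a documented
choice; it makes the call deterministic and matches how canonical
annotations are read in practice.

`compare_start_codons()` assigns transcripts to the inclusion side
(an exon matching the event interval exactly) or the skipping side
(consecutive exons joining the event's flanking boundaries), ignoring
and counting partial overlaps, and compares the genomic first base of
the start codon, strand-normalised. Each inclusion transcript gets a
verdict (`SAME` if any skipping transcript shares its start) plus an
event-level any-alternative flag; alternative starts are additionally
located relative to the event exon.

`mrna_protein_correlation()` computes per-gene Spearman correlations
between RPKM and protein abundance over shared samples, dropping
zero-RPKM samples per gene and requiring at least 10 usable pairs
(a guard against unstable small-n rank correlations; the threshold is a
package choice). BH FDR at 0.05; `correlated_fraction_test()` compares
the significantly correlated fraction between gene groups by Fisher
test.

# The synthetic cohort: what it emulates, and what not

`simulate_cohort()` generates the study conditions end to end. Per
gene, one functional SNP (allele frequency 0.3 by default) controls the
inclusion of the gene's cassette exon(s): the haplotype carrying the
alternative allele includes at `baseline_psi + delta_psi` (defaults
0.3 + 0.4), the other at `baseline_psi`; AD-labelled individuals add
`ad_specific_effect`. Inclusion levels are clamped into [0, 1] with the
clamping recorded in the truth table. Each alternative exon carries a
dedicated tag SNP in tight LD with the functional SNP (per-haplotype
flip probability `tag_ld_flip = 0.05`, i.e. r² near 0.8 as expected for
variants within a few hundred bases); consistent LD is what makes tag
ratios comparable across individuals, exactly as in real data.
Functional SNPs are exonic with probability 0.5 (then doubly usable as
tag SNPs) and otherwise intronic within 300 bp of the exon, exercising
the positional-bias analysis. Constitutive SNPs (4 per gene by default —
a multi-exon gene typically offers several expressed common SNPs, and
with fewer, a large fraction of individuals would have no heterozygous
constitutive background and be structurally untestable) have balanced
expected ratios.

Counts: coverage is Poisson with mean `mean_coverage` (60 by default)
for constitutive SNPs and `mean_coverage * (psi_h1 + psi_h2)` for
alternative-region SNPs — each haplotype contributes reads in
proportion to its inclusion. Reference counts are beta-binomial with
intra-class correlation `overdispersion` (default 0.01, a weak
technical overdispersion typical of allelic counts at this depth);
homozygous SNPs contribute all reads to their single allele and carry
no imbalance information but are emitted because the concordance
score's homozygous branch needs them. Individuals contribute
`samples_per_individual = 2` samples, as brain-bank donors contribute
multiple specimens. All coordinates are 0-based half-open internally;
the VCF writer/reader converts to and from 1-based positions.

What the generator does **not** emulate — and hence what passing tests
do and do not show about real data: no read-level artefacts (mapping
bias, double counting), no nonsense-mediated decay coupling allelic
ratios across a gene, no LD structure beyond the tag-functional pair,
no covariates (age, sex, ancestry, post-mortem interval), no junction
reads or PSI estimation, and one brain region rather than four.
Calibration and recovery results on the simulator demonstrate that the
statistics behave as designed under their own model assumptions, not
that those assumptions hold in any particular tissue.

# Problem sizes and numerical tolerances

The test suite and the acceptance script run deliberately scaled
simulation sizes chosen as the smallest that leave comfortable margins
around each property: 1,000 replicates for type-I calibration of the
LRT (30 samples per group at ~50x); cohorts of 150-200 individuals for
recovery of planted effects (20 seeds in the tests, 10 in the script);
2,000 matched background sets against the 12,000-gene universe for the
term-enrichment checks (the pipeline default remains 10,000); 100
resampled sets for positional-bias nulls. Exact-test and likelihood
implementations are compared against brute-force enumeration and
product-formula oracles at 1e-8; algebraic identities at 1e-12.

# Limitations

* The Fisher exact caller assumes binomial within-sample sampling. The
  simulator's default overdispersion (0.01) keeps the caller's null
  call rate comfortably under its bound, but strongly overdispersed
  data (rho above ~0.02 at 100x) would make the exact test
  anticonservative; a per-sample beta-binomial caller would be the
  natural extension.
* The permutation null cannot score a candidate whose usable
  individuals all share one genotype class (notably candidate = tag);
  such pairs return p = 1 with a reason rather than a guess.
* Allelic ratios are not re-oriented by functional allele before the
  group comparison; power is lost for tags in weak LD with their
  functional SNP.
* Intronic functional SNPs receive no RNA counts (they are genotype
  only), so the differential scan — which needs expressed tag SNPs —
  cannot see them directly; the disease-stratified concordance
  comparison exists precisely to cover that case.
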