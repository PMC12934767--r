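#' Specify a synthetic ASAS cohort
#'
#' Defines the generative parameters for [simulate_cohort()]: cohort size,
#' gene/event structure, the planted functional-SNP effect on exon inclusion,
#' sequencing depth, and the overdispersion of allelic counts. Defaults
#' describe a modestly sized brain-bank-style cohort with a strong planted
#' splicing effect.
#'
#' Each gene carries one planted functional SNP whose alternative allele
#' raises the inclusion level of the gene's cassette exon(s) by `delta_psi`
#' (plus `ad_specific_effect` in AD-labelled individuals). A dedicated tag
#' SNP inside each alternative exon is kept in tight linkage with the
#' functional SNP (`tag_ld_flip` is the per-haplotype allele flip
#' probability), so allelic read ratios at the tag SNP track the functional
#' genotype the way exonic reporters track nearby cis-regulatory variants.
#'
#' @param n_individuals Number of individuals (donors).
#' @param n_genes Number of simulated genes.
#' @param events_per_gene Alternative splicing events per gene.
#' @param functional_maf Minor allele frequency of the planted functional
#'   SNP, in (0, 0.5].
#' @param delta_psi Difference in exon inclusion between the two functional
#'   alleles, in \[0, 1\].
#' @param baseline_psi Inclusion level on the reference-allele haplotype,
#'   in (0, 1).
#' @param mean_coverage Expected read coverage per SNP (Poisson mean).
#' @param overdispersion Beta-binomial intra-class correlation rho of the
#'   allelic counts, in \[0, 0.9\].
#' @param constitutive_snps_per_gene Number of constitutive-exon SNPs per
#'   gene (balanced allelic ratios).
#' @param fraction_ad Proportion of individuals labelled AD, in \[0, 1\].
#' @param ad_specific_effect Additional inclusion difference applied only in
#'   AD-labelled individuals, in \[-1, 1\].
#' @param tag_ld_flip Per-haplotype probability that the tag-SNP allele
#'   disagrees with the functional-SNP allele, in \[0, 0.5\]. Small values
#'   mean tight LD.
#' @param samples_per_individual RNA-seq samples per individual (repeated
#'   sampling of the same donor, as in multi-specimen brain cohorts).
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   exactly.
#'
#' @return A validated `cohort_spec` object (a named list).
#' @seealso [simulate_cohort()], [write_cohort()]
#' @examples
#' cohort_spec(n_individuals = 20, n_genes = 2, seed = 1)
#' @export
cohort_spec <- function(n_individuals = 100,
                        n_genes = 10,
                        events_per_gene = 1,
                        functional_maf = 0.3,
                        delta_psi = 0.4,
                        baseline_psi = 0.3,
                        mean_coverage = 60,
                        overdispersion = 0.01,
                        constitutive_snps_per_gene = 4,
                        fraction_ad = 0.5,
                        ad_specific_effect = 0,
                        tag_ld_flip = 0.05,
                        samples_per_individual = 2,
                        seed = 1) {
  check_number(n_individuals, "n_individuals", lo = 1, integer = TRUE)
  check_number(n_genes, "n_genes", lo = 1, integer = TRUE)
  check_number(events_per_gene, "events_per_gene", lo = 0, integer = TRUE)
  check_number(functional_maf, "functional_maf", lo = 0, hi = 0.5, lo_open = TRUE)
  check_number(delta_psi, "delta_psi", lo = 0, hi = 1)
  check_number(baseline_psi, "baseline_psi", lo = 0, hi = 1,
               lo_open = TRUE, hi_open = TRUE)
  check_number(mean_coverage, "mean_coverage", lo = 0, lo_open = TRUE)
  check_number(overdispersion, "overdispersion", lo = 0, hi = 0.9)
  check_number(constitutive_snps_per_gene, "constitutive_snps_per_gene",
               lo = 1, integer = TRUE)
  check_number(fraction_ad, "fraction_ad", lo = 0, hi = 1)
  check_number(ad_specific_effect, "ad_specific_effect", lo = -1, hi = 1)
  check_number(tag_ld_flip, "tag_ld_flip", lo = 0, hi = 0.5)
  check_number(samples_per_individual, "samples_per_individual",
               lo = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)

  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_genes = as.integer(n_genes),
      events_per_gene = as.integer(events_per_gene),
      functional_maf = functional_maf,
      delta_psi = delta_psi,
      baseline_psi = baseline_psi,
      mean_coverage = mean_coverage,
      overdispersion = overdispersion,
      constitutive_snps_per_gene = as.integer(constitutive_snps_per_gene),
      fraction_ad = fraction_ad,
      ad_specific_effect = ad_specific_effect,
      tag_ld_flip = tag_ld_flip,
      samples_per_individual = as.integer(samples_per_individual),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
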