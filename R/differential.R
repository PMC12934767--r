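#' Differential allelic imbalance between disease groups
#'
#' For every designated tag SNP, compares its per-sample allelic counts
#' between AD and control samples with the beta-binomial likelihood-ratio
#' test ([bb_lrt()]). A SNP-region pair is testable when the SNP is a tag
#' SNP (a significant ASAS call in at least one sample of the region) and
#' has tested allelic measurements in at least `min_per_group` samples of
#' each group. Significance requires both a nominal p-value at most
#' `alpha` and an absolute difference in mean allelic ratios of at least
#' `delta_min`; no multiplicity correction is applied, the effect-size
#' filter taking its place. Group means are unweighted means of per-sample
#' ratios, so deep samples do not dominate.
#'
#' @param calls Per-sample calls from [call_asas()].
#' @param metadata Sample metadata with `sample_id`, `region`, `group`
#'   (`"AD"`/`"control"`).
#' @param min_per_group Minimum tested samples per group (default 5).
#' @param delta_min Minimum absolute difference in mean allelic ratios
#'   (default 0.1).
#' @param alpha Nominal p-value cutoff (default 0.05).
#' @return A tibble of class `differential_scan`, one row per testable
#'   (region, SNP, event): group sizes, group mean ratios, `delta`
#'   (absolute difference), `lrt_stat`, `p_value`, `significant`;
#'   untestable tag SNPs are reported with a `reason_code`.
#' @examples
#' spec <- cohort_spec(n_individuals = 40, n_genes = 2,
#'                     delta_psi = 0, ad_specific_effect = 0.3, seed = 2)
#' cohort <- simulate_cohort(spec)
#' calls <- call_asas(cohort$counts, cohort$genotypes, cohort$metadata)
#' differential_scan(calls, cohort$metadata)
#' @export
differential_scan <- function(calls, metadata, min_per_group = 5,
                              delta_min = 0.1, alpha = 0.05) {
  dat <- calls %>%
    left_join(select(metadata, "sample_id", "region", "group"),
              by = "sample_id")

  tag_keys <- dat %>%
    filter(.data$significant) %>%
    distinct(.data$region, .data$snp_id, .data$event_id, .data$gene_id)
  if (nrow(tag_keys) == 0) {
    return(empty_differential())
  }

  measured <- dat %>%
    filter(.data$tested) %>%
    semi_join(tag_keys, by = c("region", "snp_id", "event_id"))

  rows <- measured %>%
    group_by(.data$region, .data$snp_id, .data$event_id, .data$gene_id) %>%
    group_split() %>%
    purrr::map(function(g) {
      ad <- g %>% filter(.data$group == "AD")
      ct <- g %>% filter(.data$group == "control")
      base <- tibble(
        region = g$region[1], snp_id = g$snp_id[1],
        event_id = g$event_id[1], gene_id = g$gene_id[1],
        n_ad = nrow(ad), n_control = nrow(ct)
      )
      if (nrow(ad) < min_per_group || nrow(ct) < min_per_group) {
        return(base %>% mutate(
          mean_ad = NA_real_, mean_control = NA_real_, delta = NA_real_,
          lrt_stat = NA_real_, p_value = NA_real_, significant = FALSE,
          reason_code = "min_per_group"
        ))
      }
      lrt <- bb_lrt(ad$ref_count, ad$ref_count + ad$alt_count,
                    ct$ref_count, ct$ref_count + ct$alt_count)
      mean_ad <- mean(ad$ratio_alt_region)
      mean_ct <- mean(ct$ratio_alt_region)
      delta <- abs(mean_ad - mean_ct)
      base %>% mutate(
        mean_ad = mean_ad, mean_control = mean_ct, delta = delta,
        lrt_stat = lrt$statistic, p_value = lrt$p_value,
        significant = .data$p_value <= alpha & delta >= delta_min,
        reason_code = NA_character_
      )
    }) %>%
    bind_rows() %>%
    arrange(.data$region, .data$gene_id, .data$snp_id, .data$event_id)
  class(rows) <- c("differential_scan", class(rows))
  rows
}

empty_differential <- function() {
  out <- tibble(
    region = character(), snp_id = character(), event_id = character(),
    gene_id = character(), n_ad = integer(), n_control = integer(),
    mean_ad = numeric(), mean_control = numeric(), delta = numeric(),
    lrt_stat = numeric(), p_value = numeric(), significant = logical(),
    reason_code = character()
  )
  class(out) <- c("differential_scan", class(out))
  out
}

#' Disease-specific functional SNPs
#'
#' Partitions candidate functional SNPs into those called in both disease
#' groups, only in AD, or only in controls, restricted to candidates that
#' were genetically testable in both groups. Candidates testable in only
#' one group are excluded from every partition.
#'
#' @param scan_ad,scan_control `concordance_scan` tibbles from the AD and
#'   control modes, run on the same candidate universe.
#' @return A tibble (`candidate_snp_id`, `event_id`, `gene_id`, `set`)
#'   with `set` in `{"both", "AD_only", "control_only", "neither"}`.
#' @export
disease_specific_functional <- function(scan_ad, scan_control) {
  collapse <- function(scan, suffix) {
    scan %>%
      group_by(.data$candidate_snp_id, .data$event_id, .data$gene_id) %>%
      summarise(testable = any(.data$testable),
                significant = any(.data$significant), .groups = "drop") %>%
      rename(!!paste0("testable_", suffix) := "testable",
             !!paste0("significant_", suffix) := "significant")
  }
  inner_join(
    collapse(scan_ad, "ad"), collapse(scan_control, "control"),
    by = c("candidate_snp_id", "event_id", "gene_id")
  ) %>%
    filter(.data$testable_ad, .data$testable_control) %>%
    mutate(set = dplyr::case_when(
      .data$significant_ad & .data$significant_control ~ "both",
      .data$significant_ad ~ "AD_only",
      .data$significant_control ~ "control_only",
      TRUE ~ "neither"
    )) %>%
    select("candidate_snp_id", "event_id", "gene_id", "set")
}
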