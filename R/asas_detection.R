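#' Reference-allele ratio of an allelic count pair
#'
#' @param ref_count,alt_count Non-negative read counts. Vectorised.
#' @return `ref_count / (ref_count + alt_count)`.
#' @examples
#' allelic_ratio(30, 10) # 0.75
#' @export
allelic_ratio <- function(ref_count, alt_count) {
  if (any(ref_count < 0) || any(alt_count < 0)) {
    abort("counts must be non-negative")
  }
  total <- ref_count + alt_count
  if (any(total == 0)) {
    abort("ref_count + alt_count must be positive (SNP untestable)")
  }
  ref_count / total
}

#' Call allele-specific alternative splicing per sample
#'
#' For every heterozygous SNP in an alternatively spliced region, tests
#' whether its allelic ratio differs from the gene's constitutive
#' background in the same sample. The constitutive background is the
#' haplotype-oriented sum of counts over the gene's phased heterozygous
#' constitutive SNPs; the target SNP's counts are oriented the same way and
#' the two count pairs are compared with a two-sided Fisher's exact test.
#' P-values are Benjamini-Hochberg adjusted within each sample, and
#' significant SNP-event pairs are designated tag SNPs.
#'
#' @param counts Allelic count tibble with columns `sample_id`, `snp_id`,
#'   `chrom`, `pos`, `ref_count`, `alt_count`, `gene_id`, `region_class`
#'   (`"ALTERNATIVE"`/`"CONSTITUTIVE"`), `event_id` (present exactly for
#'   alternative-region rows).
#' @param genotypes Long phased genotype tibble (`individual_id`, `snp_id`,
#'   `a1`, `a2`) as produced by [simulate_cohort()] or [read_cohort()];
#'   haplotype alleles are 0 (reference) / 1 (alternative).
#' @param metadata Sample metadata linking `sample_id` to `individual_id`.
#' @param min_coverage Minimum total reads at a tested SNP (default 20).
#' @param fdr_threshold Within-sample BH FDR threshold for tag-SNP
#'   designation (default 0.05).
#' @return A tibble with one row per candidate (sample, SNP, event):
#'   ratios, Fisher p, FDR, `significant`, and a `reason_code` for
#'   untestable candidates (`"low_coverage"`, `"not_het"`,
#'   `"no_constitutive"`, `"unphased"`, `"zero_total"`). Class
#'   `asas_calls`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_individuals = 20, n_genes = 2, seed = 1))
#' calls <- call_asas(cohort$counts, cohort$genotypes, cohort$metadata)
#' dplyr::filter(calls, significant)
#' @export
call_asas <- function(counts, genotypes, metadata,
                      min_coverage = 20, fdr_threshold = 0.05) {
  stopifnot(all(c("sample_id", "snp_id", "ref_count", "alt_count",
                  "gene_id", "region_class") %in% names(counts)))

  dat <- counts %>%
    left_join(select(metadata, "sample_id", "individual_id"),
              by = "sample_id") %>%
    left_join(genotypes %>% select("individual_id", "snp_id", "a1", "a2"),
              by = c("individual_id", "snp_id")) %>%
    mutate(
      total = .data$ref_count + .data$alt_count,
      het = !is.na(.data$a1) & !is.na(.data$a2) & .data$a1 != .data$a2,
      phased = !is.na(.data$a1),
      # orient counts to (haplotype 1, haplotype 2)
      h1 = ifelse(.data$a1 == 0, .data$ref_count, .data$alt_count),
      h2 = ifelse(.data$a1 == 0, .data$alt_count, .data$ref_count)
    )

  const_agg <- dat %>%
    filter(.data$region_class == "CONSTITUTIVE", .data$het, .data$phased,
           .data$total > 0) %>%
    group_by(.data$sample_id, .data$gene_id) %>%
    summarise(const_h1 = sum(.data$h1), const_h2 = sum(.data$h2),
              n_const_snps = dplyr::n(), .groups = "drop")

  cand <- dat %>%
    filter(.data$region_class == "ALTERNATIVE") %>%
    left_join(const_agg, by = c("sample_id", "gene_id")) %>%
    mutate(
      reason_code = dplyr::case_when(
        !.data$phased ~ "no_phase",
        !.data$het ~ "not_het",
        .data$total == 0 ~ "zero_total",
        .data$total < min_coverage ~ "low_coverage",
        is.na(.data$n_const_snps) ~ "no_constitutive",
        TRUE ~ NA_character_
      ),
      tested = is.na(.data$reason_code)
    )

  tested <- cand %>% filter(.data$tested)
  if (nrow(tested) > 0) {
    tested <- tested %>%
      mutate(
        p_value = fisher2x2_p(.data$h1, .data$h2,
                              .data$const_h1, .data$const_h2)
      ) %>%
      group_by(.data$sample_id) %>%
      mutate(fdr = p.adjust(.data$p_value, method = "BH")) %>%
      ungroup() %>%
      mutate(significant = .data$fdr <= fdr_threshold)
  } else {
    tested <- tested %>%
      mutate(p_value = numeric(0), fdr = numeric(0),
             significant = logical(0))
  }

  out <- bind_rows(
    tested,
    cand %>% filter(!.data$tested) %>%
      mutate(p_value = NA_real_, fdr = NA_real_, significant = FALSE)
  ) %>%
    mutate(
      ratio_alt_region = ifelse(.data$total > 0,
                                .data$ref_count / .data$total, NA_real_),
      ratio_constitutive = ifelse(
        !is.na(.data$const_h1) & (.data$const_h1 + .data$const_h2) > 0,
        ifelse(.data$a1 == 0, .data$const_h1, .data$const_h2) /
          (.data$const_h1 + .data$const_h2),
        NA_real_
      )
    ) %>%
    select("sample_id", "individual_id", "snp_id", "event_id", "gene_id",
           "ref_count", "alt_count", "ratio_alt_region",
           "ratio_constitutive", "tested", "p_value", "fdr", "significant",
           "reason_code") %>%
    arrange(.data$sample_id, .data$gene_id, .data$snp_id, .data$event_id)

  class(out) <- c("asas_calls", class(out))
  out
}

#' Remove calls in HLA genes
#'
#' The classical HLA locus is highly polymorphic and prone to allelic
#' mapping artefacts, so calls in these genes are removed from downstream
#' analyses.
#'
#' @param calls A tag-SNP call tibble from [call_asas()].
#' @param hla_genes Character vector of gene identifiers to drop; defaults
#'   to the bundled classical HLA gene list.
#' @return The filtered calls; the number removed is reported via a message.
#' @export
filter_hla <- function(calls, hla_genes = hla_gene_default()) {
  n0 <- nrow(calls)
  out <- calls %>% filter(!(.data$gene_id %in% hla_genes))
  inform(sprintf("filter_hla: removed %d of %d calls", n0 - nrow(out), n0))
  out
}

#' Bundled classical HLA gene symbols
#' @return Character vector of HLA gene symbols.
#' @export
hla_gene_default <- function() {
  c("HLA-A", "HLA-B", "HLA-C", "HLA-E", "HLA-F", "HLA-G",
    "HLA-DRA", "HLA-DRB1", "HLA-DRB3", "HLA-DRB4", "HLA-DRB5",
    "HLA-DQA1", "HLA-DQA2", "HLA-DQB1", "HLA-DQB2",
    "HLA-DPA1", "HLA-DPB1", "HLA-DMA", "HLA-DMB", "HLA-DOA", "HLA-DOB")
}

#' Summarise ASAS calls across samples
#'
#' Aggregates per-sample tag-SNP calls into per-event tallies, event-type
#' proportions, and per-region sets of significant events.
#'
#' @param calls Calls from [call_asas()] (any number of samples), ideally
#'   with `region` attached; if absent, `metadata` supplies it.
#' @param events Event annotation tibble (`event_id`, `type`, ...).
#' @param metadata Optional sample metadata with `sample_id` and `region`.
#' @return A list of class `asas_event_summary`: `event_summary` (per
#'   event: samples tested/significant), `type_proportions` (per event
#'   type among significant events; proportions sum to 1), and
#'   `region_events` (named list of significant event-id sets per region).
#' @export
summarize_events <- function(calls, events, metadata = NULL) {
  if (!"region" %in% names(calls)) {
    if (!is.null(metadata)) {
      calls <- calls %>%
        left_join(select(metadata, "sample_id", "region"), by = "sample_id")
    } else {
      calls$region <- "all"
    }
  }
  event_summary <- calls %>%
    filter(!is.na(.data$event_id)) %>%
    group_by(.data$event_id, .data$gene_id) %>%
    summarise(
      n_samples_tested = dplyr::n_distinct(.data$sample_id[.data$tested]),
      n_samples_significant =
        dplyr::n_distinct(.data$sample_id[.data$significant]),
      .groups = "drop"
    ) %>%
    left_join(select(events, "event_id", "type"), by = "event_id")

  sig_events <- event_summary %>%
    filter(.data$n_samples_significant > 0)
  type_proportions <- sig_events %>%
    count(.data$type, name = "n_events") %>%
    mutate(proportion = .data$n_events / sum(.data$n_events))

  region_events <- calls %>%
    filter(.data$significant, !is.na(.data$event_id)) %>%
    distinct(.data$region, .data$event_id) %>%
    group_by(.data$region) %>%
    summarise(events = list(sort(unique(.data$event_id)))) %>%
    (function(d) setNames(d$events, d$region))

  structure(
    list(event_summary = event_summary,
         type_proportions = type_proportions,
         region_events = region_events),
    class = "asas_event_summary"
  )
}
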