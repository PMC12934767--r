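#' Allelic imbalance from an allelic ratio
#'
#' The imbalance of a tag SNP is its deviation from the balanced
#' expectation: `d = 0.5 - R`, where `R` is the reference-allele ratio.
#'
#' @param ratio Allelic ratio(s) in \[0, 1\].
#' @return Imbalance in \[-0.5, 0.5\].
#' @examples
#' allelic_imbalance(0.75) # -0.25
#' @export
allelic_imbalance <- function(ratio) {
  if (any(ratio < 0 | ratio > 1, na.rm = TRUE)) {
    abort("allelic ratios must lie in [0, 1]")
  }
  0.5 - ratio
}

#' Genotype-imbalance concordance score
#'
#' Scores how well a candidate SNP's genotype in one individual explains
#' the allelic imbalance `d` observed at a tag SNP: a heterozygous
#' functional candidate should produce a large imbalance
#' (`S = d^2 / 0.5^2`), a homozygous one a balanced ratio
#' (`S = 1 - d^2 / 0.5^2`). When the candidate is the tag SNP itself the
#' heterozygous branch applies.
#'
#' @param d Imbalance value(s) in \[-0.5, 0.5\].
#' @param genotype `"HET"` or `"HOM"` (recycled).
#' @return Score(s) in \[0, 1\].
#' @examples
#' concordance_score(0.3, "HET") # 0.36
#' concordance_score(0, "HOM")   # 1
#' @export
concordance_score <- function(d, genotype) {
  if (any(abs(d) > 0.5 + 1e-12, na.rm = TRUE)) {
    abort("imbalance values must lie in [-0.5, 0.5]")
  }
  genotype <- rep_len(genotype, length(d))
  if (!all(genotype %in% c("HET", "HOM"))) {
    abort("genotype must be 'HET' or 'HOM'")
  }
  s <- d^2 / 0.25
  ifelse(genotype == "HET", s, 1 - s)
}

#' Score one candidate-tag SNP pair across a cohort
#'
#' Computes per-individual imbalances `d_i` at the tag SNP and concordance
#' scores `S_i` under the candidate SNP's genotype, for every individual
#' with both a genotype call at the candidate and a testable tag ratio.
#'
#' @param candidate_snp_id,tag_snp_id SNP identifiers (may be equal).
#' @param genotypes Long phased genotype tibble.
#' @param tag_ratios Tibble (`individual_id`, `ratio`) of the tag SNP's
#'   per-individual allelic ratios.
#' @return A list of class `concordance_record`: per-individual tibble
#'   (`individual_id`, `genotype`, `d`, `s`), plus `n_het`, `n_total`,
#'   `n_missing_genotype` and `mean_si` (NA with `reason` when no usable
#'   individual exists).
#' @export
score_candidate <- function(candidate_snp_id, tag_snp_id, genotypes,
                            tag_ratios) {
  gt <- genotypes %>%
    filter(.data$snp_id == candidate_snp_id) %>%
    mutate(genotype = dplyr::case_when(
      is.na(.data$a1) | is.na(.data$a2) ~ NA_character_,
      .data$a1 != .data$a2 ~ "HET",
      TRUE ~ "HOM"
    )) %>%
    select("individual_id", "genotype")

  dat <- tag_ratios %>%
    filter(!is.na(.data$ratio)) %>%
    inner_join(gt, by = "individual_id")
  n_missing <- sum(is.na(dat$genotype))
  dat <- dat %>% filter(!is.na(.data$genotype))

  if (nrow(dat) == 0) {
    return(structure(
      list(candidate_snp_id = candidate_snp_id, tag_snp_id = tag_snp_id,
           individuals = tibble(individual_id = character(),
                                genotype = character(),
                                d = numeric(), s = numeric()),
           n_het = 0L, n_total = 0L, n_missing_genotype = n_missing,
           mean_si = NA_real_, reason = "no_usable_individuals"),
      class = "concordance_record"
    ))
  }

  dat <- dat %>%
    mutate(
      d = allelic_imbalance(.data$ratio),
      # candidate == tag: the heterozygous branch applies by definition
      genotype = if (candidate_snp_id == tag_snp_id) "HET" else .data$genotype,
      s = concordance_score(.data$d, .data$genotype)
    ) %>%
    arrange(.data$individual_id)

  structure(
    list(candidate_snp_id = candidate_snp_id, tag_snp_id = tag_snp_id,
         individuals = dat %>% select("individual_id", "genotype", "d", "s"),
         n_het = sum(dat$genotype == "HET"),
         n_total = nrow(dat),
         n_missing_genotype = n_missing,
         mean_si = mean(dat$s), reason = NA_character_),
    class = "concordance_record"
  )
}

#' Testability filter for a concordance record
#'
#' A candidate-tag pair is testable when at least 10% of usable
#' individuals are heterozygous for the candidate (inclusive bound) and
#' the number of concordance scores strictly exceeds 10% of the stratum
#' size.
#'
#' @param record A `concordance_record` from [score_candidate()].
#' @param cohort_size Number of individuals in the stratum being analysed.
#' @param het_fraction,sample_fraction Threshold fractions (defaults 0.10).
#' @return A list `(pass, reason)`.
#' @export
concordance_testability <- function(record, cohort_size,
                                    het_fraction = 0.10,
                                    sample_fraction = 0.10) {
  if (record$n_total == 0) {
    return(list(pass = FALSE, reason = "no_usable_individuals"))
  }
  if (record$n_het < het_fraction * record$n_total) {
    return(list(pass = FALSE, reason = "het_fraction"))
  }
  if (!(record$n_total > sample_fraction * cohort_size)) {
    return(list(pass = FALSE, reason = "sample_fraction"))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Permutation test for a concordance record
#'
#' Tests whether the observed mean concordance score is higher than
#' expected by permuting the candidate's genotype labels across
#' individuals (the imbalances `d_i` stay fixed). One-sided with an
#' add-one pseudocount, so p is never exactly zero. Individuals are
#' sorted by (genotype, d) before permuting, making the p-value invariant
#' to relabelling of individual identifiers.
#'
#' @param record A `concordance_record`.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Integer seed (required for reproducibility).
#' @return A list `(p_value, observed, n_permutations, reason)`.
#' @export
concordance_test <- function(record, n_permutations = 1000, seed) {
  dat <- record$individuals
  if (nrow(dat) == 0) {
    return(list(p_value = NA_real_, observed = NA_real_,
                n_permutations = n_permutations,
                reason = "no_usable_individuals"))
  }
  if (length(unique(dat$genotype)) < 2) {
    return(list(p_value = 1, observed = record$mean_si,
                n_permutations = n_permutations,
                reason = "constant_genotype"))
  }
  ord <- order(dat$genotype, dat$d, method = "radix")
  het <- dat$genotype[ord] == "HET"
  s_het <- dat$d[ord]^2 / 0.25
  obs <- mean(ifelse(het, s_het, 1 - s_het))

  rec_seed <- child_seed(seed, paste(record$candidate_snp_id,
                                     record$tag_snp_id))
  perm <- withr::with_seed(rec_seed, {
    vapply(seq_len(n_permutations), function(i) {
      g <- sample(het)
      mean(ifelse(g, s_het, 1 - s_het))
    }, numeric(1))
  })
  list(
    p_value = empirical_p(sum(perm >= obs - 1e-12), n_permutations),
    observed = obs, n_permutations = n_permutations, reason = NA_character_
  )
}

#' Scan for functional SNPs by genotype-imbalance concordance
#'
#' For every tag SNP (an alternative-region SNP with a significant ASAS
#' call in at least one sample), scores all SNPs in the same gene as
#' candidate functional SNPs, applies the testability filters, computes
#' permutation p-values, and adjusts them (BH) across all candidate-tag
#' pairs in the chosen mode.
#'
#' @param calls Per-sample calls from [call_asas()] (all samples; the tag
#'   SNP set is defined cohort-wide so that disease-stratified modes share
#'   one candidate universe).
#' @param genotypes Long phased genotype tibble.
#' @param snp_info SNP annotation (`snp_id`, `gene_id`, `pos`).
#' @param metadata Sample metadata (`sample_id`, `individual_id`, `group`).
#' @param events Event annotation with exon coordinates (for candidate
#'   distance to the event exon).
#' @param mode `"ALL"`, `"AD"` or `"CONTROL"`: which samples contribute
#'   tag allelic ratios and genotype-imbalance pairs.
#' @param het_fraction,sample_fraction Testability thresholds (0.10).
#' @param n_permutations Permutations per pair (default 1000).
#' @param fdr_threshold FDR for the significance flag (default 0.05).
#' @param min_stratum_size Strata smaller than this are skipped with a
#'   warning (default 20).
#' @param seed Integer seed for the permutation null.
#' @return A tibble of class `concordance_scan`, one row per
#'   candidate-tag-event triple: `mode`, `candidate_snp_id`, `tag_snp_id`,
#'   `event_id`, `gene_id`, `n_het`, `n_total`, `mean_si`, `testable`,
#'   `reason`, `p_value`, `fdr`, `significant`, `distance_to_exon`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_individuals = 30, n_genes = 2, seed = 1))
#' calls <- call_asas(cohort$counts, cohort$genotypes, cohort$metadata)
#' concordance_scan(calls, cohort$genotypes, cohort$snp_info,
#'                  cohort$metadata, cohort$events,
#'                  n_permutations = 100, seed = 1)
#' @export
concordance_scan <- function(calls, genotypes, snp_info, metadata, events,
                             mode = c("ALL", "AD", "CONTROL"),
                             het_fraction = 0.10, sample_fraction = 0.10,
                             n_permutations = 1000, fdr_threshold = 0.05,
                             min_stratum_size = 20, seed = 1) {
  mode <- match.arg(mode)
  meta_mode <- switch(mode,
    ALL = metadata,
    AD = metadata %>% filter(.data$group == "AD"),
    CONTROL = metadata %>% filter(.data$group == "control")
  )
  cohort_size <- dplyr::n_distinct(meta_mode$individual_id)
  if (cohort_size == 0) {
    warn(sprintf("mode %s has no samples; skipped", mode))
    return(empty_concordance_scan(mode))
  }
  if (cohort_size < min_stratum_size) {
    warn(sprintf("mode %s has only %d individuals (< %d); skipped",
                 mode, cohort_size, min_stratum_size))
    return(empty_concordance_scan(mode))
  }

  # tag SNPs: significant in >= 1 sample anywhere in the cohort
  tags <- calls %>%
    filter(.data$significant) %>%
    distinct(.data$snp_id, .data$event_id, .data$gene_id)
  if (nrow(tags) == 0) return(empty_concordance_scan(mode))

  # per-individual tag ratios within the mode (mean across the
  # individual's tested samples)
  mode_calls <- calls %>%
    semi_join(meta_mode, by = "sample_id") %>%
    filter(.data$tested)
  tag_ratio_tbl <- mode_calls %>%
    group_by(.data$snp_id, .data$event_id, .data$individual_id) %>%
    summarise(ratio = mean(.data$ratio_alt_region), .groups = "drop")

  rows <- list()
  for (i in seq_len(nrow(tags))) {
    tag <- tags[i, ]
    ratios <- tag_ratio_tbl %>%
      filter(.data$snp_id == tag$snp_id, .data$event_id == tag$event_id) %>%
      select("individual_id", "ratio")
    cands <- snp_info %>% filter(.data$gene_id == tag$gene_id)
    ev <- events %>% filter(.data$event_id == tag$event_id)
    for (j in seq_len(nrow(cands))) {
      rec <- score_candidate(cands$snp_id[j], tag$snp_id, genotypes, ratios)
      testab <- concordance_testability(rec, cohort_size,
                                        het_fraction, sample_fraction)
      if (testab$pass) {
        tst <- concordance_test(rec, n_permutations,
                                child_seed(seed, mode))
        p <- tst$p_value
        reason <- tst$reason
      } else {
        p <- NA_real_
        reason <- testab$reason
      }
      rows[[length(rows) + 1L]] <- tibble(
        mode = mode,
        candidate_snp_id = cands$snp_id[j],
        tag_snp_id = tag$snp_id,
        event_id = tag$event_id,
        gene_id = tag$gene_id,
        n_het = rec$n_het,
        n_total = rec$n_total,
        mean_si = rec$mean_si,
        testable = testab$pass,
        reason = reason,
        p_value = p,
        distance_to_exon = exon_distance(cands$pos[j], ev$exon_start,
                                         ev$exon_end)
      )
    }
  }
  out <- bind_rows(rows) %>%
    mutate(
      fdr = ifelse(.data$testable, p.adjust(.data$p_value, method = "BH"),
                   NA_real_),
      significant = !is.na(.data$fdr) & .data$fdr <= fdr_threshold
    ) %>%
    arrange(.data$gene_id, .data$event_id, .data$candidate_snp_id)
  class(out) <- c("concordance_scan", class(out))
  out
}

empty_concordance_scan <- function(mode) {
  out <- tibble(
    mode = character(), candidate_snp_id = character(),
    tag_snp_id = character(), event_id = character(),
    gene_id = character(), n_het = integer(), n_total = integer(),
    mean_si = numeric(), testable = logical(), reason = character(),
    p_value = numeric(), fdr = numeric(), significant = logical(),
    distance_to_exon = numeric()
  )
  class(out) <- c("concordance_scan", class(out))
  out
}

# signed distance from a position to an exon interval (0-based half-open):
# negative upstream of the start, positive downstream of the end, 0 inside
exon_distance <- function(pos, exon_start, exon_end) {
  dplyr::case_when(
    pos < exon_start ~ as.numeric(pos - exon_start),
    pos >= exon_end ~ as.numeric(pos - exon_end + 1),
    TRUE ~ 0
  )
}

#' Rank candidates within genes
#'
#' Collapses a concordance scan to one row per candidate (its best
#' candidate-tag pairing) and ranks candidates within each gene by the
#' reporting tie-break: smallest p, then largest mean score, then smallest
#' absolute distance to the exon, then SNP id. Untestable candidates rank
#' last.
#'
#' @param scan A `concordance_scan` tibble.
#' @return One row per (gene, candidate) with a `rank_in_gene` column,
#'   best candidate first.
#' @export
rank_candidates <- function(scan) {
  scan %>%
    group_by(.data$gene_id, .data$candidate_snp_id) %>%
    arrange(is.na(.data$p_value), .data$p_value, desc(.data$mean_si),
            abs(.data$distance_to_exon), .data$candidate_snp_id,
            .by_group = TRUE) %>%
    slice(1) %>%
    group_by(.data$gene_id) %>%
    arrange(is.na(.data$p_value), .data$p_value, desc(.data$mean_si),
            abs(.data$distance_to_exon), .data$candidate_snp_id,
            .by_group = TRUE) %>%
    mutate(rank_in_gene = row_number()) %>%
    ungroup()
}
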