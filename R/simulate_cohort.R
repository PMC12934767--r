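#' Simulate an ASAS cohort
#'
#' Generates a complete synthetic cohort from a [cohort_spec()]: phased
#' genotypes, splicing-event annotations, per-sample allelic read counts,
#' sample metadata, and a truth table recording the planted effects. The
#' generative model is:
#'
#' * each gene carries one planted functional SNP (allele frequency
#'   `functional_maf`); the haplotype carrying its alternative allele
#'   includes the gene's cassette exon(s) at level
#'   `baseline_psi + delta_psi` (plus `ad_specific_effect` in AD
#'   individuals, clamped into \[0, 1\]), the reference haplotype at
#'   `baseline_psi`;
#' * each alternative exon contains one tag SNP in tight LD with the
#'   functional SNP; its read coverage is proportional to the mean
#'   inclusion of the two haplotypes and its reference-allele count is
#'   drawn from a beta-binomial whose mean is the inclusion share of the
#'   haplotype carrying the reference allele;
#' * constitutive SNPs have balanced (0.5) expected allelic ratios with
#'   the same beta-binomial noise;
#' * with probability 0.5 the functional SNP sits inside the alternative
#'   exon (and is then itself covered by reads, i.e. usable as a tag SNP),
#'   otherwise it is intronic within 300 bp of the exon and appears only
#'   in the genotypes.
#'
#' All coordinates are 0-based half-open; identical spec and seed
#' reproduce the cohort exactly.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `asas_cohort`: a list with tibbles
#'   `genotypes` (individual by SNP phased haplotype alleles), `events`,
#'   `counts`, `metadata`, `snp_info`, and `truth` (list of
#'   `functional_snps` and `inclusion`, the per-individual per-event true
#'   haplotype inclusion levels).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_individuals = 12, n_genes = 2, seed = 7))
#' cohort$counts
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)

  ind_ids <- sprintf("ind_%03d", seq_len(spec$n_individuals))
  n_ad <- round(spec$n_individuals * spec$fraction_ad)
  ad_ind <- sample(ind_ids, n_ad)
  metadata <- tidyr::expand_grid(
    individual_id = ind_ids,
    rep = seq_len(spec$samples_per_individual)
  ) %>%
    mutate(
      sample_id = sprintf("%s_s%d", .data$individual_id, .data$rep),
      region = "synthetic",
      group = ifelse(.data$individual_id %in% ad_ind, "AD", "control")
    ) %>%
    select("sample_id", "individual_id", "region", "group")

  structure_tabs <- build_gene_structure(spec)
  events <- structure_tabs$events
  snp_info <- structure_tabs$snp_info

  genotypes <- draw_genotypes(spec, ind_ids, snp_info)

  # true per-haplotype inclusion per (gene, individual)
  fun_snps <- snp_info %>% filter(.data$role == "FUNCTIONAL")
  fgt <- genotypes %>%
    inner_join(select(fun_snps, "snp_id", "gene_id"), by = "snp_id") %>%
    mutate(is_ad = .data$individual_id %in% ad_ind,
           delta_eff = spec$delta_psi +
             ifelse(.data$is_ad, spec$ad_specific_effect, 0)) %>%
    mutate(
      psi_h1_raw = spec$baseline_psi + .data$delta_eff * .data$a1,
      psi_h2_raw = spec$baseline_psi + .data$delta_eff * .data$a2,
      psi_h1 = clamp(.data$psi_h1_raw, 0, 1),
      psi_h2 = clamp(.data$psi_h2_raw, 0, 1),
      clamped = .data$psi_h1_raw != .data$psi_h1 |
        .data$psi_h2_raw != .data$psi_h2
    )

  inclusion <- events %>%
    select("event_id", "gene_id") %>%
    inner_join(
      fgt %>%
        select("gene_id", "individual_id",
               functional_snp_id = "snp_id",
               functional_a1 = "a1", functional_a2 = "a2",
               "psi_h1", "psi_h2", "clamped"),
      by = "gene_id", relationship = "many-to-many"
    ) %>%
    arrange(.data$event_id, .data$individual_id)

  counts <- draw_counts(spec, metadata, snp_info, genotypes, fgt)

  untestable_genes <- counts %>%
    group_by(.data$gene_id) %>%
    summarise(total = sum(.data$ref_count + .data$alt_count)) %>%
    filter(.data$total == 0) %>%
    pull("gene_id")
  events <- events %>%
    mutate(untestable = .data$gene_id %in% untestable_genes)

  structure(
    list(
      spec = spec,
      metadata = metadata,
      events = events,
      snp_info = snp_info,
      genotypes = genotypes,
      counts = counts,
      truth = list(
        functional_snps = fun_snps %>%
          select("snp_id", "gene_id", "pos", "placement", "event_id",
                 "distance_to_exon"),
        inclusion = inclusion
      )
    ),
    class = "asas_cohort"
  )
}

#' @export
print.asas_cohort <- function(x, ...) {
  cat(sprintf(
    "<asas_cohort> %d individuals x %d samples, %d genes, %d events, %d SNPs, %d count rows\n",
    x$spec$n_individuals, nrow(x$metadata), x$spec$n_genes,
    nrow(x$events), nrow(x$snp_info), nrow(x$counts)
  ))
  invisible(x)
}

# gene/event/SNP layout; consumes RNG (functional SNP placement)
build_gene_structure <- function(spec) {
  genes <- tibble(
    gene_idx = seq_len(spec$n_genes),
    gene_id = sprintf("gene_%03d", seq_len(spec$n_genes)),
    gene_base = (seq_len(spec$n_genes) - 1L) * 1000000L
  )

  events <- tidyr::expand_grid(
    genes,
    event_idx = seq_len(max(spec$events_per_gene, 0L))
  )
  if (spec$events_per_gene > 0) {
    events <- events %>%
      mutate(
        event_id = sprintf("%s_ev%d", .data$gene_id, .data$event_idx),
        type = "SE",
        chrom = "chr1",
        exon_start = .data$gene_base + 5000L + (.data$event_idx - 1L) * 3000L,
        exon_end = .data$exon_start + 100L,
        upstream_flank = .data$exon_start - 1000L,
        downstream_flank = .data$exon_end + 1000L,
        strand = "+"
      ) %>%
      select("event_id", "gene_id", "type", "chrom", "exon_start",
             "exon_end", "upstream_flank", "downstream_flank", "strand")
  } else {
    events <- tibble(
      event_id = character(), gene_id = character(), type = character(),
      chrom = character(), exon_start = integer(), exon_end = integer(),
      upstream_flank = integer(), downstream_flank = integer(),
      strand = character()
    )
  }

  tag_snps <- events %>%
    mutate(
      gene_idx = match(.data$gene_id, genes$gene_id),
      snp_id = sprintf("snp_%s_tag", .data$event_id),
      pos = .data$exon_start + 50L,
      role = "TAG",
      region_class = "ALTERNATIVE",
      placement = "exonic",
      distance_to_exon = 0L
    )

  # one functional SNP per gene, tied to the gene's first event
  fun_snps <- NULL
  if (spec$events_per_gene > 0) {
    first_ev <- events %>%
      group_by(.data$gene_id) %>%
      slice(1) %>%
      ungroup()
    exonic <- runif(nrow(first_ev)) < 0.5
    offset <- integer(nrow(first_ev))
    updist <- sample(300L, nrow(first_ev), replace = TRUE)
    fun_snps <- first_ev %>%
      mutate(
        gene_idx = match(.data$gene_id, genes$gene_id),
        placement = ifelse(exonic, "exonic", "intronic"),
        pos = ifelse(exonic, .data$exon_start + 20L,
                     .data$exon_start - updist),
        snp_id = sprintf("snp_%s_fun", .data$gene_id),
        role = "FUNCTIONAL",
        region_class = ifelse(exonic, "ALTERNATIVE", "INTRONIC"),
        distance_to_exon = ifelse(exonic, 0L, .data$pos - .data$exon_start)
      )
  }

  const_snps <- tidyr::expand_grid(
    genes,
    const_idx = seq_len(spec$constitutive_snps_per_gene)
  ) %>%
    mutate(
      snp_id = sprintf("snp_%s_const%d", .data$gene_id, .data$const_idx),
      pos = .data$gene_base + 1000L + .data$const_idx * 100L,
      role = "CONSTITUTIVE",
      region_class = "CONSTITUTIVE",
      event_id = NA_character_,
      placement = "constitutive",
      distance_to_exon = NA_integer_
    )

  cols <- c("snp_id", "gene_id", "gene_idx", "pos", "role", "region_class",
            "event_id", "placement", "distance_to_exon")
  snp_info <- bind_rows(
    tag_snps %>% select(all_of(cols)),
    if (!is.null(fun_snps)) fun_snps %>% select(all_of(cols)),
    const_snps %>% select(all_of(cols))
  ) %>%
    mutate(chrom = "chr1", ref = "A", alt = "G",
           pos = as.integer(.data$pos),
           distance_to_exon = as.integer(.data$distance_to_exon)) %>%
    arrange(.data$gene_idx, .data$pos, .data$snp_id) %>%
    select(-"gene_idx")

  list(events = events, snp_info = snp_info)
}

# phased haplotype alleles for every (individual, SNP); 0 = ref, 1 = alt
draw_genotypes <- function(spec, ind_ids, snp_info) {
  n <- length(ind_ids)
  fun <- snp_info %>% filter(.data$role == "FUNCTIONAL") %>%
    arrange(.data$snp_id)
  tags <- snp_info %>% filter(.data$role == "TAG") %>%
    arrange(.data$snp_id)
  const <- snp_info %>% filter(.data$role == "CONSTITUTIVE") %>%
    arrange(.data$snp_id)

  out <- list()
  # functional haplotypes drawn first; tag haplotypes copy them with flips
  fun_hap <- list()
  for (i in seq_len(nrow(fun))) {
    a1 <- rbinom(n, 1L, spec$functional_maf)
    a2 <- rbinom(n, 1L, spec$functional_maf)
    fun_hap[[fun$gene_id[i]]] <- cbind(a1, a2)
    out[[length(out) + 1L]] <- tibble(
      individual_id = ind_ids, snp_id = fun$snp_id[i], a1 = a1, a2 = a2
    )
  }
  for (i in seq_len(nrow(tags))) {
    fh <- fun_hap[[tags$gene_id[i]]]
    if (is.null(fh)) {
      a1 <- rbinom(n, 1L, 0.5); a2 <- rbinom(n, 1L, 0.5)
    } else {
      flip1 <- rbinom(n, 1L, spec$tag_ld_flip)
      flip2 <- rbinom(n, 1L, spec$tag_ld_flip)
      a1 <- as.integer(xor(fh[, 1], flip1))
      a2 <- as.integer(xor(fh[, 2], flip2))
    }
    out[[length(out) + 1L]] <- tibble(
      individual_id = ind_ids, snp_id = tags$snp_id[i], a1 = a1, a2 = a2
    )
  }
  for (i in seq_len(nrow(const))) {
    out[[length(out) + 1L]] <- tibble(
      individual_id = ind_ids, snp_id = const$snp_id[i],
      a1 = rbinom(n, 1L, 0.5), a2 = rbinom(n, 1L, 0.5)
    )
  }
  bind_rows(out) %>%
    mutate(gt = paste0(.data$a1, "|", .data$a2)) %>%
    arrange(.data$snp_id, .data$individual_id)
}

# beta-binomial allelic counts for every (sample, covered SNP)
draw_counts <- function(spec, metadata, snp_info, genotypes, fgt) {
  covered <- snp_info %>% filter(.data$region_class != "INTRONIC")
  grid <- metadata %>%
    select("sample_id", "individual_id") %>%
    tidyr::expand_grid(covered) %>%
    left_join(genotypes, by = c("individual_id", "snp_id")) %>%
    left_join(
      fgt %>% select("gene_id", "individual_id", "psi_h1", "psi_h2"),
      by = c("gene_id", "individual_id")
    ) %>%
    arrange(.data$gene_id, .data$snp_id, .data$individual_id, .data$sample_id)

  alt_region <- grid$region_class == "ALTERNATIVE"
  psi_sum <- ifelse(alt_region, grid$psi_h1 + grid$psi_h2, NA_real_)
  # each haplotype contributes reads in proportion to its inclusion level
  lambda <- ifelse(alt_region, spec$mean_coverage * psi_sum,
                   spec$mean_coverage)

  het <- grid$a1 != grid$a2
  mu <- numeric(nrow(grid))
  # hom: all reads carry the single allele
  mu[!het] <- ifelse(grid$a1[!het] == 0, 1, 0)
  # het, constitutive: balanced
  sel <- het & !alt_region
  mu[sel] <- 0.5
  # het, alternative: inclusion share of the haplotype carrying the ref allele
  sel <- het & alt_region
  psi_ref <- ifelse(grid$a1 == 0, grid$psi_h1, grid$psi_h2)
  mu[sel] <- ifelse(psi_sum[sel] > 0, psi_ref[sel] / psi_sum[sel], 0.5)

  lambda[alt_region & psi_sum == 0] <- 0
  total <- rpois(nrow(grid), lambda)
  ref_count <- rbetabinom(nrow(grid), total, mu, spec$overdispersion)

  grid %>%
    mutate(
      total = total,
      ref_count = as.integer(ref_count),
      alt_count = as.integer(total - ref_count)
    ) %>%
    select("sample_id", "snp_id", "chrom", "pos", "ref_count", "alt_count",
           "gene_id", "region_class", "event_id") %>%
    arrange(.data$sample_id, .data$gene_id, .data$pos, .data$snp_id)
}
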