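#' LD-block overlap between ASAS-associated SNPs and GWAS SNPs
#'
#' A query SNP overlaps a trait when some GWAS SNP of that trait shares
#' its LD block and lies within `window` bases; exact positional
#' coincidence is additionally flagged as a direct overlap. SNPs absent
#' from the LD map are treated as singleton blocks.
#'
#' @param asas_snps Tibble (`snp_id`, `chrom`, `pos`) of query SNPs.
#' @param gwas_snps Tibble (`snp_id`, `chrom`, `pos`, `trait`) of GWAS
#'   associations (pre-filtered to genome-wide significance upstream).
#' @param ld_map Tibble (`snp_id`, `block_id`) mapping SNPs to LD blocks.
#' @param window Maximum distance in bases (default 200000).
#' @return A list: `per_snp` (query SNP x trait overlap flags, including
#'   `direct`), and `per_trait` (tally of query SNPs in LD overlap per
#'   trait).
#' @export
ld_overlap <- function(asas_snps, gwas_snps, ld_map, window = 200000) {
  block_of <- function(ids) {
    b <- ld_map$block_id[match(ids, ld_map$snp_id)]
    ifelse(is.na(b), paste0("__singleton__", ids), b)
  }
  q <- asas_snps %>% mutate(block = block_of(.data$snp_id))
  g <- gwas_snps %>% mutate(block = block_of(.data$snp_id))

  pairs <- q %>%
    inner_join(g, by = "block", suffix = c("_q", "_g"),
               relationship = "many-to-many") %>%
    filter(.data$chrom_q == .data$chrom_g,
           abs(.data$pos_q - .data$pos_g) <= window)

  direct <- q %>%
    inner_join(g, by = c("chrom" = "chrom", "pos" = "pos"),
               suffix = c("_q", "_g"), relationship = "many-to-many") %>%
    distinct(snp_id = .data$snp_id_q, trait = .data$trait)

  per_snp <- pairs %>%
    distinct(snp_id = .data$snp_id_q, trait = .data$trait) %>%
    mutate(ld_overlap = TRUE) %>%
    dplyr::full_join(direct %>% mutate(direct = TRUE),
                     by = c("snp_id", "trait")) %>%
    mutate(ld_overlap = !is.na(.data$ld_overlap),
           direct = !is.na(.data$direct))

  per_trait <- per_snp %>%
    filter(.data$ld_overlap) %>%
    count(.data$trait, name = "n_snps_in_ld")

  list(per_snp = per_snp, per_trait = per_trait,
       n_query = nrow(asas_snps),
       n_query_in_ld = dplyr::n_distinct(
         per_snp$snp_id[per_snp$ld_overlap]))
}

#' Trait-level GWAS enrichment score
#'
#' The enrichment of a trait is the ratio of proportions
#' `(x_trait / x_total) / (y_trait / y_total)`, where x counts
#' ASAS-associated SNPs in LD with GWAS SNPs (for the trait / for any
#' trait) and y counts the same for background SNPs. A two-sided Fisher's
#' exact test on `[[x_trait, x_total - x_trait], [y_trait, y_total -
#' y_trait]]` accompanies the score. When `y_trait` is zero the score is
#' computed with 0.5 added to all four cells (noted in the output); the
#' Fisher p is always computed on the raw counts.
#'
#' @param x_trait,x_total,y_trait,y_total Non-negative counts with
#'   `x_trait <= x_total`, `y_trait <= y_total`, positive totals.
#' @return A one-row tibble: the four counts, `score`, `p_value`, `note`.
#' @examples
#' gwas_enrichment_score(5, 50, 2, 100) # score 5
#' @export
gwas_enrichment_score <- function(x_trait, x_total, y_trait, y_total) {
  if (x_total <= 0 || y_total <= 0) abort("totals must be positive")
  if (x_trait > x_total || y_trait > y_total || x_trait < 0 || y_trait < 0) {
    abort("trait counts must lie in [0, total]")
  }
  note <- NA_character_
  if (y_trait == 0) {
    score <- ((x_trait + 0.5) / (x_total + 0.5)) /
      ((y_trait + 0.5) / (y_total + 0.5))
    note <- "continuity-corrected score (y_trait = 0)"
  } else {
    score <- (x_trait / x_total) / (y_trait / y_total)
  }
  tibble(
    x_trait = x_trait, x_total = x_total,
    y_trait = y_trait, y_total = y_total,
    score = score,
    p_value = fisher2x2_p(x_trait, x_total - x_trait,
                          y_trait, y_total - y_trait),
    note = note
  )
}

#' Group GWAS traits into broad categories
#'
#' Case-insensitive substring matching against three keyword lists:
#' AD-related ("Alzheimer", "dementia", "amyloid", "neurofibrillary
#' tangles"), other brain-related ("neuroticism", "Parkinson",
#' "schizophrenia", "brain"), and immune-related ("immune", "antigen",
#' "microglia", "cytokine", "antibody", "interferon", "inflammatory").
#' Traits matching several lists are assigned by precedence AD > brain >
#' immune; unmatched traits fall into `"other"`.
#'
#' @param trait_labels Character vector of trait descriptions.
#' @return Character vector of categories, one per trait.
#' @examples
#' gwas_trait_category(c("Alzheimer's disease (late onset)", "Standing height"))
#' @export
gwas_trait_category <- function(trait_labels) {
  kw <- list(
    AD_related = c("alzheimer", "dementia", "amyloid",
                   "neurofibrillary tangles"),
    brain_related = c("neuroticism", "parkinson", "schizophrenia", "brain"),
    immune_related = c("immune", "antigen", "microglia", "cytokine",
                       "antibody", "interferon", "inflammatory")
  )
  lab <- tolower(trait_labels)
  out <- rep("other", length(lab))
  for (cat in rev(names(kw))) { # apply in reverse so AD wins precedence
    hit <- Reduce(`|`, lapply(kw[[cat]], function(k) grepl(k, lab,
                                                           fixed = TRUE)))
    out[hit] <- cat
  }
  out
}

#' Direct GWAS overlap Fisher test
#'
#' Compares the number of ASAS-associated SNPs versus background SNPs
#' whose positions coincide exactly with a GWAS SNP, with a two-sided
#' Fisher's exact test. The background should be an equal-size sample of
#' common SNPs drawn from genes without ASAS events.
#'
#' @param asas_snps,background_snps Tibbles with `chrom`, `pos`.
#' @param gwas_positions Tibble with `chrom`, `pos` of GWAS SNPs.
#' @return A list with the 2x2 `table` and the Fisher `p_value`.
#' @export
direct_overlap_fisher <- function(asas_snps, background_snps,
                                  gwas_positions) {
  gw <- gwas_positions %>% distinct(.data$chrom, .data$pos)
  n_hit <- function(d) {
    nrow(d %>% distinct(.data$chrom, .data$pos) %>%
           semi_join(gw, by = c("chrom", "pos")))
  }
  a <- n_hit(asas_snps)
  b <- nrow(distinct(asas_snps, .data$chrom, .data$pos)) - a
  c <- n_hit(background_snps)
  d <- nrow(distinct(background_snps, .data$chrom, .data$pos)) - c
  list(table = matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                      dimnames = list(c("asas", "background"),
                                      c("overlap", "no_overlap"))),
       p_value = fisher2x2_p(a, b, c, d))
}
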