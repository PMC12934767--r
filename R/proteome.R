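#' Per-gene mRNA-protein correlation
#'
#' Spearman correlation between per-gene RNA expression (RPKM) and
#' protein abundance across shared samples. Samples with zero RPKM are
#' removed per gene; genes retaining fewer than `min_pairs` paired
#' samples are reported untestable. BH FDR across tested genes.
#'
#' @param expression Tibble with `gene_id` plus one column per sample
#'   (RPKM).
#' @param protein Tibble with `gene_id` plus one column per sample
#'   (abundance, any centred scale).
#' @param min_pairs Minimum usable sample pairs per gene (default 10).
#' @param fdr_threshold Significance cutoff on the FDR (default 0.05).
#' @return A tibble of class `gene_correlation`: `gene_id`,
#'   `n_samples_used`, `rho`, `p_value`, `fdr`, `significant`,
#'   `reason_code`.
#' @export
mrna_protein_correlation <- function(expression, protein, min_pairs = 10,
                                     fdr_threshold = 0.05) {
  shared_samples <- intersect(setdiff(names(expression), "gene_id"),
                              setdiff(names(protein), "gene_id"))
  if (length(shared_samples) == 0) {
    abort("expression and protein matrices share no sample columns")
  }
  genes <- intersect(expression$gene_id, protein$gene_id)

  e_mat <- as.matrix(expression[match(genes, expression$gene_id),
                                shared_samples])
  p_mat <- as.matrix(protein[match(genes, protein$gene_id),
                             shared_samples])

  rows <- purrr::map(seq_along(genes), function(i) {
    x <- e_mat[i, ]
    y <- p_mat[i, ]
    keep <- !is.na(x) & !is.na(y) & x != 0
    n_used <- sum(keep)
    if (n_used < min_pairs) {
      return(tibble(gene_id = genes[i], n_samples_used = n_used,
                    rho = NA_real_, p_value = NA_real_,
                    reason_code = "too_few_pairs"))
    }
    ct <- suppressWarnings(
      cor.test(x[keep], y[keep], method = "spearman", exact = FALSE)
    )
    tibble(gene_id = genes[i], n_samples_used = n_used,
           rho = unname(ct$estimate), p_value = ct$p.value,
           reason_code = NA_character_)
  }) %>% bind_rows()

  rows %>%
    mutate(
      fdr = ifelse(is.na(.data$p_value), NA_real_,
                   p.adjust(.data$p_value, method = "BH")),
      significant = !is.na(.data$fdr) & .data$fdr <= fdr_threshold
    ) %>%
    (function(d) { class(d) <- c("gene_correlation", class(d)); d })
}

#' Compare correlated-gene fractions between two gene groups
#'
#' Two-sided Fisher test of the fraction of significantly mRNA-protein
#' correlated genes between two gene groups (e.g. genes with 5' UTR ASAS
#' events versus all other genes).
#'
#' @param group_a_genes,group_b_genes Character vectors of gene ids.
#' @param correlations Output of [mrna_protein_correlation()].
#' @return A list with the 2x2 `table`, per-group correlated fractions,
#'   and the Fisher `p_value`; NULL with a warning when either group has
#'   no tested gene.
#' @export
correlated_fraction_test <- function(group_a_genes, group_b_genes,
                                     correlations) {
  tested <- correlations %>% filter(!is.na(.data$p_value))
  a <- tested %>% filter(.data$gene_id %in% group_a_genes)
  b <- tested %>% filter(.data$gene_id %in% group_b_genes)
  if (nrow(a) == 0 || nrow(b) == 0) {
    warn("one of the groups has no tested gene; no test performed")
    return(NULL)
  }
  a_sig <- sum(a$significant)
  b_sig <- sum(b$significant)
  list(
    table = matrix(c(a_sig, nrow(a) - a_sig, b_sig, nrow(b) - b_sig),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("group_a", "group_b"),
                                   c("correlated", "not_correlated"))),
    fraction_a = a_sig / nrow(a),
    fraction_b = b_sig / nrow(b),
    p_value = fisher2x2_p(a_sig, nrow(a) - a_sig,
                          b_sig, nrow(b) - b_sig)
  )
}
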