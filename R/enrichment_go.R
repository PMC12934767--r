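#' Matched background gene sets
#'
#' Draws background gene sets matched to a query set on expression level
#' (within +/-10%) and gene length (within +/-10%), excluding genes that
#' themselves harbour ASAS events. One matched gene is sampled per query
#' gene; sampling is with replacement across sets and without replacement
#' within a set. When a query gene has no eligible match the tolerance is
#' widened stepwise by 5 points up to +/-25%, after which the gene is
#' dropped with a warning.
#'
#' @param query_genes Character vector of query gene ids (must appear in
#'   `universe`).
#' @param universe Gene universe tibble with columns `gene_id`,
#'   `expression`, `length`, `is_asas`.
#' @param n_sets Number of background sets (default 10000).
#' @param seed Integer seed.
#' @param tolerance Initial matching tolerance (default 0.10).
#' @return A list of `n_sets` character vectors of matched gene ids.
#' @export
matched_background_sets <- function(query_genes, universe, n_sets = 10000,
                                    seed = 1, tolerance = 0.10) {
  stopifnot(all(c("gene_id", "expression", "length", "is_asas") %in%
                  names(universe)))
  pool <- universe %>% filter(!.data$is_asas)
  qrows <- universe %>% filter(.data$gene_id %in% query_genes)
  if (nrow(qrows) < length(unique(query_genes))) {
    abort("some query genes are missing from the universe")
  }

  eligible <- list()
  dropped <- character()
  for (i in seq_len(nrow(qrows))) {
    e <- qrows$expression[i]
    l <- qrows$length[i]
    tol <- tolerance
    elig <- character()
    while (length(elig) == 0 && tol <= 0.25 + 1e-9) {
      elig <- pool %>%
        filter(.data$expression >= (1 - tol) * e,
               .data$expression <= (1 + tol) * e,
               .data$length >= (1 - tol) * l,
               .data$length <= (1 + tol) * l) %>%
        pull("gene_id")
      if (length(elig) == 0) tol <- tol + 0.05
    }
    if (length(elig) == 0) {
      dropped <- c(dropped, qrows$gene_id[i])
    } else {
      eligible[[qrows$gene_id[i]]] <- elig
    }
  }
  if (length(dropped) > 0) {
    warn(sprintf("no matched background for %d query gene(s): %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  if (length(eligible) == 0) abort("no query gene has an eligible match")

  withr::with_seed(child_seed(seed, "matched_background_sets"), {
    lapply(seq_len(n_sets), function(s) {
      chosen <- character(length(eligible))
      taken <- character()
      for (k in seq_along(eligible)) {
        avail <- setdiff(eligible[[k]], taken)
        if (length(avail) == 0) avail <- eligible[[k]] # duplicate, rare
        pick <- if (length(avail) == 1) avail else sample(avail, 1)
        chosen[k] <- pick
        taken <- c(taken, pick)
      }
      chosen
    })
  })
}

#' Empirical term enrichment against matched backgrounds
#'
#' For each annotation term, compares its count among the query genes to
#' the null distribution of its counts across matched background sets.
#' The empirical p-value uses an add-one pseudocount, so it can never fall
#' below `1 / (n_sets + 1)`; BH FDR is computed across terms.
#'
#' @param query_genes Character vector of query gene ids.
#' @param background_sets List of background gene-id vectors from
#'   [matched_background_sets()].
#' @param annotations Tibble (`gene_id`, `term`) of gene-term links.
#' @param fdr_threshold Significance threshold on the FDR (default 0.05).
#' @return A tibble of class `enrichment_result`: `term`, `query_count`,
#'   `null_mean`, `null_sd`, `n_sets`, `empirical_p`, `fdr`,
#'   `significant`.
#' @export
empirical_term_enrichment <- function(query_genes, background_sets,
                                      annotations,
                                      fdr_threshold = 0.05) {
  terms <- sort(unique(annotations$term))
  gene_terms <- split(annotations$term, annotations$gene_id)
  count_terms <- function(genes) {
    tt <- unlist(gene_terms[intersect(genes, names(gene_terms))],
                 use.names = FALSE)
    tabulate(factor(tt, levels = terms), nbins = length(terms))
  }

  q_counts <- count_terms(query_genes)
  null_counts <- vapply(background_sets, count_terms,
                        integer(length(terms)))
  if (is.null(dim(null_counts))) {
    null_counts <- matrix(null_counts, nrow = length(terms))
  }
  n_sets <- length(background_sets)

  n_ge <- rowSums(null_counts >= matrix(q_counts, nrow = length(terms),
                                        ncol = n_sets))
  out <- tibble(
    term = terms,
    query_count = q_counts,
    null_mean = rowMeans(null_counts),
    null_sd = apply(null_counts, 1, sd),
    n_sets = n_sets,
    empirical_p = empirical_p(n_ge, n_sets)
  ) %>%
    mutate(fdr = p.adjust(.data$empirical_p, method = "BH"),
           significant = .data$fdr <= fdr_threshold) %>%
    arrange(.data$empirical_p, .data$term)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Upper-tail hypergeometric overlap test
#'
#' Tests whether a query gene set overlaps a target set more than
#' expected given the universe (query plus background genes).
#'
#' @param query,target,background Character vectors of gene ids; the
#'   universe is `union(query, background)` and the target is intersected
#'   with it.
#' @return A list with the overlap count, set sizes, and the upper-tail
#'   hypergeometric `p_value`.
#' @export
hypergeometric_overlap <- function(query, target, background) {
  universe <- union(query, background)
  if (length(universe) == 0) abort("empty gene universe")
  target_u <- intersect(target, universe)
  k <- length(intersect(query, target_u))
  list(
    overlap = k,
    n_query = length(unique(query)),
    n_target = length(target_u),
    n_universe = length(universe),
    p_value = phyper(k - 1, length(target_u),
                     length(universe) - length(target_u),
                     length(unique(query)), lower.tail = FALSE)
  )
}

#' Simulate a gene universe with annotated terms
#'
#' Builds a synthetic gene universe for exercising the matched-background
#' enrichment machinery: log-normal expression, log-normal gene lengths,
#' term annotations with strongly varying prevalence (as gene-ontology
#' term sizes do), an ASAS flag on the query genes, and one planted term
#' enriched among them.
#'
#' @param n_genes Universe size (default 12000, the scale of the expressed genome).
#' @param n_terms Number of unplanted terms (default 200).
#' @param n_query Number of query (ASAS) genes (default 200, the order of
#'   magnitude of an ASAS gene set in a brain cohort).
#' @param planted_prob Probability that a query gene carries the planted
#'   term (default 0.6); background genes carry it with probability 0.05.
#' @param seed Integer seed.
#' @return A list with `universe` (gene tibble), `annotations`
#'   (gene-term tibble), `query_genes`, and `planted_term`.
#' @export
simulate_gene_universe <- function(n_genes = 12000, n_terms = 200,
                                   n_query = 200, planted_prob = 0.6,
                                   seed = 1) {
  withr::with_seed(child_seed(seed, "gene_universe"), {
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    query_genes <- sample(gene_id, n_query)
    universe <- tibble(
      gene_id = gene_id,
      expression = exp(rnorm(n_genes, mean = 3, sd = 1)),
      length = round(exp(rnorm(n_genes, mean = 8, sd = 0.6))),
      is_asas = gene_id %in% query_genes
    )
    # term prevalence varies widely, like real ontology term sizes
    prev <- exp(runif(n_terms, log(0.05), log(0.5)))
    ann <- purrr::map(seq_len(n_terms), function(t) {
      members <- gene_id[runif(n_genes) < prev[t]]
      tibble(gene_id = members, term = sprintf("term_%03d", t))
    }) %>% bind_rows()
    planted_members <- c(
      query_genes[runif(n_query) < planted_prob],
      setdiff(gene_id, query_genes)[
        runif(n_genes - n_query) < 0.05]
    )
    ann <- bind_rows(ann, tibble(gene_id = planted_members,
                                 term = "term_planted"))
    list(universe = universe, annotations = ann,
         query_genes = query_genes, planted_term = "term_planted")
  })
}
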