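#' KS enrichment of observed QTL p-values against a sampled background
#'
#' Compares the nominal p-values of QTLs overlapping a query SNP set to a
#' background sampled uniformly from all tested associations, with a
#' Kolmogorov-Smirnov test that is one-sided toward stochastically
#' smaller observed p-values by default.
#'
#' @param observed_p P-values of the overlapping associations.
#' @param all_tested_p P-values of all tested associations.
#' @param n_background Number of background draws, each of size
#'   `length(observed_p)`, pooled into the comparison sample (default 1).
#' @param seed Integer seed for the background sampling.
#' @param alternative `"greater"` (observed stochastically smaller, the
#'   default) or `"two.sided"`.
#' @return A list: `statistic` (KS D), `p_value`, and the background
#'   sample used.
#' @export
ks_pvalue_enrichment <- function(observed_p, all_tested_p,
                                 n_background = 1, seed = 1,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(observed_p) == 0 || length(all_tested_p) == 0) {
    abort("both p-value lists must be non-empty")
  }
  background <- withr::with_seed(child_seed(seed, "ks_background"), {
    unlist(lapply(seq_len(n_background), function(i) {
      sample(all_tested_p, length(observed_p),
             replace = length(all_tested_p) < length(observed_p))
    }))
  })
  # alternative = "greater": CDF of x above CDF of y, i.e. x smaller
  ks <- suppressWarnings(
    ks.test(observed_p, background, alternative = alternative)
  )
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       background = background)
}

#' Compare observed effect sizes with a resampled background
#'
#' Tests whether query-overlapping QTL effect sizes are larger in
#' magnitude than random draws from the full QTL pool: a rank-sum test of
#' the absolute observed effects against pooled background draws, plus
#' the empirical percentile of the observed median among the per-draw
#' medians.
#'
#' @param observed_effects Effect sizes of the overlapping QTLs.
#' @param pool Effect sizes of the full QTL table (at least as many as
#'   observed).
#' @param n_iterations Number of background draws (default 1000).
#' @param seed Integer seed.
#' @param alternative Passed to [stats::wilcox.test()] (default
#'   `"greater"`).
#' @return A list: `wilcoxon_p`, `observed_median`, `null_medians`,
#'   `median_percentile` (fraction of draws with median below the
#'   observed one).
#' @export
resampled_effect_comparison <- function(observed_effects, pool,
                                        n_iterations = 1000, seed = 1,
                                        alternative = "greater") {
  if (length(pool) < length(observed_effects)) {
    abort("pool must be at least as large as the observed set")
  }
  obs <- abs(observed_effects)
  draws <- withr::with_seed(child_seed(seed, "effect_background"), {
    lapply(seq_len(n_iterations), function(i) {
      abs(sample(pool, length(obs)))
    })
  })
  null_medians <- vapply(draws, median, numeric(1))
  background <- unlist(draws)
  w <- suppressWarnings(
    wilcox.test(obs, background, alternative = alternative)
  )
  list(
    wilcoxon_p = w$p.value,
    observed_median = median(obs),
    null_medians = null_medians,
    median_percentile = mean(null_medians < median(obs)) +
      0.5 * mean(null_medians == median(obs))
  )
}

#' Resampling fold change for per-SNP score changes
#'
#' Compares score changes (e.g. predicted binding-affinity deltas) at
#' functional SNPs against repeated equal-size samples from a pool of
#' control SNPs. The fold change is the observed median divided by the
#' median of the per-iteration sample medians; a one-sided Mann-Whitney U
#' test compares the functional deltas against the pooled sampled deltas,
#' and an empirical p counts iterations whose median reaches the observed
#' one.
#'
#' @param functional_deltas Score changes at functional SNPs.
#' @param random_pool_deltas Score changes of the control pool (at least
#'   as many as `functional_deltas`; sampling within an iteration is
#'   without replacement).
#' @param n_iterations Number of resampling iterations (default 1000).
#' @param seed Integer seed.
#' @return A list: `fold_change` (NA with a note when the null median is
#'   zero), `mwu_p`, `empirical_p`, `observed_median`, `null_medians`.
#' @export
resampling_fold_change <- function(functional_deltas, random_pool_deltas,
                                   n_iterations = 1000, seed = 1) {
  n <- length(functional_deltas)
  if (length(random_pool_deltas) < n) {
    abort("pool too small for sampling without replacement")
  }
  draws <- withr::with_seed(child_seed(seed, "fold_change"), {
    lapply(seq_len(n_iterations), function(i) {
      sample(random_pool_deltas, n)
    })
  })
  null_medians <- vapply(draws, median, numeric(1))
  obs_median <- median(functional_deltas)
  null_med <- median(null_medians)
  fold <- if (null_med == 0) NA_real_ else obs_median / null_med
  w <- suppressWarnings(
    wilcox.test(functional_deltas, unlist(draws), alternative = "greater")
  )
  list(
    fold_change = fold,
    fold_change_defined = null_med != 0,
    mwu_p = w$p.value,
    empirical_p = empirical_p(sum(null_medians >= obs_median),
                              n_iterations),
    observed_median = obs_median,
    null_medians = null_medians
  )
}
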