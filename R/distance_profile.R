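#' Positional profile of functional SNPs around ASAS exons
#'
#' Computes the distribution of signed distances from significant
#' functional-SNP calls to their associated exon boundaries, normalised by
#' the number of testable SNPs at each position, together with resampled
#' null profiles built by drawing equally sized random sets from the
#' testable SNPs. A cis-regulatory signal shows up as a boundary-proximal
#' peak in the observed profile that the resampled profiles lack.
#'
#' Distances are negative upstream of the exon start, positive downstream
#' of the exon end, and zero inside the exon; they are binned before
#' normalisation. Bins with no testable SNP are masked (NA density), never
#' divided by zero.
#'
#' @param calls A `concordance_scan` tibble (significant rows are used),
#'   or any tibble with `candidate_snp_id` and `distance_to_exon`.
#' @param testable Tibble of the testable-SNP universe with a
#'   `distance_to_exon` column (one row per testable candidate-event
#'   pairing).
#' @param n_random_sets Number of resampled null sets (default 100).
#' @param bin_width Bin width in base pairs (default 25).
#' @param max_distance Profile half-width in base pairs (default 500);
#'   distances beyond it are truncated into the outermost bins.
#' @param seed Integer seed for the resampling.
#' @return A list of class `distance_profile`: `observed` (tibble of bin
#'   midpoint, observed count, testable count, density) and `random`
#'   (long tibble of per-set densities).
#' @export
distance_profile <- function(calls, testable, n_random_sets = 100,
                             bin_width = 25, max_distance = 500, seed = 1) {
  obs_d <- calls %>%
    (function(d) if ("significant" %in% names(d)) {
      filter(d, .data$significant)
    } else d) %>%
    pull("distance_to_exon")
  test_d <- testable %>% pull("distance_to_exon")
  if (length(test_d) == 0) abort("empty testable SNP universe")

  breaks <- seq(-max_distance - bin_width / 2, max_distance + bin_width / 2,
                by = bin_width)
  clip <- function(x) clamp(x, -max_distance, max_distance)
  bin_of <- function(x) as.integer(cut(clip(x), breaks, include.lowest = TRUE))
  mids <- (head(breaks, -1) + breaks[-1]) / 2

  tab <- function(x) tabulate(bin_of(x), nbins = length(mids))
  n_testable <- tab(test_d)
  n_obs <- tab(obs_d)
  density <- ifelse(n_testable > 0, n_obs / n_testable, NA_real_)

  rnd <- withr::with_seed(child_seed(seed, "distance_profile"), {
    purrr::map(seq_len(n_random_sets), function(i) {
      draw <- sample(test_d, size = min(length(obs_d), length(test_d)))
      tibble(set = i, bin_mid = mids,
             density = ifelse(n_testable > 0,
                              tab(draw) / n_testable, NA_real_))
    })
  }) %>% bind_rows()

  structure(
    list(
      observed = tibble(bin_mid = mids, n_observed = n_obs,
                        n_testable = n_testable, density = density),
      random = rnd,
      bin_width = bin_width,
      n_random_sets = n_random_sets
    ),
    class = "distance_profile"
  )
}

#' Flatness of the aggregated null profile
#'
#' Ratio of the maximum to the median of the mean resampled density over
#' non-masked bins; values near 1 indicate a flat null profile.
#'
#' @param profile A `distance_profile`.
#' @return A single number (max/median of the mean null density).
#' @export
profile_flatness <- function(profile) {
  mean_density <- profile$random %>%
    group_by(.data$bin_mid) %>%
    summarise(density = mean(.data$density)) %>%
    filter(!is.na(.data$density), .data$density > 0) %>%
    pull("density")
  max(mean_density) / median(mean_density)
}
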